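context,n_zero,n_one_plus,printed_pct_zero
cote_divoire,994,1804,35.5
ethiopia,942,2783,25.3
java,4374,4595,48.8
nigeria,5315,5988,47.0
rajasthan,932,4983,15.8
uganda,404,1684,19.3
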