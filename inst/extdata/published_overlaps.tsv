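pair	n_common	n_a	n_b	pct_of_a_published	pct_of_b_published
balaji_vs_yeastract_b	10909	12871	45209	84.76	24.13
balaji_vs_yeastract_b_and_e	3359	12871	11486	26.10	29.24
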