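network	evidence	n_nodes	n_interactions	n_tfs	n_tgs	density_pct_published
costanzo_b	B	688	1079	131	592	1.20
balaji_b	B	4441	12871	159	4408	1.82
yeastract_b_or_e	B_or_E	6886	195470	220	6886	12.90
yeastract_e	E	6711	161747	215	6711	11.21
yeastract_b	B	6478	45209	176	6475	3.97
yeastract_b_and_e	B_and_E	3937	11486	152	3912	1.92
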