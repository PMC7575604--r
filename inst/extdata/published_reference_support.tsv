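reference	n_interactions	n_exclusive	n_shared
salin	74131	1966	72165
reimand	58089	48385	9704
moxley	25142	20614	4528
chua	17756	12294	5462
harbison	10026	3955	6071
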