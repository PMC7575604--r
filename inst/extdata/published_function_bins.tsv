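category	bin	count
Stress response	1-4	87
Stress response	5-9	48
Stress response	10-25	13
all annotated	1-4	3160
all annotated	5-9	608
all annotated	10-25	144
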