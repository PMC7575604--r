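display_id	code	man	name	edges
1	3	021D	single regulator of two targets	1>2;1>3
2	10	021U	two regulators converging on one target	2>1;3>1
3	6	021C	regulatory cascade	1>2;2>3
4	21	111D	mutual dyad with an incoming regulator	1>2;2>1;3>1
5	7	111U	mutual dyad regulating an outside target	1>2;2>1;1>3
6	25	030C	three-node feedback cycle	1>2;2>3;3>1
7	11	030T	feed-forward loop	1>2;1>3;2>3
8	23	201	two mutual dyads sharing a node	1>2;2>1;1>3;3>1
9	30	120D	regulator targeting both members of a mutual dyad	1>2;2>1;3>1;3>2
10	15	120U	mutual dyad regulating a common target	1>2;2>1;1>3;2>3
11	27	120C	mutual dyad inside a cascade	1>2;2>1;3>1;2>3
12	31	210	two mutual dyads plus one directed edge	1>2;2>1;1>3;3>1;2>3
13	63	300	fully mutual triangle	1>2;2>1;1>3;3>1;2>3;3>2
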