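protein_id	family_acc	start	end	score
P0000001	SF0001	26	61	110.4
P0000002	SF0002	30	62	277.8
P0000003	SF0001	21	56	269
P0000003	SF0001	71	106	217.8
P0000003	SF0001	115	150	194.2
P0000004	SF0001	27	62	222.3
P0000004	SF0002	77	109	158.5
P0000005	SF0001	15	50	197.1
P0000005	SF0002	62	94	62.2
P0000006	SF0002	23	55	205.4
P0000006	SF0001	57	92	73.1
P0000007	BF0001	15	48	270.2
P0000009	SF0001	12	47	211.3
P0000010	SF0002	17	49	173.7
P0000010	SF0002	58	90	126.7
P0000011	AF0001	16	58	208.8
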