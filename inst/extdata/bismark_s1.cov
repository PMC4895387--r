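chr1	100	100	75	3	1
chr1	200	200	50	2	2
chr1	300	300	0	0	5
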