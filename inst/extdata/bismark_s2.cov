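chr1	100	100	40	2	3
chr1	300	300	20	1	4
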