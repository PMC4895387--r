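chr1	100	100	90	9	1
chr1	200	200	80	4	1
chr1	300	300	60	3	2
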