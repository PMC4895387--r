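chrom	pos	s1.meth	s1.total	s2.meth	s2.total	s3.meth	s3.total	s4.meth	s4.total
chr1	101	3	10	5	12	8	10	9	11
chr1	205	10	10	12	12	9	9	11	11
chr1	310	0	10	1	12	9	10	10	11
chr1	422	0	10	0	9	0	8	0	7
chr1	537	5	10	6	12	5	10	6	12
chr2	118	5	5	6	6	7	7	8	8
chr2	220	0	0	4	8	3	9	2	6
chr2	333	0	6	6	6	2	5	3	6
chr2	447	2	9	3	8	4	9	5	8
chr2	551	7	9	6	8	1	9	2	8
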