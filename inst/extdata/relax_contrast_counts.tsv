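group	contrast	direction	significant	total
testis-region	present_absent	all	239	503
ovary-region	present_absent	all	34	116
tail-region	present_absent	all	23	95
ubiquitous	present_absent	all	71	231
testis-region	present_absent	k_gt1	30	503
ovary-region	present_absent	k_gt1	12	116
tail-region	present_absent	k_gt1	6	95
ubiquitous	present_absent	k_gt1	16	231
testis-region	present_absent	k_lt1	209	503
ovary-region	present_absent	k_lt1	22	116
tail-region	present_absent	k_lt1	17	95
ubiquitous	present_absent	k_lt1	55	231
testis-region	present_reduced	k_gt1	18	555
ovary-region	present_reduced	k_gt1	10	121
tail-region	present_reduced	k_gt1	5	89
ubiquitous	present_reduced	k_gt1	12	201
testis-region	present_reduced	k_lt1	61	555
ovary-region	present_reduced	k_lt1	4	121
tail-region	present_reduced	k_lt1	5	89
ubiquitous	present_reduced	k_lt1	8	201
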