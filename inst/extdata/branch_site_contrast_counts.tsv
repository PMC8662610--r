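group	contrast	significant	total
testis-region	present_absent	38	503
ovary-region	present_absent	6	116
tail-region	present_absent	9	95
ubiquitous	present_absent	11	231
testis-region	present_reduced	41	555
ovary-region	present_reduced	7	121
tail-region	present_reduced	11	89
ubiquitous	present_reduced	14	201
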