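item	intra_snv	intra_indel	inter_snv	inter_indel
non_coding	88	17	126	23
coding	8	1	18	5
synonymous	1	NA	4	NA
non_synonymous	7	NA	14	NA
frame_shift	NA	1	NA	4
non_frame_shift	NA	0	NA	1
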