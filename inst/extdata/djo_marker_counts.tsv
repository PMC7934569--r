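id	chrom	pos	allele_double	allele_single	d_hom_double	n_hom_double	d_het	n_het	d_hom_single	n_hom_single
0008F-2_3250598	CHR17	43855890	A	G	37	37	0	61	0	47
0008F-2_3250523	CHR17	43855965	A	C	37	37	0	61	0	47
0008F-2_780104	CHR17	43626384	C	A	37	37	0	60	0	48
0259F_404610	CHR17	33708714	T	A	37	37	0	60	0	48
1207F_365533	CHR17	34478996	C	T	38	38	0	61	0	48
1207F_372121	CHR17	34485554	C	A	38	38	0	61	0	47
0437F_170787	CHR17	35610977	G	A	36	37	1	60	1	49
0437F_170821	CHR17	35611011	A	G	36	37	1	60	1	49
0994F_216439	CHR17	35213652	C	T	36	37	1	60	1	49
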