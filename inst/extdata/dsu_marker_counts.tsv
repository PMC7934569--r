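id	chrom	pos	allele_double	allele_single	d_hom_double	n_hom_double	d_het	n_het	d_hom_single	n_hom_single
0577F_1204837	NA	NA	AG	AAACATG	22	22	0	51	1	20
3145F_55089	NA	NA	TA	TAA	22	22	0	51	1	20
3145F_55109	NA	NA	G	A	22	22	0	51	1	20
3145F_55446	NA	NA	G	A	22	22	0	51	1	20
0109F_868569	CHR04	57436162	C	G	22	25	0	44	1	24
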