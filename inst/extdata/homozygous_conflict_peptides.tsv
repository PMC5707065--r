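variant_peptide	reference_peptide	protein_id	variant_label	protein_position	saav_offset	ref_aa	alt_aa	rna_ref_count	rna_alt_count	wgs_ref_count	wgs_alt_count	variant_intensity	reference_intensity
MVWDSQVSEHFFEYKK	MVWDSQASEHFFEYKK	NM_001142677	p.A307V	307	7	A	V	26	45	0	3	122530000	29178000
SQLPDLSAPHSYSPGR	SQLPDLSGPHSYSPGR	NM_015114	p.G891A	891	8	G	A	75	120	0	2	469400000	339370000
QVPPDLFQPYTEEICQNLR	QVPPDLFQPYIEEICQNLR	NM_001619	p.I150T	150	11	I	T	335	385	0	2	22980000	96743000
SGVHVVVTGPPNAGK	SGAHVVVTGPPNAGK	NM_133644	p.V282A	282	3	A	V	41	42	0	3	797570000	64056000
YHSLPPMYYR	YHSLAPMYYR	NM_001252036	p.A86P	86	5	A	P	93	94	0	5	27447000	482390000
TGSTLVQR	TGSALVQR	NM_002675	p.A331T	331	4	A	T	27	26	0	9	1232100000	1585200000
ADGTPITQSVEMTTPSK	ADGTPITQGVEMTTPSK	NM_020070	p.G159S	159	9	G	S	135	120	0	2	220560000	140030000
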