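gene	saav_label	peptide_sequence	saav_offset	ref_aa	alt_aa	site_offset	genomic_coordinates	dbsnp_id	population_allele_freq
ATP5A1	p.A126S	VGLKSPGIIPR	5	A	S	5	chr18:43669656	NA	0.0000
SGK223	p.G1222S	QKPGSTPNLQQK	5	G	S	5	chr8:8176221	rs13269488	0.5286
TANC1	p.N250S	SGSSLEWNKDGSLR	12	N	S	12	chr2:160019863	rs12466551	0.9907
TADA2A	p.P6S	LGSFSNDPSDKPPCR	3	P	S	3	chr17:35771468	rs7211875	0.8597
ATP5SL	p.N40S	LGAAVAPEGSQKK	10	N	S	10	chr19:41944237	rs2231940	0.4053
GBF1	p.G1690S	GGSPSALWEITWER	3	G	S	3	chr10:104140350	rs11191274	0.0972
PCM1	p.N159S	DASTSPPNRETIGSAQCK	5	N	S	5	chr8:17796382	rs41364448	0.7324
PCM1	p.N159S	SKDASTSPPNRETIGSAQCK	7	N	S	7	chr8:17796382	rs41364448	0.7324
SPDL1	p.L586S	SHPILYVSSK	1	L	S	1	chr5:169031150	rs3777084	0.6613
DDX27	p.G766S	ASPSFEER	2	G	S	2	chr20:47859217	rs1130146	0.3498
GPANK1	p.A78S	IMKSPAAEAVAEGASGR	4	A	S	4	chr6:31632024	NA	0.0000
SF3B1	p.A86T	KPGYHTPVALLNDIPQSTEQYDPFAEHRPPK	6	A	T	6	chr2:198285797	NA	0.0000
MEX3A	p.A430T	SPTTSAGPELAGLPR	4	A	T	4	chr1:156046640	NA	0.0000
LMO7	p.M1162T	YLDQIGNTTSSQRR	8	M	T	8	chr13:76423248	rs7986131	0.7203
RMI1	p.N455S	SSQISNENDCNLQSCSLR	1	N	S	1	chr9:86617265	rs1982151	0.7152
ICE1	p.C391S	NSAESVSEDDTTESQNYFGSLR	5	C	S	5	chr5:5460619	rs2619844	0.6964
LAT	p.P253S	TEPAALSSQEAEEVEEEGASDYENLQELN	20	P	S	20	chr16:29001301	NA	0.0000
PNPLA6	p.A403P	ETPGRPPDPTGAPLPGPTGDPVKPTSLETPSPPLLSR	32	A	P	31	chr19:7606908	rs17854645	0.1651
DMXL2	p.S1288P	FGDTEADSPNAEEAAMQDHSTFK	9	S	P	8	chr15:51791559	rs12102203	0.4925
KIAA0586	p.L703P	EASPPPVQTWIK	4	L	P	3	chr14:58937416	rs1748986	0.9916
GGA2	p.A424P	NLLDLLSPQPAPCPLNYVSQK	8	A	P	7	chr16:23489711	rs1135045	0.7564
ZNF235	p.H296P	SPACSTPEKDTSYSSGIPVQQSVR	7	H	P	6	chr19:44792701	rs2125579	0.5206
BRIP1	p.S919P	YSTPPYLLEAASHLSPENFVEDEAK	4	S	P	3	chr17:59763347	rs4986764	0.5972
SHF	p.A242P	ETATQPLPLYDTPYEPEEDGATPEGEGAPWPR	23	A	P	22	chr15:45467540	rs1632144	0.9763
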