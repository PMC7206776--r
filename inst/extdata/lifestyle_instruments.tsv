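trait	snp_id	ancestry	chrom	pos	gene	effect_allele	eaf	beta	se	n	pvalue	source
sedentary	rs26579	European	5	87985295	MEF2C-AS2	G	0.415	0.028	0.005	91105	2.6e-09	UK Biobank
sedentary	rs25966	European	5	106822908	EFNA5	G	0.531	0.028	0.005	91105	3.0e-09	UK Biobank
sedentary	rs6801032	European	3	68527135	LOC105377146	A	0.259	0.031	0.005	91105	3.1e-09	UK Biobank
sedentary	rs7779206	European	7	71723883	CALN1	A	0.558	0.028	0.005	91105	4.2e-09	UK Biobank
MVPA	rs429358	European	19	45411941	APOE	T	0.850	-0.019	0.003	377234	7.3e-11	UK Biobank
MVPA	rs7804463	European	7	133447651	EXOC4	T	0.530	0.013	0.002	377234	4.1e-10	UK Biobank
MVPA	rs2854277	European	6	32628084	HLA-DQB1	C	0.920	0.027	0.005	377234	1.4e-08	UK Biobank
MVPA	rs1379183	European	7	50237784	C7orf72/SPATA48	C	0.410	-0.012	0.002	377234	1.7e-08	UK Biobank
MVPA	rs3094622	European	6	30327952	RPP21	A	0.860	0.018	0.003	377234	1.0e-08	UK Biobank
MVPA	rs149943	European	6	28002388	ZNF165	G	0.850	0.016	0.003	377234	5.6e-08	UK Biobank
MVPA	rs2035562	European	3	85056521	CADM2	A	0.330	-0.014	0.002	377234	1.0e-09	UK Biobank
MVPA	rs7854466	European	9	37044388	PAX5	T	0.560	-0.014	0.002	377234	2.4e-11	UK Biobank
MVPA	rs1043595	European	7	128410012	CALU	G	0.720	0.013	0.002	377234	4.2e-08	UK Biobank
VPA	rs1248860	European	3	85015779	CADM2	G	0.480	-0.051	0.007	261055	5.3e-15	UK Biobank
VPA	rs2764261	European	6	108927842	FOXO3	A	0.370	0.030	0.005	261055	5.3e-08	UK Biobank
VPA	rs13243553	European	7	133506955	EXOC4	G	0.610	0.039	0.007	261055	2.4e-09	UK Biobank
VPA	rs3781411	European	10	126715436	CTBP2	C	0.880	0.058	0.009	261055	1.0e-10	UK Biobank
VPA	rs328902	European	7	35020843	DPY19L1	C	0.690	-0.041	0.006	261055	1.3e-10	UK Biobank
sleep_duration	rs1191685	European	2	113811454	PAX8	C	0.370	2.870	0.470	44563	1.06e-09	CHARGE
sleep_duration	rs1823125	European	2	113806882	PAX8	G	0.260	3.010	0.500	45281	1.71e-08	CHARGE
sleep_duration	rs1807282	European	2	113826506	PAX8	T	0.260	2.890	0.490	46805	3.91e-09	CHARGE
sleep_duration	rs1964463	European	2	113785491	PAX8	G	0.250	2.840	0.500	45281	1.07e-08	CHARGE
sleep_duration	rs4587207	European	6	30874924	IER3	G	0.800	-3.140	0.560	46807	2.02e-08	CHARGE
sleep_duration	rs4248149	European	6	30875606	IER3	C	0.800	-3.080	0.560	46810	3.95e-08	CHARGE
sleep_duration	rs2394403	European	6	30875848	IER3	T	0.800	-3.070	0.560	46811	4.39e-08	CHARGE
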