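id	chromosome	strand	start	end	length_aa	mw	pi	n_introns
GaCAMTA2.1	CA_chr13	-	71972149	71984252	1073	120631.7	5.84	12
GaCAMTA2.2	CA_chr5	-	48849059	48856677	1057	119070.7	5.56	12
GaCAMTA4	CA_chr10	-	111920640	111926272	986	109945	5.68	11
GaCAMTA5.1	CA_chr9	-	96490041	96496016	907	102259.5	6.68	12
GaCAMTA5.2	CA_chr5	+	41655137	41661738	1038	116596.2	7.84	15
GaCAMTA7	CA_chr9	-	2798738	2804286	968	107062.9	8.07	11
GrCAMTA2.1	Chr13	-	6625467	6634301	1067	119814.7	5.74	11
GrCAMTA2.2	Chr05	+	60341564	60349789	1052	118318.9	5.67	12
GrCAMTA3.1	Chr08	-	21118330	21127475	1087	123051	6.13	11
GrCAMTA5.1	Chr06	+	30416003	30422953	907	102683.8	7.9	12
GrCAMTA5.2	Chr11	+	47994290	48001178	914	102996.6	7.58	12
GrCAMTA5.3	Chr05	+	7009778	7014890	910	102757.4	7.61	12
GrCAMTA7	Chr11	-	49581143	49586771	980	109118.1	7.35	10
GhCAMTA2A.1	At_chr13	-	76266490	76278551	1073	120643.6	5.8	12
GhCAMTA2A.2	At_chr5	-	51890245	51897861	1057	119099.8	5.56	12
GhCAMTA2D.1	Dt_chr5	-	10886018	10893621	1057	118913.7	5.61	12
GhCAMTA3A.1	At_chr12	+	5508767	5516875	1088	123132.9	6.04	12
GhCAMTA3D.1	Dt_chr9	+	6259590	6267679	1070	121661.3	6.17	12
GhCAMTA4D	Dt_chr9	+	26547082	26552392	968	108026.8	5.81	9
GhCAMTA5D.1	Dt_chr5	-	5701131	5710161	1016	115094.2	8.72	15
GhCAMTA7A	At_chr11	-	9038073	9043485	963	106755.6	6.99	10
GhCAMTA7D	Dt_chr11	-	56557476	56562833	976	108662.4	7.01	11
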