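chrom	pos	ref	alt	rsid	gene	consequence	aa_change	maf_1000g	maf_esp	q2_esp	sift	polyphen2	fathmm	siphy
16	3656625	G	A	rs79842542	FANCP/SLX4	missense	R204C	0.06	0.071264	-	0	1	3.49	12.9
16	3658545	C	A	rs137976282	FANCP/SLX4	missense	G141W	0	0.00077	-	0	0.96	5.2	7.27
10	95278683	G	A	rs75139274	CEP55	missense	R348K	0.03	0.074581	-	0.19	0.21	2.05	11.44
10	95279506	A	T	rs2293277	CEP55	missense	H378L	0.56	0.610257	-	0.13	0.48	2.21	14.69
17	7673930	A	G	rs140035206	DNAH2	missense	Y1385C	0	0.004075	-	0	1	-0.15	15.1
17	7734114	A	C	rs79350244	DNAH2	missense	I4023L	0.01	0.021913	-	1	0.52	3.81	15.2
17	7734476	A	T	rs117465420	DNAH2	missense	L4062F	0.01	0.021759	-	0.02	0.41	3.06	8.22
17	7736480	T	A	rs78354379	DNAH2	missense	V4357D	0.05	0.008073	-	0.03	0.99	2.95	12.12
1	144879090	C	T	rs1778120	PDE4DIP	missense	K1410E	-	0.124712	-	0.11	1	4.64	11.54
1	144916676	C	T	rs1698683	PDE4DIP	-	W626*	-	0.321203	-	0.16	-	3.81	18.03
2	17946243	A	G	rs16981869	GEN1	missense	N143S	0.13	0.145394	0.025	0.03	0.81	-0.45	8.03
13	31891746	G	A	rs1041073	B3GALTL	missense	E370K	0.67	0.65539	0.442	0.28	0.96	-1.92	7.09
9	35674053	G	A	rs2071676	CA9	missense	V33L	0.32	0.269107	0.56	0	0.82	-0.66	8.01
1	203194186	C	T	rs2297950	CHIT1	missense	G102S	0.29	0.285253	0.065	0	1	3.81	7.76
17	7348625	A	G	rs17856697	CHRNB1	missense	E32G	0.12	0.25585	0.052	0.08	0.77	-1.16	8.74
17	37884037	C	G	rs1058808	ERBB2	missense	P1170A	0.45	0.513532	0.278	0.03	0.95	-0.81	18.01
17	30692396	G	T	rs3795244	ZNF207	missense	A240S	0.05	0.045748	0.001	0.41	0.75	0.85	20.21
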