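##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	SIBA	SIBB	FATHER	MOTHER
16	3656625	rs79842542	G	A	.	PASS	.	GT	0/1	0/1	0/1	0/0
16	3658545	rs137976282	C	A	.	PASS	.	GT	0/1	0/1	0/0	0/1
10	95278683	rs75139274	G	A	.	PASS	.	GT	0/1	0/1	0/1	0/0
10	95279506	rs2293277	A	T	.	PASS	.	GT	0/1	0/1	0/0	0/1
17	7673930	rs140035206	A	G	.	PASS	.	GT	0/1	0/1	0/1	0/0
17	7734114	rs79350244	A	C	.	PASS	.	GT	0/1	0/1	0/0	0/1
17	7734476	rs117465420	A	T	.	PASS	.	GT	0/1	0/1	0/0	0/1
17	7736480	rs78354379	T	A	.	PASS	.	GT	0/1	0/1	0/1	0/0
1	144879090	rs1778120	C	T	.	PASS	.	GT	0/1	0/1	0/1	1/1
1	144916676	rs1698683	C	T	.	PASS	.	GT	0/1	0/1	0/0	0/1
2	17946243	rs16981869	A	G	.	PASS	.	GT	1/1	1/1	0/1	0/1
13	31891746	rs1041073	G	A	.	PASS	.	GT	1/1	1/1	0/1	0/1
9	35674053	rs2071676	G	A	.	PASS	.	GT	1/1	1/1	0/1	0/1
1	203194186	rs2297950	C	T	.	PASS	.	GT	1/1	1/1	0/1	0/1
17	7348625	rs17856697	A	G	.	PASS	.	GT	1/1	1/1	0/1	0/1
17	37884037	rs1058808	C	G	.	PASS	.	GT	1/1	1/1	0/1	0/1
17	30692396	rs3795244	G	T	.	PASS	.	GT	1/1	1/1	0/1	0/1
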