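rsid	SIBA	SIBB
rs7073837	-	AA
rs10994982	GG	GA
rs10740055	-	CC
rs10821936	-	CC
rs7089424	-	GG
rs2239633	CT	TT
rs7809758	AG	AG
rs880028	TC	TC
rs3779084	TC	TC
rs2242041	GG	CG
rs6964823	GA	GA
rs11978267	-	AG
rs4132601	-	TG
rs6944602	GG	GG
rs1881797	TT	-
rs36228834	TT	TT
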