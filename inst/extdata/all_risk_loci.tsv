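gene	rsid	ref
ARID5B	rs7073837	C
ARID5B	rs10994982	G
ARID5B	rs10740055	A
ARID5B	rs10821936	T
ARID5B	rs7089424	T
CEBPE	rs2239633	C
DDC	rs7809758	A
DDC	rs880028	T
DDC	rs3779084	T
DDC	rs2242041	C
IKZF1	rs6964823	G
IKZF1	rs11978267	A
IKZF1	rs4132601	T
IKZF1	rs6944602	G
OR2C3	rs1881797	T
CDKN2A	rs36228834	T
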