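gene	rsid	phenotype	mean_diff	ci_lo	ci_hi	p_value	risk_allele
GIPR	rs10423928	twl_nadir	-3.32	-5.53	-1.11	0.0036	A
GIPR	rs10423928	twl_6y	-3.55	-6.33	-0.77	0.013	A
DPPIV	rs1861975	twl_nadir	2.92	-0.11	5.72	0.042	A
DPPIV	rs1861975	twl_6y	3.92	0.47	7.36	0.026	A
NPY1R	rs9764	twl_nadir	4.61	0.09	9.13	0.047	T
NPY5R	rs11100493	twl_6y	22.2	2.19	42.2	0.03	T
CLOCK	rs1801260	twl_6y	1.85	0.07	3.62	0.042	A
CLOCK	rs1801260	wr_mwl	-3.27	-6.42	-0.12	0.042	A
GLP1R	rs10305439	twl_6y	2.71	0.41	5.01	0.022	C
GLP1R	rs10305439	wr_mwl	-4.88	-8.84	-0.92	0.016	C
GLP1R	rs2143734	twl_6y	-1.76	-3.46	-0.05	0.039	G
GLP1R	rs877446	wr_mwl	-5.03	-9.72	0.34	0.036	A
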