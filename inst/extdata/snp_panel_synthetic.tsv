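gene	rsid	ref	alt	maf
GHSR	rs572169	C	T	0.294
WFS1	rs10010131	A	G	0.383
BDNF	rs6265	C	T	0.172
MC4R	rs17782313	T	C	0.362
GIPR	rs10423928	T	A	0.257
DPPIV	rs17759529	C	T	0.407
DPPIV	rs2389643	C	T	0.427
DPPIV	rs2268889	C	T	0.344
DPPIV	rs12995983	T	C	0.115
DPPIV	rs3788979	C	T	0.405
DPPIV	rs741529	G	A	0.401
DPPIV	rs12469968	G	A	0.181
DPPIV	rs1861975	A	G	0.138
NPY2R	rs6849115	T	C	0.285
NPY2R	rs11099992	A	G	0.189
NPY2R	rs6857715	C	T	0.293
NPY2R	rs1047214	C	T	0.121
NPY2R	rs17304901	G	A	0.13
NPY2R	rs11728843	G	A	0.342
NPY1R	rs9764	T	C	0.345
NPY1R	rs7687423	A	G	0.189
NPY1R	rs11100489	T	C	0.401
NPY5R	rs11100493	T	C	0.278
NPY5R	rs4632602	C	T	0.383
NPY5R	rs11724320	T	C	0.409
NPY5R	rs7678265	C	T	0.192
CLOCK	rs3749474	C	T	0.38
CLOCK	rs1801260	A	G	0.221
CLOCK	rs4580704	G	A	0.29
GLP1R	rs10305439	C	T	0.4
GLP1R	rs2143734	A	G	0.161
GLP1R	rs877446	A	G	0.439
GLP1R	rs6923761	G	A	0.169
GLP1R	rs932443	T	C	0.144
GLP1R	rs2300612	T	C	0.41
GLP1R	rs2268640	G	A	0.39
TCF7L2	rs7903146	C	T	0.316
TCF7L2	rs12255372	G	A	0.429
KCNJ11	rs5215	C	T	0.416
KCNJ11	rs5218	G	A	0.272
KCNJ11	rs5219	T	C	0.407
KCNJ11	rs886288	A	G	0.217
FTO	rs9939609	T	C	0.152
FTO	rs9939973	G	A	0.431
PYY	rs2700831	T	C	0.173
PYY	rs9890045	G	A	0.126
PYY	rs1684668	T	C	0.341
PYY	rs1618809	A	G	0.129
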