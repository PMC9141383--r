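group	locus	genotype	proportion
athlete	ANKK1	AA	0.038
athlete	ANKK1	AG	0.310
athlete	ANKK1	GG	0.652
athlete	APOE_e	e4+	0.289
athlete	APOE_e	e4-	0.711
athlete	rs405509	GG	0.258
athlete	rs405509	GT	0.487
athlete	rs405509	TT	0.255
athlete	BDNF_AS	CC	0.675
athlete	BDNF_AS	CT	0.289
athlete	BDNF_AS	TT	0.036
athlete	COMT	AA	0.248
athlete	COMT	AG	0.498
athlete	COMT	GG	0.254
athlete	MAPT	CC	0.047
athlete	MAPT	CT	0.357
athlete	MAPT	TT	0.596
athlete	NOS3	CC	0.148
athlete	NOS3	CT	0.476
athlete	NOS3	TT	0.376
nonathlete	ANKK1	AA	0.042
nonathlete	ANKK1	AG	0.306
nonathlete	ANKK1	GG	0.652
nonathlete	APOE_e	e4+	0.282
nonathlete	APOE_e	e4-	0.718
nonathlete	rs405509	GG	0.262
nonathlete	rs405509	GT	0.473
nonathlete	rs405509	TT	0.265
nonathlete	BDNF_AS	CC	0.663
nonathlete	BDNF_AS	CT	0.301
nonathlete	BDNF_AS	TT	0.036
nonathlete	COMT	AA	0.302
nonathlete	COMT	AG	0.474
nonathlete	COMT	GG	0.224
nonathlete	MAPT	CC	0.047
nonathlete	MAPT	CT	0.314
nonathlete	MAPT	TT	0.639
nonathlete	NOS3	CC	0.170
nonathlete	NOS3	CT	0.443
nonathlete	NOS3	TT	0.387
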