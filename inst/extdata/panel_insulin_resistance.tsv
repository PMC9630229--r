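variant_id	risk_allele	other_allele	weight	freq
rs4734224	G	C	0.098	0.715
rs5174921	C	G	0.1709	0.532
rs1917404	G	A	0.2263	0.595
rs1052087	A	C	0.2104	0.438
rs5046757	T	C	0.2394	0.447
rs8878049	A	T	0.1095	0.342
rs9213641	G	C	0.131	0.307
rs6661392	C	G	0.1691	0.494
rs3175385	T	A	0.122	0.403
rs3513201	A	T	0.1854	0.322
rs6787865	C	T	0.131	0.688
rs7902922	A	C	0.2286	0.596
rs4329933	G	A	0.2467	0.71
rs3454767	A	G	0.1715	0.758
rs6862065	G	T	0.1224	0.699
rs9460434	C	T	0.1802	0.301
rs6195441	A	G	0.1049	0.479
rs4905418	A	T	0.2025	0.614
rs8247791	G	C	0.124	0.733
rs6742446	G	C	0.161	0.377
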