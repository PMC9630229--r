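variant_id	risk_allele	other_allele	weight	freq
rs4706928	A	C	0.1471	0.769
rs7989873	G	C	0.2276	0.529
rs1004087	T	C	0.0901	0.795
rs6400256	C	A	0.0887	0.374
rs7538704	C	T	0.0823	0.694
rs1902140	C	A	0.2542	0.309
rs2969682	C	G	0.1864	0.73
rs5400202	A	C	0.1939	0.531
rs1631188	G	C	0.2626	0.561
rs3924843	G	C	0.1536	0.757
rs8619297	C	T	0.2649	0.74
rs1379804	T	A	0.0716	0.23
rs7970583	A	T	0.168	0.366
rs7652027	A	C	0.1434	0.705
rs4482870	A	G	0.0556	0.692
rs4050754	C	A	0.1866	0.68
rs5128015	C	T	0.1588	0.643
rs7046228	G	C	0.2947	0.204
rs9397777	T	G	0.2292	0.664
rs1012704	C	G	0.1003	0.231
rs2198451	T	A	0.1707	0.671
rs8393085	G	T	0.2707	0.277
rs2327174	A	G	0.215	0.727
rs8966791	A	C	0.0688	0.337
rs7685054	T	A	0.2814	0.313
rs7794902	A	G	0.0933	0.507
rs1602991	C	T	0.1396	0.623
rs7017868	C	G	0.2299	0.373
rs8124969	G	A	0.2088	0.456
rs5573744	T	C	0.1133	0.531
rs1779027	A	C	0.1896	0.234
rs8746676	T	G	0.2232	0.734
rs9777903	G	A	0.1617	0.669
rs7551934	T	C	0.2515	0.792
rs5631495	A	T	0.2148	0.599
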