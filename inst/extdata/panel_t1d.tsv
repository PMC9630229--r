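variant_id	risk_allele	other_allele	weight	freq
rs7497306	G	T	0.233	0.437
rs4350901	A	C	0.1125	0.227
rs4261445	T	C	0.1004	0.253
rs2540814	A	G	0.5046	0.737
rs3151447	G	C	0.1019	0.766
rs4523523	A	C	0.3648	0.771
rs7567167	T	G	0.5828	0.331
rs9609565	T	A	0.2613	0.778
rs2441251	C	A	0.497	0.555
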