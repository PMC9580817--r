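rsID	effect_allele	other_allele	effect_weight
rs77294520	A	G	0.19
rs99000001	G	A	0.11
rs99000002	T	C	0.08
rs99000003	C	T	0.06
rs99000004	A	G	0.17
rs99000005	G	A	0.09
rs99000006	T	C	0.13
rs99000007	C	T	0.07
rs99000008	A	G	0.10
rs99000009	G	A	0.15
rs99000010	T	C	0.05
rs99000011	C	T	0.12
rs99000012	A	G	0.20
rs99000013	G	A	0.08
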