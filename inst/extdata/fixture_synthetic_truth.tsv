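genome_id	protein_id	window_start	anchor_start	planted_21mer	motif_id
g0002	g0002|p003	62	67	MTNWEYRLAFCRVKKTEIVCS	full
g0002	g0002|p002	66	71	YTFWHYEMNFERVAYLYTVAV	relax_R1
g0001	g0001|p004	81	86	EMNDSYRNKKPRVFSAGETSI	relax_F4
g0001	g0001|p001	20	25	MEVGWYRSPFSRVVHLYRNGK	full
g0001	g0001|p002	30	35	TTLSFYRPPFLRVRRPFYIIF	full
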