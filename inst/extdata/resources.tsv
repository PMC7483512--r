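name	unit	molar_mass	carbon_atoms	in_feed	is_gas_sink
protein	g_per_L	110	NA	2.0	FALSE
starch	g_per_L	162	6	5.6	FALSE
NSP	g_per_L	162	6	1.8	FALSE
acetate	mM	60	2	32	FALSE
propionate	mM	74	3	0	FALSE
butyrate	mM	88	4	0	FALSE
lactate	mM	90	3	0	FALSE
formate	mM	46	1	0	FALSE
H2	mM	2	0	0	TRUE
CO2	mM	44	1	0	TRUE
CH4	mM	16	1	0	TRUE
H2O	mM	18	0	0	TRUE
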