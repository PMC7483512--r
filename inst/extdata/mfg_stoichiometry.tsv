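mfg	pathway	resource	role	moles
M1	starch	starch	substrate	3
M1	starch	propionate	product	4
M1	starch	acetate	product	2
M1	starch	CO2	product	2
M1	nsp	NSP	substrate	3
M1	nsp	propionate	product	4
M1	nsp	acetate	product	2
M1	nsp	CO2	product	2
M1	protein	protein	substrate	3
M1	protein	acetate	product	2
M1	protein	propionate	product	1
M2	starch	starch	substrate	1
M2	starch	acetate	product	2
M2	starch	CO2	product	2
M2	starch	H2	product	4
M3	nsp	NSP	substrate	1
M3	nsp	acetate	product	2
M3	nsp	formate	product	2
M3	protein	protein	substrate	1
M3	protein	acetate	product	1
M3	protein	formate	product	1
M4	starch	starch	substrate	1
M4	starch	lactate	product	2
M5	starch	starch	substrate	4
M5	starch	acetate	substrate	2
M5	starch	butyrate	product	5
M5	starch	H2	product	6
M5	starch	CO2	product	8
M5	starch	H2O	product	2
M5	nsp	NSP	substrate	4
M5	nsp	acetate	substrate	2
M5	nsp	butyrate	product	5
M5	nsp	H2	product	6
M5	nsp	CO2	product	8
M5	nsp	H2O	product	2
M6	nsp	NSP	substrate	2
M6	nsp	acetate	substrate	1
M6	nsp	butyrate	product	2.5
M6	nsp	formate	product	2
M6	nsp	CO2	product	2
M7	lactate	lactate	substrate	3
M7	lactate	propionate	product	2
M7	lactate	acetate	product	1
M7	lactate	CO2	product	1
M7	lactate	H2O	product	1
M8	lactate	lactate	substrate	4
M8	lactate	acetate	substrate	2
M8	lactate	butyrate	product	3
M8	lactate	CO2	product	4
M8	lactate	H2	product	2
M8	lactate	H2O	product	2
M9	starch	starch	substrate	1
M9	starch	acetate	product	3
M9	acetogenesis	H2	substrate	4
M9	acetogenesis	CO2	substrate	2
M9	acetogenesis	acetate	product	1
M9	acetogenesis	H2O	product	2
M10	hydrogenotrophic	H2	substrate	4
M10	hydrogenotrophic	CO2	substrate	1
M10	hydrogenotrophic	CH4	product	1
M10	hydrogenotrophic	H2O	product	2
M10	formate	formate	substrate	4
M10	formate	CH4	product	1
M10	formate	CO2	product	3
M10	formate	H2O	product	2
M7	starch	starch	substrate	3
M7	starch	propionate	product	4
M7	starch	acetate	product	2
M7	starch	CO2	product	2
M8	starch	starch	substrate	4
M8	starch	acetate	substrate	2
M8	starch	butyrate	product	5
M8	starch	H2	product	6
M8	starch	CO2	product	8
M8	starch	H2O	product	2
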