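mfg	pathway	mu_max	yield	primary_substrate
M1	starch	5.0	0.30	starch
M1	nsp	3.5	0.30	NSP
M1	protein	2.0	0.30	protein
M2	starch	3.5	0.30	starch
M3	nsp	3.0	0.30	NSP
M3	protein	2.0	0.30	protein
M4	starch	5.0	0.25	starch
M5	starch	4.0	0.30	starch
M5	nsp	2.5	0.30	NSP
M6	nsp	3.0	0.30	NSP
M7	lactate	5.0	0.06	lactate
M8	lactate	5.0	0.06	lactate
M9	starch	2.0	0.30	starch
M9	acetogenesis	2.0	0.25	H2
M10	hydrogenotrophic	2.0	0.30	H2
M10	formate	2.0	0.02	formate
M7	starch	2.5	0.30	starch
M8	starch	2.5	0.30	starch
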