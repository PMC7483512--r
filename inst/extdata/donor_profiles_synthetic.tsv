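donor	mfg	fraction
D2	M1	0.300
D2	M2	0.030
D2	M3	0.299
D2	M4	0.050
D2	M5	0.100
D2	M6	0.120
D2	M7	0.008
D2	M8	0.007
D2	M9	0.080
D2	M10	0.006
D7	M1	0.250
D7	M2	0.040
D7	M3	0.320
D7	M4	0.100
D7	M5	0.120
D7	M6	0.100
D7	M7	0.001
D7	M8	0.001
D7	M9	0.067
D7	M10	0.001
D19	M1	0.350
D19	M2	0.020
D19	M3	0.280
D19	M4	0.080
D19	M5	0.090
D19	M6	0.110
D19	M7	0.0015
D19	M8	0.0005
D19	M9	0.067
D19	M10	0.001
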