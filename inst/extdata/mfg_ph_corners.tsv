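mfg	c1	c2	c3	c4
M1	5.3	6.0	7.0	7.5
M2	5.2	5.8	6.9	7.5
M3	5.2	5.8	6.9	7.5
M4	4.0	4.5	5.8	6.8
M5	5.0	5.4	6.9	7.5
M6	5.0	5.4	6.9	7.5
M7	5.0	5.4	6.9	7.5
M8	5.0	5.4	6.9	7.5
M9	5.3	5.9	6.9	7.5
M10	5.4	6.0	7.1	7.6
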