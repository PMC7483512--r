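mfg	ki_mM
M1	5
M2	15
M3	15
M4	NA
M5	15
M6	15
M7	15
M8	15
M9	15
M10	15
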