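TF1	synthetic regulon	G1	G2	G3	G4	G5	G6
TF2	synthetic regulon	G4	G5	G7	G8	G9	G10
TF3	synthetic regulon	G2	G8	G11	G12	G13	G14
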