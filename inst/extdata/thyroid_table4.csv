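histology,stage,g1,g2,g3,g4,g5,g6,g7
differentiated,I,45302,466,205,0,0,0,0
differentiated,II,441,3228,476,0,32,0,0
differentiated,III,0,0,0,421,130,0,0
differentiated,IVA,0,0,0,0,234,96,0
differentiated,IVB,0,0,0,0,35,185,40
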