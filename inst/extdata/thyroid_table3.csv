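histology,stage,g1,g2,g3,g4,g5,g6,g7
follicular,I,3668,3,25,0,0,0,0
follicular,II,5,659,15,0,2,0,0
follicular,III,0,0,0,33,2,0,0
follicular,IVA,0,0,0,0,42,7,0
follicular,IVB,0,0,0,0,16,67,13
papillary,I,41634,463,180,0,0,0,0
papillary,II,436,2569,461,0,30,0,0
papillary,III,0,0,0,388,128,0,0
papillary,IVA,0,0,0,0,192,89,0
papillary,IVB,0,0,0,0,19,118,27
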