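taxon_id,species,cultivar,cluster,c1,c2,c3,c4,c5,c6,c7
ANG_W,Lavandula angustifolia,White,1,1,0,0,0,0,1,0
ANG_B,Lavandula angustifolia,Blue,1,1,1,1,0,0,1,0
INT_A,Lavandula x intermedia,Abrial,1,1,0,0,0,0,1,0
INT_G,Lavandula x intermedia,Grosso,1,1,1,1,0,0,1,0
ALL,Lavandula allardi,,2,0,1,1,0,0,0,0
DEN,Lavandula dentata,,2,1,1,1,0,0,0,0
LAT,Lavandula latifolia,,2,0,1,1,0,0,0,0
PIN,Lavandula pinnata,,3,0,1,0,1,0,0,0
CAN,Lavandula canariensis,,4,0,1,0,1,1,0,0
STO,Lavandula stoechas,Pedunculata,5,0,1,0,1,1,1,0
PER,Perovskia atriplicifolia,,6,0,1,0,1,1,0,1
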