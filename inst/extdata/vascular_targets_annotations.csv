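assay_id,platform,cell_system,gene_symbol,target_feature,direction,measure
VEGFR1,NVS,cell-free,FLT1,VEGFR1,na,AC50
VEGFR2,NVS,cell-free,KDR,VEGFR2,na,AC50
VEGFR3,NVS,cell-free,FLT4,VEGFR3,na,AC50
TIE2,NVS,cell-free,TEK,TIE2,na,AC50
EphB2,NVS,cell-free,EPHB2,EphB2,na,AC50
PI3Ka,NVS,cell-free,PIK3CA,PI3Ka,na,AC50
PTEN,NVS,cell-free,PTEN,PTEN,na,AC50
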