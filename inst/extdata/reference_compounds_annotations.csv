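assay_id,platform,cell_system,gene_symbol,target_feature,direction,measure
CCL2_down,BSK,BSK:SAg,CCL2,CCL2_down,down,LEC
CXCL10_up,BSK,BSK:SAg,CXCL10,CXCL10_up,up,LEC
uPAR_updown,BSK,BSK:BE3C,PLAUR,uPAR_updown,updown,LEC
PAI1_updown,BSK,BSK:BE3C,SERPINE1,PAI1_updown,updown,LEC
VEGFR2_down,BSK,BSK:4H,KDR,VEGFR2_down,down,LEC
TIE2_inhib,NVS,cell-free,TEK,TIE2_inhib,down,AC50
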