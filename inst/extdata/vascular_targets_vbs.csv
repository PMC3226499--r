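chemical,vbs,group
Abamectin,5.19,pvdc
Maneb,4.69,pvdc
Metiram-zinc,4.35,pvdc
Oxytetracycline dihydrate,3.85,pvdc
Perfluorooctanesulfonic acid,3.48,pvdc
Perfluorooctanoic acid,3.04,pvdc
Mancozeb,3.00,pvdc
Emamectin benzoate,2.91,pvdc
"2,2-bis-(p-Hydroxyphenyl)-1,1,1-trichloroethane",2.28,pvdc
Diclosulam,2.09,pvdc
Milbemectin,1.49,pvdc
Captan,1.14,non_pvdc
Cyclanilide,0.21,non_pvdc
Sethoxydim,0.00,non_pvdc
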