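chemical,VEGFR1,VEGFR2,VEGFR3,TIE2,EphB2,PI3Ka,PTEN
Abamectin,,,,38.8,17,6.4,
Maneb,4.1,31,12,8.08,23,,0.9
Metiram-zinc,6.6,41,22,15,,29,12
Oxytetracycline dihydrate,,19,6.5,15,,6.2,1.6
Perfluorooctanesulfonic acid,8.2,50,8,4.43,,6.5,17
Perfluorooctanoic acid,,,,31.9,,,
Mancozeb,19,5.9,1.3,10.4,21,20,0.23
Emamectin benzoate,,,,,21,7.9,2.1
"2,2-bis-(p-Hydroxyphenyl)-1,1,1-trichloroethane",,,,,,28,
Diclosulam,,,,,,,50
Milbemectin,,,,,20,11,12
Captan,,,,,,,35
Cyclanilide,,,,,50,,3.9
Sethoxydim,,,,,,,22
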