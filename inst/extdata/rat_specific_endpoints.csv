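chemical,species,category,lel
Diniconazole,rat,"general fetal pathology; embryo fetal loss; maternal pregnancy loss; skeletal: appendicular; skeletal: axial; urogenital: renal",
Naled,rat,"embryo fetal loss; trunk: body wall",
"(Z,E)-Fenpyroximate",rat,"skeletal: axial",
Cyazofamid,rat,"skeletal: axial",
Chlorothalonil,rat,"embryo fetal loss; maternal pregnancy loss",
Lactofen,rat,"fetal weight reduction; maternal pregnancy loss; skeletal: appendicular; skeletal: axial",
Spirodiclofen,rat,"urogenital: renal",
Thiodicarb,rat,"fetal weight reduction; general fetal pathology; embryo fetal loss; maternal pregnancy loss; skeletal: axial",
Alachlor,rat,"fetal weight reduction; embryo fetal loss",
Emamectin benzoate,rat,"fetal weight reduction; skeletal: appendicular; skeletal: axial; skeletal: cranial",
Fluoxastrobin,rat,"skeletal: appendicular",
Hexythiazox,rat,"skeletal: appendicular",
Tetraconazole,rat,"general fetal pathology; skeletal: axial; urogenital: renal; urogenital: ureteric",
Prodiamine,rat,"neurosensory: eye",
Fenpropathrin,rat,"maternal pregnancy loss",
Acetochlor,rat,"fetal weight reduction; general fetal pathology; embryo fetal loss; maternal pregnancy loss; skeletal: axial",
Prallethrin,rat,"maternal pregnancy loss",
Thiazopyr,rat,"skeletal: axial",
Fludioxonil,rat,"urogenital: renal; urogenital: ureteric",
Profenofos,rat,"maternal pregnancy loss",
Metolachlor,rat,"fetal weight reduction; embryo fetal loss; maternal pregnancy loss",
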