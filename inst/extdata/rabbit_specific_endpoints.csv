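chemical,species,category,lel
Methylene bis(thiocyanate),rabbit,"maternal pregnancy loss",
Trifloxystrobin,rabbit,"skeletal: axial",
Propargite,rabbit,"skeletal: axial",
Etoxazole,rabbit,"skeletal: axial",
Fenoxycarb,rabbit,"skeletal: axial",
Azamethiphos,rabbit,"maternal pregnancy loss",
Quinoxyfen,rabbit,"maternal pregnancy loss",
Butafenacil,rabbit,"embryo fetal loss",
Dazomet,rabbit,"general fetal pathology; embryo fetal loss; skeletal: axial",
Rimsulfuron,rabbit,"embryo fetal loss; maternal pregnancy loss",
Dichlorvos,rabbit,"maternal pregnancy loss",
Bensulide,rabbit,"maternal pregnancy loss",
Flumiclorac-pentyl,rabbit,"maternal pregnancy loss",
Diclosulam,rabbit,"maternal pregnancy loss",
Propetamphos,rabbit,"embryo fetal loss",
Butachlor,rabbit,"fetal weight reduction; embryo fetal loss; maternal pregnancy loss",
Dicofol,rabbit,"maternal pregnancy loss",
Oxyfluorfen,rabbit,"embryo fetal loss; maternal pregnancy loss",
Famoxadone,rabbit,"embryo fetal loss; maternal pregnancy loss",
Flufenpyr-ethyl,rabbit,"maternal pregnancy loss",
Dicrotophos,rabbit,"fetal weight reduction; maternal pregnancy loss",
Carboxin,rabbit,"maternal pregnancy loss",
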