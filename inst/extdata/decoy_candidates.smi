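# Small hard-coded candidate library for decoy-selection examples
aspirin	CC(=O)Oc1ccccc1C(=O)O
paracetamol	CC(=O)Nc1ccc(O)cc1
caffeine	Cn1cnc2c1c(=O)n(C)c(=O)n2C
ibuprofen	CC(C)Cc1ccc(cc1)C(C)C(=O)O
naproxen	COc1ccc2cc(ccc2c1)C(C)C(=O)O
salicin	OCC1OC(Oc2ccccc2CO)C(O)C(O)C1O
arbutin	OCC1OC(Oc2ccc(O)cc2)C(O)C(O)C1O
esculin	OCC1OC(Oc2cc3ccc(=O)oc3cc2O)C(O)C(O)C1O
helicin	OCC1OC(Oc2ccccc2C=O)C(O)C(O)C1O
phlorizin	OCC1OC(Oc2cc(O)cc(O)c2C(=O)CCc2ccc(O)cc2)C(O)C(O)C1O
quercetin	Oc1cc(O)c2c(c1)oc(-c1ccc(O)c(O)c1)c(O)c2=O
rutin_aglycone	COc1cc(ccc1O)-c1oc2cc(O)cc(O)c2c(=O)c1O
naringenin	Oc1ccc(cc1)C1CC(=O)c2c(O)cc(O)cc2O1
catechin	Oc1cc(O)c2c(c1)OC(c1ccc(O)c(O)c1)C(O)C2
chlorogenic_acid	OC1CC(O)(CC(OC(=O)C=Cc2ccc(O)c(O)c2)C1O)C(=O)O
gluconic_acid	OCC(O)C(O)C(O)C(O)C(=O)O
sucrose	OCC1OC(OC2(CO)OC(CO)C(O)C2O)C(O)C(O)C1O
trehalose	OCC1OC(OC2OC(CO)C(O)C(O)C2O)C(O)C(O)C1O
glucuronide_phenyl	Oc1ccccc1OC1OC(C(O)C(O)C1O)C(=O)O
citric_acid	OC(=O)CC(O)(CC(=O)O)C(=O)O
ascorbic_acid	OCC(O)C1OC(=O)C(O)=C1O
menthol	CC(C)C1CCC(C)CC1O
camphor	CC1(C)C2CCC1(C)C(=O)C2
limonene	CC(=C)C1CCC(C)=CC1
vanillin	COc1cc(C=O)ccc1O
coumarin	O=c1ccc2ccccc2o1
umbelliferone	Oc1ccc2ccc(=O)oc2c1
indomethacin_core	COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1
nicotinamide	NC(=O)c1cccnc1
pyridoxine	Cc1ncc(CO)c(CO)c1O
riboflavin_core	Cc1cc2nc3c(=O)[nH]c(=O)n(C)c3nc2cc1C
shikimic_acid	OC1CC(=CC(O)C1O)C(=O)O
quinic_acid	OC1CC(O)(CC(O)C1O)C(=O)O
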