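# Secoiridoid/iridoid glucosides of Gentiana lutea roots
loganic_acid	CC1C(O)CC2C1C(OC=C2C(=O)O)OC3OC(CO)C(O)C(O)C3O
gentiopicroside	C=CC1C2=CCOC(=O)C2=COC1OC3OC(CO)C(O)C(O)C3O
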