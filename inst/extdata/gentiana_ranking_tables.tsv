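compound	target_name	pdb_id	conformer	v_printed	v0	vr	pct_printed
loganic_acid	Transient Receptor Potential Cation Channel Subfamily V Member 1	5irz		1.48	-7.7	-5.2	0.3
loganic_acid	Alpha-1-Acid Glycoprotein 2	3apw		1.18	-8.3	-7.0	0.1
loganic_acid	Transient Receptor Potential Cation Channel Subfamily V Member 1	5is0		1.18	-8.7	-7.3	0.3
loganic_acid	Tumor Necrosis Factor Ligand Superfamily Member 4	2hew		1.13	-9.4	-8.3	0.2
loganic_acid	Complement C3 Membrane Cofactor Protein	5fo8		1.12	-9.5	-8.5	2.6
loganic_acid	Alpha-1-Antichymotrypsin	5om2		1.12	-8.6	-7.7	1.2
loganic_acid	Tumor Necrosis Factor Ligand Superfamily Member 4	2hey		1.11	-9.2	-8.2	0.2
loganic_acid	Alpha-1-Acid Glycoprotein 2	3apu		1.10	-9.1	-8.3	0.1
loganic_acid	Prothrombin	4ax9		1.10	-7.8	-7.1	23.3
loganic_acid	Prostaglandin H2 Synthase-2	1ddx		1.09	-9.5	-8.7	0.6
gentiopicroside	Alpha-1-Acid Glycoprotein 2	3apw		1.21	-8.5	-7.0	0.1
gentiopicroside	Alpha-1-Antichymotrypsin	5om2		1.13	-8.7	-7.7	1.2
gentiopicroside	Alpha-1-Antichymotrypsin	5om3		1.10	-8.6	-7.8	1.2
gentiopicroside	Prostaglandin H2 Synthase-2	1ddx		1.09	-9.5	-8.7	1.0
gentiopicroside	Tumor Necrosis Factor Ligand Superfamily member 4	2hew		1.09	-9.0	-8.3	0.1
gentiopicroside	Alpha-1-Antichymotrypsin	5om7	a	1.08	-8.3	-7.7	1.2
gentiopicroside	Tyrosine-Protein Kinase BTK	6aub		1.07	-8.0	-7.4	3.2
gentiopicroside	Alpha-1-Antichymotrypsin	5om7	b	1.06	-8.3	-7.8	1.2
gentiopicroside	Tyrosine-Protein Kinase BTK	6bik		1.06	-8.1	-7.6	3.2
gentiopicroside	Tumor Necrosis Factor Ligand Superfamily Member 4	2hey		1.05	-8.7	-8.28	0.1
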