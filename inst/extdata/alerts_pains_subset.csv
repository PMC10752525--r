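alert_id,smarts,description
pains_quinone_p,O=C1C=CC(=O)C=C1,para-quinone
pains_quinone_o,O=C1C(=O)C=CC=C1,ortho-quinone
pains_catechol,[OX2H]c1ccccc1[OX2H],catechol (ortho-dihydroxybenzene)
pains_rhodanine,O=C1CSC(=S)N1,rhodanine core
pains_hydroxyphenyl_hydrazone,[OX2H]c1ccccc1C=NN,2-hydroxyphenyl hydrazone
pains_azo_aryl,c[NX2]=[NX2]c,aryl azo dye
pains_alkylidene_barbiturate,O=C1NC(=O)NC(=O)C1=C,alkylidene barbiturate
pains_ene_rhodanine,O=C1N=C(S)SC1=C,ene-rhodanine tautomer
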