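alert_id,smarts,description
nitro_aromatic,[c][N+](=O)[O-],aromatic nitro group (charged form)
nitro_aromatic_neutral,[c][NX3](=O)=O,aromatic nitro group (uncharged form)
acid_halide,"[CX3](=O)[Cl,Br,I]",acid halide (e.g. acid chloride)
sulfonyl_halide,"[SX4](=O)(=O)[Cl,Br]",sulfonyl halide
aldehyde,[CX3H1](=O)[#6],aldehyde
alkyl_halide,"[CX4][Cl,Br,I]",alkyl halide
michael_acceptor,[CX3]=[CX3][CX3](=O)[#6],alpha/beta-unsaturated ketone
isocyanate,[NX2]=[CX2]=[OX1],isocyanate
epoxide,C1OC1,epoxide
anhydride,[CX3](=O)[OX2][CX3](=O),acid anhydride
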