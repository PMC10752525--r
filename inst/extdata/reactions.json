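[
  {
    "reaction_id": "amide",
    "transform": "[NX3;H2,H1;!$(NC=O):3].[CX3:1](=[OX1:2])[OX2H1]>>[C:1](=[O:2])[N:3]",
    "role_a": "amine",
    "role_b": "acid",
    "complexity": "simple",
    "note": "amide bond formation: carboxylic acid + primary/secondary amine"
  },
  {
    "reaction_id": "sulfonamide",
    "transform": "[SX4:1](=[OX1:2])(=[OX1:3])[Cl].[NX3;H2,H1;!$(NC=O):4]>>[S:1](=[O:2])(=[O:3])[N:4]",
    "role_a": "sulfonyl_chloride",
    "role_b": "amine",
    "complexity": "simple",
    "note": "sulfonamide formation: sulfonyl chloride + amine"
  },
  {
    "reaction_id": "reductive_amination",
    "transform": "[CX3H1:1]=[OX1].[NX3;H2,H1;!$(NC=O):2]>>[CH2:1][N:2]",
    "role_a": "aldehyde",
    "role_b": "amine",
    "complexity": "complex",
    "note": "reductive amination: aldehyde + amine -> secondary/tertiary amine"
  },
  {
    "reaction_id": "n_arylation",
    "transform": "[c:1][Br].[NX3;H2,H1;!$(NC=O):2]>>[c:1][N:2]",
    "role_a": "aryl_bromide",
    "role_b": "amine",
    "complexity": "complex",
    "note": "Buchwald-type N-arylation: aryl bromide + amine"
  }
]
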