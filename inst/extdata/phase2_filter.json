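{
  "name": "phase2-filter-config",
  "description": "Configuration of the phase II substrate pre-filter and featurizer: excluded chemical classes, the maximum molecular weight, the 64-entry conjugatable-motif gate (a documented stand-in list covering groups attacked by UGT/SULT/MT/NAT/GST/amino-acid transferases), and the 32-descriptor feature schema (9 constitutional descriptors + 23 binary structural flags).",
  "max_mass": 900,
  "excluded_classes": [
    {"name": "ether lipids", "smarts": "[CX4][CH2X4][OX2][CH2X4][CHX4]([OX2])[CH2X4][OX2]P"},
    {"name": "glycerolipids", "smarts": "[#6][CX3](=O)[OX2][CH2X4][CHX4][CH2X4][OX2][CX3](=O)[#6]"},
    {"name": "glycerophospholipids", "smarts": "[OX2][CH2X4][CHX4]([OX2])[CH2X4][OX2]P(=O)"},
    {"name": "sphingolipids", "smarts": "[#6][CX4H]([OX2H])[CX4H]([NX3])[CX4H2][OX2H1,OX2]"},
    {"name": "acyl-CoA conjugates", "smarts": "C(=O)SCCNC(=O)CCNC(=O)"}
  ],
  "motifs": [
    {"name": "phenol", "smarts": "[OX2H][c]"},
    {"name": "primary aliphatic alcohol", "smarts": "[OX2H][CX4H2]"},
    {"name": "secondary aliphatic alcohol", "smarts": "[OX2H][CX4H1]"},
    {"name": "tertiary aliphatic alcohol", "smarts": "[OX2H][CX4H0]"},
    {"name": "benzylic alcohol", "smarts": "[OX2H][CX4][c]"},
    {"name": "allylic alcohol", "smarts": "[OX2H][CX4][CX3]=[CX3]"},
    {"name": "catechol", "smarts": "[OX2H]c1ccccc1[OX2H]"},
    {"name": "resorcinol", "smarts": "[OX2H]c1cccc([OX2H])c1"},
    {"name": "hydroquinone", "smarts": "[OX2H]c1ccc([OX2H])cc1"},
    {"name": "carboxylic acid", "smarts": "[CX3](=O)[OX2H1]"},
    {"name": "carboxylate", "smarts": "[CX3](=O)[OX1-]"},
    {"name": "alpha-hydroxy acid", "smarts": "[OX2H][CX4][CX3](=O)[OX2H1]"},
    {"name": "primary aliphatic amine", "smarts": "[NX3H2][CX4]"},
    {"name": "primary aromatic amine", "smarts": "[NX3H2][c]"},
    {"name": "secondary aliphatic amine", "smarts": "[NX3H1]([CX4])[CX4]"},
    {"name": "secondary aromatic amine", "smarts": "[NX3H1]([c])[#6]"},
    {"name": "tertiary aliphatic amine", "smarts": "[NX3H0]([CX4])([CX4])[CX4]"},
    {"name": "hydrazine", "smarts": "[NX3][NX3]"},
    {"name": "hydroxylamine", "smarts": "[NX3][OX2H]"},
    {"name": "thiol", "smarts": "[SX2H][#6]"},
    {"name": "thiophenol", "smarts": "[SX2H][c]"},
    {"name": "carboxamide N-H", "smarts": "[NX3H1,NX3H2][CX3]=O"},
    {"name": "sulfonamide N-H", "smarts": "[NX3H1,NX3H2]S(=O)=O"},
    {"name": "imidazole N-H", "smarts": "[nX3H1]1cncc1"},
    {"name": "pyrrole N-H", "smarts": "[nX3H1]1cccc1"},
    {"name": "indole N-H", "smarts": "[nX3H1]1ccc2ccccc21"},
    {"name": "pyrazole N-H", "smarts": "[nX3H1]1nccc1"},
    {"name": "triazole N-H", "smarts": "[nX3H1]1nncc1"},
    {"name": "tetrazole N-H", "smarts": "[nX3H1]1nnnc1"},
    {"name": "pyridine nitrogen", "smarts": "[nX2]1ccccc1"},
    {"name": "piperidine nitrogen", "smarts": "[NX3;R]1[CX4][CX4][CX4][CX4][CX4]1"},
    {"name": "piperazine nitrogen", "smarts": "[NX3;R]1[CX4][CX4][NX3;R][CX4][CX4]1"},
    {"name": "morpholine nitrogen", "smarts": "[NX3;R]1[CX4][CX4][OX2;R][CX4][CX4]1"},
    {"name": "pyrrolidine nitrogen", "smarts": "[NX3;R]1[CX4][CX4][CX4][CX4]1"},
    {"name": "aldehyde", "smarts": "[CX3H1]=O"},
    {"name": "ketone", "smarts": "[#6][CX3](=O)[#6]"},
    {"name": "epoxide", "smarts": "C1OC1"},
    {"name": "arene oxide", "smarts": "C1OC1c"},
    {"name": "olefin", "smarts": "[CX3]=[CX3]"},
    {"name": "styrene", "smarts": "[CX3]=[CX3][c]"},
    {"name": "quinone", "smarts": "O=C1C=CC(=O)C=C1"},
    {"name": "quinone imine", "smarts": "O=C1C=CC(=N)C=C1"},
    {"name": "nitroarene", "smarts": "[c][N+](=O)[O-]"},
    {"name": "nitrosamine", "smarts": "[NX3][NX2]=O"},
    {"name": "aryl halide", "smarts": "[c][F,Cl,Br,I]"},
    {"name": "alkyl halide", "smarts": "[CX4][Cl,Br,I]"},
    {"name": "benzylic halide", "smarts": "[c][CX4][Cl,Br,I]"},
    {"name": "oxime", "smarts": "[CX3]=[NX2][OX2H]"},
    {"name": "enol", "smarts": "[OX2H][CX3]=[CX3]"},
    {"name": "phosphate ester", "smarts": "P(=O)([OX2])[OX2]"},
    {"name": "phosphorothioate", "smarts": "P(=S)([OX2])[OX2]"},
    {"name": "glycoside aglycone oxygen", "smarts": "[c][OX2][CX4]1[OX2][CX4][CX4][CX4][CX4]1"},
    {"name": "methoxyarene", "smarts": "[CH3][OX2][c]"},
    {"name": "carbamate", "smarts": "[NX3][CX3](=O)[OX2]"},
    {"name": "urea", "smarts": "[NX3][CX3](=O)[NX3]"},
    {"name": "guanidine", "smarts": "[NX3][CX3](=[NX2,NX3+])[NX3]"},
    {"name": "amidine", "smarts": "[NX3][CX3]=[NX2]"},
    {"name": "sulfoxide", "smarts": "[#6][SX3](=O)[#6]"},
    {"name": "sulfone", "smarts": "[#6]S(=O)(=O)[#6]"},
    {"name": "aryl carboxylic acid", "smarts": "[c][CX3](=O)[OX2H1]"},
    {"name": "alpha-amino acid", "smarts": "[NX3H2][CX4][CX3](=O)[OX2H1,OX1-]"},
    {"name": "flavan-3-ol core", "smarts": "OC1Cc2ccccc2OC1c1ccccc1"},
    {"name": "chromen-4-one core", "smarts": "c1ccc2occc(=O)c2c1"},
    {"name": "steroid 3-hydroxyl", "smarts": "[OX2H]C1CCC2(C)CCCC2C1"}
  ],
  "constitutional_descriptors": [
    "exact_mass", "alogp", "hbond_donors", "hbond_acceptors",
    "rotatable_bonds", "heavy_atoms", "ring_count", "aromatic_ring_count",
    "tpsa"
  ],
  "structural_features": [
    {"name": "amine", "smarts": "[NX3+0,NX4+;!$([N]~[!#6]);!$([N]*~[#7,#8,#15,#16])]"},
    {"name": "carboxyl", "smarts": "[#8;A;X2H1,X1-][#6]([#6,#1;A])=O"},
    {"name": "phenol", "smarts": "[OX2H][c]"},
    {"name": "aliphatic_hydroxyl", "smarts": "[OX2H][CX4]"},
    {"name": "catechol", "smarts": "[OX2H]c1ccccc1[OX2H]"},
    {"name": "thiol", "smarts": "[SX2H]"},
    {"name": "primary_aromatic_amine", "smarts": "[NX3H2][c]"},
    {"name": "secondary_amine", "smarts": "[NX3H1]([#6])[#6]"},
    {"name": "carboxamide", "smarts": "[NX3][CX3]=O"},
    {"name": "ester", "smarts": "[#6][CX3](=O)[OX2][#6]"},
    {"name": "aryl_ether", "smarts": "[c][OX2][#6]"},
    {"name": "n_heterocycle", "smarts": "[n,N;R]"},
    {"name": "sulfonamide", "smarts": "[NX3]S(=O)=O"},
    {"name": "halogen", "smarts": "[F,Cl,Br,I]"},
    {"name": "nitro", "smarts": "[N+](=O)[O-]"},
    {"name": "ketone", "smarts": "[#6][CX3](=O)[#6]"},
    {"name": "aldehyde", "smarts": "[CX3H1]=O"},
    {"name": "olefin", "smarts": "[CX3]=[CX3]"},
    {"name": "aromatic_ring", "smarts": "a1aaaaa1"},
    {"name": "guanidine", "smarts": "[NX3][CX3](=[NX2,NX3+])[NX3]"},
    {"name": "imidazole", "smarts": "c1cnc[nX3H1,n]1"},
    {"name": "indole", "smarts": "c1ccc2c(c1)cc[nH]2"},
    {"name": "pyridine", "smarts": "[nX2]1ccccc1"}
  ]
}
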