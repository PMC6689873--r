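{
  "name": "fixture-env",
  "version": 1,
  "description": "Fixture rule pack for the environmental microbial biosystem (aerobic and anaerobic consensus rules, each assigned to a single unspecified enzyme).",
  "enzymes": [
    {"id": "ENV_UNSPEC", "name": "Unspecified environmental microbial enzyme", "family": "Unspecified"}
  ],
  "rules": [
    {
      "id": "env_pte_hydrolysis",
      "name": "Phosphorothioate triester hydrolytic dealkylation",
      "smirks": "[P:1](=[S:2])[O:3][#6:4]>>[P:1](=[S:2])O.[O:3][#6:4]",
      "enzymes": ["ENV_UNSPEC"],
      "biosystems": ["env"],
      "modules": ["envmicro"],
      "reaction_type": "Hydrolysis",
      "priority_tier": 0,
      "mass_delta": "+H2O"
    },
    {
      "id": "env_desulfurization",
      "name": "Oxidative desulfurization (P=S to P=O)",
      "smirks": "[P:1]=[S:2]>>[P:1]=O",
      "enzymes": ["ENV_UNSPEC"],
      "biosystems": ["env"],
      "modules": ["envmicro"],
      "reaction_type": "Oxidation",
      "priority_tier": 0,
      "mass_delta": "+O-S"
    },
    {
      "id": "env_nitro_reduction",
      "name": "Aromatic nitro reduction",
      "smirks": "[c:1][N+:2](=[O:3])[O-:4]>>[c:1][N:2]",
      "enzymes": ["ENV_UNSPEC"],
      "biosystems": ["env"],
      "modules": ["envmicro"],
      "reaction_type": "Reduction",
      "priority_tier": 0,
      "mass_delta": "+H2-O2"
    },
    {
      "id": "env_amide_hydrolysis",
      "name": "Carboxamide hydrolysis",
      "smirks": "[C:1](=[O:2])[N;X3:3]>>[C:1](=[O:2])O.[N:3]",
      "enzymes": ["ENV_UNSPEC"],
      "biosystems": ["env"],
      "modules": ["envmicro"],
      "reaction_type": "Hydrolysis",
      "priority_tier": 0,
      "mass_delta": "+H2O"
    }
  ],
  "precedence": [
    {"dominant": "env_nitro_reduction", "suppressed": "env_amide_hydrolysis", "biosystem": "env"}
  ],
  "pathways": [],
  "records": []
}
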