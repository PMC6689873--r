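{
  "name": "cyp450-prefilter-config",
  "description": "Heuristic exclusions for the CYP450 substrate pre-filter: inorganic input is rejected programmatically; the classes below are excluded by structure search. The per-isozyme reactivity classifier is pluggable; the default is permissive.",
  "isozymes": ["1A2", "2A6", "2B6", "2C8", "2C9", "2C18/2C19", "2D6", "2E1", "3A4"],
  "excluded_classes": [
    {"name": "glycerolipids", "smarts": "[#6][CX3](=O)[OX2][CH2X4][CHX4][CH2X4][OX2][CX3](=O)[#6]"},
    {"name": "glycerophospholipids", "smarts": "[OX2][CH2X4][CHX4]([OX2])[CH2X4][OX2]P(=O)"},
    {"name": "ether glycerophospholipids", "smarts": "[CX4][CH2X4][OX2][CH2X4][CHX4]([OX2])[CH2X4][OX2]P"}
  ]
}
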