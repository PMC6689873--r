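{
  "description": "Offline synonym table for fixture compounds, keyed by InChIKey.",
  "synonyms": {
    "UHOVQNZJYSORNB-UHFFFAOYSA-N": ["benzene"],
    "ISWSIDIOOBJBQZ-UHFFFAOYSA-N": ["phenol"],
    "RZVAJINKPMORJF-UHFFFAOYSA-N": ["acetaminophen", "paracetamol"],
    "URNSECGXFRDEDC-UHFFFAOYSA-N": ["NAPQI", "N-acetyl-p-benzoquinone imine"],
    "BSYNRYMUTXBXSQ-UHFFFAOYSA-N": ["aspirin", "acetylsalicylic acid"],
    "YGSDEFSMJLZEOE-UHFFFAOYSA-N": ["salicylic acid"],
    "QTBSBXVTEAMEQO-UHFFFAOYSA-N": ["acetic acid"],
    "SNICXCGAKADSCV-UHFFFAOYSA-N": ["nicotine"],
    "MYKUKUCHPMASKF-UHFFFAOYSA-N": ["nornicotine"],
    "RYYVLZVUVIJVGH-UHFFFAOYSA-N": ["caffeine"],
    "PFTAWBLQPZVEMU-UHFFFAOYSA-N": ["epicatechin", "(-)-epicatechin"],
    "LDAMBCHZYBPAPF-UHFFFAOYSA-N": ["kaempferol 7,4'-dimethyl ether 3-glucoside"],
    "NABCJYMXPFVERX-UHFFFAOYSA-N": ["methyl parathion analog (fixture)"],
    "WVHAUDNUGBNUDZ-UHFFFAOYSA-N": ["phenyl glucuronide"],
    "WSFSSNUMVMOOMR-UHFFFAOYSA-N": ["formaldehyde"],
    "OKKJLVBELUTLKV-UHFFFAOYSA-N": ["methanol"],
    "LFQSCWFLJHTTHZ-UHFFFAOYSA-N": ["ethanol"],
    "PAYRUJLWNCNPSJ-UHFFFAOYSA-N": ["aniline"],
    "KILNVBDSWZSGLL-UHFFFAOYSA-N": ["dipalmitoyl glycerophosphocholine"],
    "QIJYAMAPPUXBSC-UHFFFAOYSA-N": ["dibutyryl glycerophosphocholine (fixture)"]
  }
}
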