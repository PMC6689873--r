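# Independent reaction oracle: RDKit (via the system python) applies the
# same SMIRKS at every site and reports product InChIKeys. Used on a small
# set of (molecule, rule) pairs to cross-check the package's own transform
# engine. Fragments below 2 heavy atoms are filtered to match the engine's
# co-product policy.

rdkitReactionProducts <- function(smiles, smirks) {
  script <- '
import sys, json
from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem
RDLogger.DisableLog("rdApp.*")
data = json.load(sys.stdin)
mol = Chem.MolFromSmiles(data["smiles"])
mol = Chem.AddHs(mol)
rxn = AllChem.ReactionFromSmarts(data["smirks"])
keys = set()
for prods in rxn.RunReactants((mol,)):
    for p in prods:
        try:
            p = Chem.RemoveHs(p)
            Chem.SanitizeMol(p)
        except Exception:
            continue
        if sum(1 for a in p.GetAtoms() if a.GetAtomicNum() > 1) < 2:
            continue
        ik = Chem.MolToInchiKey(p)
        if ik:
            keys.add(ik)
json.dump(sorted(keys), sys.stdout)
'
  inp <- jsonlite::toJSON(list(smiles = smiles, smirks = smirks),
                          auto_unbox = TRUE)
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  input = as.character(inp),
                                  stdout = TRUE, stderr = FALSE))
  jsonlite::fromJSON(paste(out, collapse = ""))
}
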