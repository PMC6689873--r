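# MetabolizR

Rule-based prediction of small-molecule metabolism, and MS-driven
metabolite identification, in R.

## The problem

Xenobiotics — drugs, pesticides, food phytochemicals, contaminants — are
chemically transformed by host enzymes (CYP450-mediated phase I
oxidation, phase II conjugation, promiscuous EC-classified enzymes), by
the gut microbiome, and, once excreted, by environmental microbes.
Knowing which metabolites to expect is central to ADMET profiling,
metabolomics and exposomics: most features in an untargeted LC–MS run of
a treated organism are metabolites of something, not the parent
compound. MetabolizR is for scientists who need those candidate
structures: it enumerates metabolites over explicit, inspectable
reaction knowledge and then matches predicted metabolites against
experimental neutral masses or molecular formulas.

## The model

The engine is a knowledge-based production system over three components:

* **A reaction knowledgebase** (a JSON *rule pack*): biotransformation
  rules encoded as atom-mapped SMIRKS transforms, with applicability
  constraints encoded *separately* — required/forbidden SMARTS patterns
  and property predicates (e.g. monoisotopic mass ≤ 900 Da) — plus
  enzymes, biosystems (`human`, `gut`, `env`), chemical class–pathway
  associations, precedence relations, and curated example reactions.
* **A reasoning engine.** For a substrate *M* and rule *r*, *r* fires iff
  its reactant pattern matches at least one site of *M* and all
  constraints hold. The transform is applied at **every** matching site;
  each site's full product set (including small co-products such as
  formaldehyde) is standardized and deduplicated by InChIKey. *Relative
  reasoning* implements rule precedence: if a dominant rule fires, all
  candidates of the suppressed rule are discarded (e.g. polyphenol
  glucosides are deconjugated by gut glycosidases before anything else,
  and flavonoid O-demethylation prefers the C-7 position). Multi-step
  metabolism is a breadth-first *metabolic tree*: nodes are metabolites
  keyed by InChIKey, edges carry (rule, enzymes, biosystem, step), and
  convergent products gain extra parent edges rather than duplicate
  nodes. In the current packs all rules share one likelihood tier, so
  absolute reasoning is a no-op hook.
* **Substrate filters.** The CYP450 module first consults a heuristic
  pre-filter (inorganics and glycero-/glycerophospholipids are out of
  scope) plus a pluggable per-isozyme reactivity classifier over the
  nine major isozymes (permissive by default). The phase II module uses
  a rule-based pre-filter (five excluded lipid/CoA classes, mass ≤ 900
  Da, presence of ≥ 1 of 64 conjugatable motifs) and an optional random
  forest over 32 descriptors (9 constitutional + 23 binary structural
  flags, including the canonical amine and carboxyl SMARTS).

Seven transformer options are exposed: `ecbased`, `cyp450`, `phaseII`,
`hgut`, `envmicro`, plus the human super-transformers `allHuman` (union
of the four human modules at every step) and `superbio` (a fixed ordered
12-slot pipeline starting with hydrolysis and ending with one
conjugation step).

The metabolite identification tool converts [M+H]+ ions to neutral
masses (m/z − 1.00727 Da), expands the metabolic tree step by step, and
reports every metabolite matching each still-unmatched target mass
(inclusive ± tolerance, default 0.01 Da) or formula, together with the
reaction/enzyme pathway leading to it; expansion stops early once every
target has a match.

Molecule handling (SMILES/InChI/MOL/SDF parsing, canonicalization,
InChI/InChIKey, logP, constraint SMARTS) is backed by OpenBabel through
ChemmineR/ChemmineOB; the SMIRKS transform engine, matcher and the
reasoning layer are implemented in the package itself.

## Worked example

```r
library(MetabolizR)

apap <- molecule("CC(=O)Nc1ccc(O)cc1", label = "acetaminophen")
tree <- runModule(apap, "cyp450", nsteps = 1)
annotateTree(tree)[, c("MetaboliteID", "MolecularFormula",
                       "MonoisotopicMass", "ReactionType", "Synonyms")]
#>   MetaboliteID MolecularFormula MonoisotopicMass
#> 1      BTM0000          C8H9NO2         151.0633
#> 2      BTM0001          C8H9NO3         167.0582
#> 3      BTM0002          C8H9NO3         167.0582
#> 4      BTM0003          C8H7NO2         149.0477
#>                                     ReactionType                             Synonyms
#> 1                                                        acetaminophen; paracetamol
#> 2                         Aromatic hydroxylation
#> 3                         Aromatic hydroxylation
#> 4 Oxidation of 4-hydroxyanilide to quinone imine NAPQI; N-acetyl-p-benzoquinone imine
```

One step of CYP450 metabolism predicts the two ring-hydroxylated
regioisomers (+15.9949 Da each) and the reactive quinone imine NAPQI
(−2 H), each row carrying identifiers, masses and provenance. Trees are
written to SDF/CSV/JSON with `writeStructures()`.

Identification from an MS ion: the epicatechin [M+H]+ ion at m/z
467.11840 gives a neutral mass of 466.11113 Da, and one step of
`allHuman` metabolism explains it as a glucuronide:

```r
epi <- molecule("Oc1cc(O)c2CC(O)C(Oc2c1)c1ccc(O)c(O)c1")
identifyMetabolites(epi, masses = neutralMassFromIon(467.11840),
                    tolerance = 0.01, steps = 1, scope = "allHuman")
#> Metabolite identification (allHuman, tolerance 0.01 Da)
#>   query: Oc1cc2OC(c3ccc(c(c3)O)O)C(Cc2c(c1)O)O
#>   mass 466.11113         5 match(es)
```

The five matches are the five regioisomeric epicatechin
O-glucuronides (C21H22O12); each match records its pathway
(`O-glucuronidation [UGT1A1; UGT2B7]`). `writeIdentification()` saves
them as an annotated SDF.

A command-line wrapper ships in `inst/exec/metabolizr`
(`metabolizr predict -i <structure> -m cyp450 -s 1 -o out.sdf`;
`metabolizr identify -i <structure> --masses masses.txt -o out.sdf`).

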