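---
title: "Predicting xenobiotic metabolism with MetabolizR: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting xenobiotic metabolism with MetabolizR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the reaction model and its assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic data emulate (and
do not), the numerical conventions, and the design decisions that were
genuinely open.

## The reaction model

A *biotransformation rule* is an atom-mapped SMIRKS transform together
with separately encoded applicability constraints. The separation is
deliberate: substrate-specificity knowledge (e.g. "UGTs do not act on
molecules above ~900 Da", "do not re-hydroxylate an already dioxygenated
ring") is awkward or impossible to express inside a single SMIRKS
string, and separating it keeps both parts legible and independently
editable. A rule fires on a standardized molecule when

1. its reactant pattern embeds at least once into the molecular graph,
2. every `smarts_required` pattern matches, no `smarts_forbidden`
   pattern matches, and
3. every property predicate (monoisotopic mass, ALogP, heavy-atom
   count) holds.

Constraints are conjunctive across a rule's list; alternatives are
expressed by splitting a generic reaction into sibling sub-rules (the
two gut O-demethylation rules are an example). Constraint matching is
molecule-level, not site-level: a forbidden pattern anywhere in the
molecule vetoes the rule. This is coarser than site-level vetoes but
far more predictable, and the packaged rules are written with that
semantics in mind.

Application is exhaustive over sites: the transform is applied at every
embedding of the reactant pattern, each application keeps its *complete*
product set (so a three-site phosphotriester cleavage yields six
products — an acid and an alcohol per site), fragments below two heavy
atoms are discarded as leaving groups, products are standardized, and
the set is deduplicated by full InChIKey. Products identical to the
substrate are dropped. Symmetry is handled by the deduplication, not by
symmetry perception: benzene has six equivalent C–H sites but exactly
one hydroxylation product.

*Relative reasoning* ranks competing reactions qualitatively. A
precedence pair (dominant > suppressed) removes every candidate of the
suppressed rule whenever the dominant rule itself fires on the same
substrate at the same step. Chains are resolved by processing the
precedence graph restricted to the applicable rules in topological
order; a cycle among co-applicable rules raises an error rather than an
arbitrary tie-break. *Absolute reasoning* — thresholding per-rule
occurrence scores — is present only as a hook: every packaged rule sits
in priority tier 0 because no defensible rule-specific likelihoods ship
with the fixture packs; the loader accepts non-uniform tiers.

Metabolic trees are breadth-first: round *k* expands only molecules
first produced in round *k − 1*; a molecule is never re-expanded
(visited set on InChIKey), and a product that converges onto an
existing node adds a parent edge instead of a node. Re-expansion is
*once globally*, not once per parent: the alternative would multiply
work without changing the node set, because expansion depends only on
the molecule. The step cap (default hard cap 12) plus the visited set
guarantee termination even for mutually inverse rule pairs
(methylation/demethylation).

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `nsteps` per module | 1 | reaction steps | single-step metabolism is the common unit of evidence in metabolite studies |
| hard step cap | 12 | steps | matches the depth of the ordered human pipeline |
| mass tolerance (identification) | 0.01 | Da | appropriate for high-resolution QToF neutral masses |
| identification steps | 1 | steps | conjugates of the parent dominate first-pass urine/plasma data |
| [M+H]+ offset | 1.00727 | Da | proton mass on the monoisotopic scale |
| phase II mass gate | 900 | Da | substrates above this are not observed conjugation substrates |
| phase II motif gate | 64 motifs | — | conjugation requires an attackable functional group |
| RF trees / CV folds | 200 / 10 | — | stable out-of-fold estimates at harness scale |

## Standardization conventions

Input structures (SMILES, InChI, MOL, single- or multi-record SDF) are
canonicalized with OpenBabel. Multi-fragment input is rejected outright
as a mixture/salt — no counter-ion stripping, because silently editing
the user's structure invites misattributed predictions. Carbon-free
input is rejected as inorganic. Charges are neutralized *toward net
zero*: internally balanced charge-separated groups (nitro, N-oxides,
zwitterions such as phosphocholines) are left as written, which
reproduces the conventional nitro exception as a consequence of one
policy instead of a special case; the exception patterns are
configurable. Stereochemistry supplied by the user is preserved on the
standardized molecule, but reaction products are emitted without stereo
annotations: the transform engine is constitutional, rules never invent
stereocenters, and identity, formulas and masses are unaffected.
Deduplication identity everywhere is the full standard InChIKey — it is
deterministic and independent of the toolkit's canonical atom order.

## The fixture rule packs

The packaged human/gut pack (17 rules) and environmental pack (4 rules)
are *fixtures*: a small, fully exercised subset of the rule-pack format,
not a comprehensive knowledgebase. Every documented engine behaviour is
reachable offline: multi-site application, co-product retention,
deconjugation-first precedence, the C-7 regiopreference of flavonoid
O-demethylation, chemical class–pathway gating (glycerophospholipids
route only through their pathway and see no CYP450/UGT chemistry), and
the quinone-imine oxidation that turns acetaminophen into NAPQI.

Two pack-level choices bound the enumeration chemically rather than
computationally. Aromatic hydroxylation is constrained to rings that do
not already carry two oxygen substituents (highly oxygenated rings are
poorer CYP substrates and successive oxidations rapidly lose
plausibility), and O-glucuronidation/O-sulfation do not re-conjugate a
molecule that already carries the same conjugate (multi-glucuronides of
one scaffold are rarely observed; mixed conjugates — e.g. a glucuronide
of a sulfate — remain reachable). Without these constraints the
transitive closure of "add a hydroxyl anywhere, then conjugate every
hydroxyl" grows combinatorially while describing chemistry nobody
observes.

## Filters

The CYP450 pre-filter implements an organic-substructure policy: a
molecule with no C–H or C–C bond (CO~2~, carbonates) is out of scope, as
are configured lipid classes. Per-isozyme reactivity over the nine
major isozymes (1A2, 2A6, 2B6, 2C8, 2C9, 2C18/2C19, 2D6, 2E1, 3A4) is
delegated to a pluggable classifier; the default is permissive — the
package deliberately makes no claim about trained per-isozyme accuracy.

The phase II featurizer emits exactly 32 descriptors: nine
constitutional values (monoisotopic mass, ALogP, H-bond donors and
acceptors, rotatable bonds, heavy atoms, ring count, aromatic ring
count, TPSA) and 23 binary structural flags. The amine and carboxyl
flags use the canonical published SMARTS for those groups; the
remaining 21 flags and the 64-entry conjugatable-motif gate are this
package's own curated stand-ins covering the groups attacked by the six
conjugating enzyme families (hydroxyls, phenols, catechols, amines,
carboxyls, thiols, N-heterocycles, …). Ring counts are cyclomatic
numbers (bonds − atoms + components), so fused-system counts follow the
SSSR convention. An information-gain feature-selection step is left out
of the default pipeline: at fixture scale it only adds variance.

## Synthetic data: what it shows and what it cannot

The synthetic phase II training set pairs decorated scaffolds that carry
conjugatable motifs by construction (label 1) against alkanes, aliphatic
ethers and alkylbenzenes that carry none (label 0). It emulates the
*shape* of a curated substrate/non-substrate collection — mixed
aromatic/aliphatic scaffolds, realistic size range, class imbalance near
1:1 — but it is separable by design in the featurizer's own flag space.
Harness scores on it (cross-validated weighted F1, ROC area) therefore
validate the plumbing: featurization, fold handling, thresholding, and
the null behaviour under label permutation (ROC ≈ 0.5). They say
nothing about accuracy on real substrate data, which is *not* separable;
the package accordingly reports no real-data F1/ROC claims. The same
generator provides the seeded random molecules used by the round-trip
and monotonicity property tests.

## Numerical and determinism conventions

Monoisotopic masses use most-abundant-isotope values to ≥ 6 decimals and
are reported to 5 decimals; the formula-derived mass and the atomwise
structure mass agree to 10^−4^ Da by construction. The identification
tolerance is inclusive (≤) and absolute in Da; a ppm mode is a flagged
future extension. Formula matching compares neutral Hill formulas
exactly. All collections are sorted — rules by id, products and nodes by
InChIKey, edges by (step, rule id, child, parent) — so identical inputs
produce byte-identical SDF/CSV/JSON output; metabolite IDs (`BTM` +
zero-padded ordinal) are assigned by sorted traversal and are stable
across runs. Degenerate inputs have defined behaviour: zero steps gives
a root-only tree, a molecule matching no rule gives a root-only tree, an
unmatched target gives an empty match list, and per-record parse
failures in a batch are reported without aborting the batch.

## Open design choices

* **superbio slot order.** Only the endpoints of the ordered human
  pipeline are externally fixed (hydrolysis first, conjugation last).
  The packaged order is: EC hydrolysis; gut deconjugation; gut
  reduction/ring-cleavage; EC oxidation; CYP450; EC; CYP450; gut; EC;
  then methylation/acetylation, sulfation, glucuronidation. Gut
  deconjugation runs early because absorbed polyphenol conjugates are
  deconjugated before any other transformation; the order is a config
  default, not a scientific claim. Conjugation products are terminal —
  one conjugation step is usually enough to render a metabolite
  excretable, so the pipeline does not stack conjugates.
* **Identification scope of the parent.** The query molecule itself is
  never reported as a match: reporting the input back as an
  "identification" at step 0 carries no information.
* **Convergent metabolites** are expanded once globally (see above).
* **Mass-balance declarations.** Every rule declares its stoichiometric
  formula delta (e.g. +C6H8O6 for glucuronidation, +SO3 for sulfation,
  +O for O-demethylation counting the formaldehyde co-product); the
  test suite verifies each rule against it over all fixture substrates,
  counting every fragment including sub-threshold leaving groups.

## Problem sizes

The shipped tests and the acceptance script run the engine at fixture
scale: ~20 catalog molecules across both packs, 100 seeded random
molecules for the monotonicity property, a 100-molecule synthetic set
with 10-fold cross-validation for the ML harness, and identification
queries with 1–2 steps. These sizes were chosen because they already
exercise every code path; the engine itself is bounded by rule count ×
tree size, and the fixture packs keep trees in the tens-to-hundreds of
nodes.

## Known limitations

* The packs are fixtures; coverage of real metabolic space requires a
  full-scale rule set, which the format (but not the content) supports.
* No site-of-metabolism probabilities or rule-specific likelihoods: all
  regioisomers of an applicable reaction are reported as peers.
* Products lose stereochemical annotation.
* Only the [M+H]+ adduct is interpreted; isotope patterns and MS/MS
  fragments are out of scope and better served by dedicated tools.
* The default CYP450 reactivity classifier is permissive; plugging a
  trained classifier is supported but none is shipped.
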