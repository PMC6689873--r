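# The SMARTS-subset matcher and the SMIRKS transform engine, checked
# against two independent oracles: OpenBabel's full SMARTS engine for
# embedding counts, and RDKit for reaction products.

test_that("embedding counts agree with OpenBabel across a pattern battery", {
  mols <- c("c1ccccc1", "Oc1ccccc1", "CC(=O)Nc1ccc(O)cc1",
            "CC(=O)Oc1ccccc1C(=O)O", "CN1CCCC1c1cccnc1",
            "CCOP(=S)(OC)Oc1ccc(cc1)[N+](=O)[O-]",
            "Oc1cc(O)c2CC(O)C(Oc2c1)c1ccc(O)c(O)c1",
            "C1(c2ccccc2)CO1", "CC", "Oc1ccccc1O",
            "COc1ccc(cc1)c1oc2cc(OC)cc(O)c2c(=O)c1OC1OC(CO)C(O)C(O)C1O")
  pats <- c("[c;H1]", "[OX2;H1]", "[c][OX2H]", "[C;H2;X4][c]",
            "[N;X3]([C])([C])[C;H3]", "[C](=[O])[O][#6]", "[C]1[O][C]1",
            "[O;H1][c][c][O;H1]", "[N;H2;X3][c]", "[P](=[S])([O][c])",
            "[C;H3][O][c]", "[c][O][C]1[O][C][C][C][C]1", "[P]=[S]",
            "[c][N+](=[O])[O-]", "[N;X3;R]", "[*]~[*]")
  for (smi in mols) {
    can <- MetabolizR:::obCanonicalSmiles(smi)
    g <- MetabolizR:::parseSmilesGraph(can)
    ctx <- MetabolizR:::mgMatchContext(g)
    ref <- ChemmineOB::forEachMol("SMILES", paste0(smi, "\n"), identity)
    for (p in pats) {
      mine <- length(MetabolizR:::matchSmarts(g, p, ctx))
      ob <- ChemmineOB::smartsSearch_OB(ref, p, uniqueMatches = FALSE)
      expect_identical(as.integer(mine), as.integer(ob),
                       info = paste(smi, p))
    }
  }
})

test_that("SMIRKS compilation enforces atom-map discipline", {
  expect_error(MetabolizR:::compileSmirks("[c;H1:1]>[c:1]O"),
               class = "RuleCompileError")
  expect_error(MetabolizR:::compileSmirks("[cH1][cH1:2]>>[c:2]O"),
               class = "RuleCompileError")   # unmapped reactant atom
  expect_error(MetabolizR:::compileSmirks("[c;H1:1]>>[c:1][*]"),
               class = "RuleCompileError")   # wildcard new atom
  r <- MetabolizR:::compileSmirks("[c;H1:1]>>[c:1]O")
  expect_s3_class(r, "smirksRule")
})

test_that("reaction products match the RDKit oracle on fixture chemistry", {
  kb <- humanKb(); kbe <- envKb()
  pairs <- list(
    list("benzene", "arom_hydroxylation"),
    list("phenol", "o_glucuronidation"),
    list("aspirin", "ester_hydrolysis"),
    list("nicotine", "tert_amine_n_demethylation"),
    list("triester", "env_pte_hydrolysis"),
    list("acetaminophen", "quinoneimine_oxidation"),
    list("styrene_oxide", "epoxide_hydrolysis"),
    list("catechol", "catechol_o_methylation"))
  for (p in pairs) {
    mol <- fixtureMol(p[[1]])
    rule <- kbRules(kb)[[p[[2]]]] %||% kbRules(kbe)[[p[[2]]]]
    mine <- bruteForceProducts(mol, rule)
    oracle <- rdkitReactionProducts(smiles(mol), rule@smirks)
    expect_identical(sort(mine), sort(oracle),
                     info = paste(p[[1]], p[[2]]))
  }
})

test_that("every (fixture molecule x applicable rule) pair satisfies oracle equivalence", {
  ## applyRule must equal the brute-force enumeration + InChIKey dedup
  fx <- quietly_(generateFixtures(seed = 42, nRandom = 0))
  kb <- humanKb(); kbe <- envKb()
  expect_gt(length(fx$manifests), 20L)
  for (key in names(fx$manifests)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    rowi <- match(parts[1], fx$catalog$name)
    mol <- standardizeMolecule(fx$catalog$smiles[rowi])
    rule <- kbRules(kb)[[parts[2]]] %||% kbRules(kbe)[[parts[2]]]
    bt <- quietly_(applyRule(mol, rule))
    got <- if (is.null(bt)) character(0) else
      sort(vapply(bt@products, inchikey, ""))
    expect_identical(got, fx$manifests[[key]], info = key)
  }
})

`%||%` <- function(a, b) if (is.null(a)) b else a
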