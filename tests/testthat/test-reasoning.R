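# Rule application semantics, relative reasoning, and tree enumeration.

test_that("symmetric sites collapse to unique products; mass shifts are exact", {
  kb <- humanKb()
  bt <- applyRule(fixtureMol("benzene"), kbRules(kb)$arom_hydroxylation)
  expect_length(bt@products, 1L)
  expect_identical(inchikey(bt@products[[1]]), inchikey(fixtureMol("phenol")))

  bt <- applyRule(fixtureMol("phenol"), kbRules(kb)$o_glucuronidation)
  expect_length(bt@products, 1L)
  expect_equal(exactMass(bt@products[[1]]) - exactMass(fixtureMol("phenol")),
               176.03209, tolerance = 1e-4)

  bt <- applyRule(fixtureMol("phenol"), kbRules(kb)$o_sulfation)
  expect_equal(exactMass(bt@products[[1]]) - exactMass(fixtureMol("phenol")),
               79.95682, tolerance = 1e-4)
})

test_that("a 3-site cleavage rule keeps both fragments per site (6 products)", {
  bt <- applyRule(fixtureMol("triester"), kbRules(envKb())$env_pte_hydrolysis)
  expect_length(bt@products, 6L)
  ## two products per site: 3 diester acids + 3 alcohols
  formulas <- sort(vapply(bt@products, molFormula, ""))
  expect_identical(sum(formulas %in% c("CH4O", "C2H6O", "C6H6O")), 3L)
})

test_that("mass balance: product-minus-substrate formula delta matches each rule's stoichiometry", {
  fx <- fixtureMolecules()
  kb <- humanKb(); kbe <- envKb()
  checked <- 0L
  for (i in seq_len(nrow(fx))) {
    ruleIds <- strsplit(fx$rules[i], ",", fixed = TRUE)[[1]]
    ruleIds <- ruleIds[nzchar(ruleIds)]
    if (!length(ruleIds)) next
    mol <- standardizeMolecule(fx$smiles[i])
    sub <- parseFormula(molFormula(mol))
    for (rid in ruleIds) {
      rule <- kbRules(kb)[[rid]] %||% kbRules(kbe)[[rid]]
      delta <- MetabolizR:::parseMassDelta(rule@massDelta)
      sites <- MetabolizR:::applySmirksAll(mol@graph, rule@compiled, minFragment = 0L)
      for (frags in sites) {
        tot <- integer(0)
        for (f in frags) {
          fc <- MetabolizR:::mgFormulaCounts(f)
          for (el in names(fc))
            tot[el] <- (if (el %in% names(tot)) tot[[el]] else 0L) + fc[[el]]
        }
        els <- union(union(names(tot), names(sub)), names(delta))
        for (el in els) {
          got <- (if (el %in% names(tot)) tot[[el]] else 0L) -
                 (if (el %in% names(sub)) sub[[el]] else 0L)
          want <- if (el %in% names(delta)) delta[[el]] else 0L
          expect_identical(got, want,
                           info = sprintf("%s / %s / %s", fx$name[i], rid, el))
        }
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 30L)
})

test_that("relative reasoning suppresses dominated rules with chains and scope", {
  kb <- humanKb()
  kae <- fixtureMol("kaempferide_glucoside")

  ## step 1: deglycosylation dominates both demethylation rules
  cands <- candidateBiotransformations(kae, "hgut", kb)
  expect_identical(unique(vapply(cands, function(b) b@ruleId, "")),
                   "gut_o_deglycosylation")

  ## step 2 on the aglycone: the C-7 regio-preference wins over the generic
  aglycone <- Filter(function(p) molFormula(p) == "C17H14O6",
                     cands[[1]]@products)
  expect_length(aglycone, 1L)
  cands2 <- candidateBiotransformations(aglycone[[1]], "hgut", kb)
  expect_identical(unique(vapply(cands2, function(b) b@ruleId, "")),
                   "gut_o_demethylation_c7")

  ## without precedence the candidate set is unchanged
  none <- data.frame(dominant = character(0), suppressed = character(0))
  raw <- candidateBiotransformations(kae, "hgut", kb, applyPrecedence = FALSE)
  expect_identical(filterByPrecedence(raw, none), raw)
  expect_gt(length(raw), length(cands))

  ## dominance requires the dominant rule to apply: B alone is retained
  prec <- data.frame(dominant = "rule_absent", suppressed = "gut_o_deglycosylation",
                     biosystem = "gut", stringsAsFactors = FALSE)
  expect_identical(filterByPrecedence(cands, prec), cands)

  ## a cycle among co-applicable rules is an error
  ids <- vapply(raw, function(b) b@ruleId, "")
  two <- raw[!duplicated(ids)][1:2]
  cyc <- data.frame(dominant = c(two[[1]]@ruleId, two[[2]]@ruleId),
                    suppressed = c(two[[2]]@ruleId, two[[1]]@ruleId),
                    stringsAsFactors = FALSE)
  expect_error(filterByPrecedence(two, cyc), class = "ReasoningError")
})

test_that("trees: nsteps=0 root only; provenance on every edge; parameter cap", {
  m <- fixtureMol("epicatechin")
  t0 <- predictTree(m, "phaseII", 0)
  expect_length(treeNodes(t0), 1L)
  expect_identical(nrow(treeEdges(t0)), 0L)

  t1 <- quietly_(runModule(m, "phaseII", 1))
  e <- treeEdges(t1)
  expect_gt(nrow(e), 0L)
  expect_true(all(nzchar(e$ruleId)))
  expect_true(all(nzchar(e$ruleName)))
  expect_true(all(nzchar(e$enzymes)))
  expect_true(all(e$biosystem == "human"))

  expect_error(predictTree(m, "phaseII", 13), class = "ParameterError")
  expect_error(predictTree(m, "phaseII", -1), class = "ParameterError")
})

test_that("convergent products become one node with two parent edges", {
  ## two sibling hydroxylation rules (ortho- and para-split of the same
  ## generic reaction) both produce phenol from benzene
  pack <- list(
    enzymes = list(list(id = "E1", name = "e1")),
    rules = list(
      list(id = "hydrox_a", name = "hydroxylation (variant a)",
           smirks = "[c;H1:1]>>[c:1]O", enzymes = list("E1"),
           biosystems = list("human"), modules = list("cyp450"),
           reaction_type = "Hydroxylation"),
      list(id = "hydrox_b", name = "hydroxylation (variant b)",
           smirks = "[c;H1:1][c;H1:2]>>[c:1][c:2]O", enzymes = list("E1"),
           biosystems = list("human"), modules = list("cyp450"),
           reaction_type = "Hydroxylation")))
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(pack, path, auto_unbox = TRUE)
  kb <- loadRulePack(path)
  tr <- quietly_(runModule(fixtureMol("benzene"), "cyp450", 1, kb = kb))
  phenolKey <- inchikey(fixtureMol("phenol"))
  expect_identical(setdiff(names(treeNodes(tr)),
                           inchikey(fixtureMol("benzene"))), phenolKey)
  e <- treeEdges(tr)
  expect_identical(nrow(e), 2L)
  expect_setequal(e$ruleId, c("hydrox_a", "hydrox_b"))
  expect_true(all(e$child == phenolKey))
})

test_that("node sets grow monotonically with nsteps and trees are deterministic", {
  smis <- randomFixtureMolecules(12, seed = 99)
  for (s in smis) {
    m <- standardizeMolecule(s)
    t1 <- quietly_(runModule(m, "cyp450", 1))
    t2 <- quietly_(runModule(m, "cyp450", 2))
    expect_true(all(names(treeNodes(t1)) %in% names(treeNodes(t2))), info = s)
  }
  m <- fixtureMol("epicatechin")
  j1 <- treeToJson(quietly_(runAllHuman(m, 1)))
  j2 <- treeToJson(quietly_(runAllHuman(m, 1)))
  expect_identical(j1, j2)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
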