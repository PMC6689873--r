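# Rule-pack loading, validation, constraint semantics and serialization.

minimalPack <- function(rules = NULL, precedence = NULL, mutate = NULL) {
  doc <- list(
    enzymes = list(list(id = "E1", name = "enzyme one", family = "CYP450")),
    rules = rules %||% list(list(
      id = "rule_x", name = "test hydroxylation",
      smirks = "[c;H1:1]>>[c:1]O",
      enzymes = list("E1"), biosystems = list("human"),
      modules = list("cyp450"), reaction_type = "Hydroxylation",
      priority_tier = 0)),
    precedence = precedence %||% list())
  if (!is.null(mutate)) doc <- mutate(doc)
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  path
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("packaged fixture packs load completely and validate clean", {
  kb <- humanKb()
  expect_s4_class(kb, "Knowledgebase")
  expect_gte(length(kbRules(kb)), 12L)
  expect_identical(nrow(validateKnowledgebase(kb)), 0L)
  ## all fixture rules share tier 0 (uniform likelihoods), loader accepts others
  expect_true(all(vapply(kbRules(kb), function(r) r@priorityTier, 0L) == 0L))

  kbe <- envKb()
  expect_gte(length(kbRules(kbe)), 3L)
  expect_identical(nrow(validateKnowledgebase(kbe)), 0L)
})

test_that("loader reports compile, schema and reference errors precisely", {
  bad <- minimalPack(mutate = function(doc) {
    doc$rules[[1]]$smirks <- "not-a-smirks"
    doc
  })
  err <- tryCatch(loadRulePack(bad), error = function(e) e)
  expect_s3_class(err, "RuleCompileError")
  expect_identical(err$ruleId, "rule_x")

  dangling <- minimalPack(precedence = list(
    list(dominant = "rule_x", suppressed = "rule_missing")))
  expect_error(loadRulePack(dangling), class = "ReferenceError")

  noRules <- minimalPack(mutate = function(doc) { doc$rules <- NULL; doc })
  err <- tryCatch(loadRulePack(noRules), error = function(e) e)
  expect_s3_class(err, "SchemaError")
  expect_identical(err$pointer, "/rules")

  badEnzyme <- minimalPack(mutate = function(doc) {
    doc$rules[[1]]$enzymes <- list("E_missing"); doc
  })
  expect_error(loadRulePack(badEnzyme), class = "ReferenceError")
})

test_that("ruleApplies combines pattern, SMARTS constraints and predicates", {
  kb <- humanKb()
  gluc <- kbRules(kb)$o_glucuronidation
  expect_true(ruleApplies(fixtureMol("phenol"), gluc))
  expect_false(ruleApplies(fixtureMol("ethane"), gluc))

  ## hydroxyl present but mass over the 900 Da predicate -> rule gated off
  heavy <- standardizeMolecule(paste0("OC", strrep("C", 70), "O"))
  expect_gt(exactMass(heavy), 900)
  expect_true(exactMass(heavy) <= 1100)
  expect_false(ruleApplies(heavy, gluc))

  sulf <- kbRules(kb)$o_sulfation
  expect_true(ruleApplies(fixtureMol("phenol"), sulf))
  ## required-SMARTS constraint: aliphatic alcohol alone is not enough
  expect_false(ruleApplies(standardizeMolecule("CCO"), sulf))
})

test_that("validateKnowledgebase reports cycles and orphan enzymes", {
  cyc <- minimalPack(
    rules = list(
      list(id = "rule_a", name = "a", smirks = "[c;H1:1]>>[c:1]O",
           enzymes = list("E1"), biosystems = list("human"),
           modules = list("cyp450"), reaction_type = "Hydroxylation"),
      list(id = "rule_b", name = "b", smirks = "[C;H3:1]>>[C:1]O",
           enzymes = list("E1"), biosystems = list("human"),
           modules = list("cyp450"), reaction_type = "Hydroxylation")),
    precedence = list(list(dominant = "rule_a", suppressed = "rule_b"),
                      list(dominant = "rule_b", suppressed = "rule_a")))
  rep <- validateKnowledgebase(loadRulePack(cyc))
  expect_true(any(rep$kind == "precedence_cycle"))

  orphan <- minimalPack(mutate = function(doc) {
    doc$enzymes <- c(doc$enzymes,
                     list(list(id = "E_unused", name = "unused")))
    doc
  })
  rep <- validateKnowledgebase(loadRulePack(orphan))
  expect_true(any(rep$kind == "orphan_enzyme" & rep$subject == "E_unused"))
})

test_that("save/load round trip is structurally identical", {
  kb <- humanKb()
  out <- tempfile(fileext = ".json")
  saveRulePack(kb, out)
  kb2 <- loadRulePack(out)
  expect_identical(names(kbRules(kb)), names(kbRules(kb2)))
  expect_identical(lapply(kbRules(kb), function(r) r@smirks),
                   lapply(kbRules(kb2), function(r) r@smirks))
  expect_identical(lapply(kbRules(kb), function(r) r@constraints),
                   lapply(kbRules(kb2), function(r) r@constraints))
  expect_identical(kbPrecedence(kb), kbPrecedence(kb2))
  expect_identical(kbEnzymes(kb), kbEnzymes(kb2))
  expect_identical(kbPathways(kb), kbPathways(kb2))
  expect_identical(kbRecords(kb), kbRecords(kb2))
})

test_that("curated biotransformation records keep their invariants", {
  kb <- humanKb()
  for (rec in kbRecords(kb)) {
    expect_gte(length(rec$product_inchikeys), 1L)
    expect_gte(length(rec$citations), 1L)
    expect_match(rec$substrate_inchikey, "^[A-Z]{14}-[A-Z]{10}-[A-Z]$")
  }
  ## record products are reproduced by the engine
  rec <- kbRecords(kb)[[1]]
  mol <- standardizeMolecule(rec$substrate_smiles)
  tr <- quietly_(runModule(mol, "cyp450", 1))
  expect_true(all(rec$product_inchikeys %in% names(treeNodes(tr))))
})
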