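# The five modules, allHuman union, and the ordered superbio pipeline.

test_that("single-module runs: NAPQI, inorganic filtering, phase II conjugates", {
  tr <- quietly_(runModule(fixtureMol("acetaminophen"), "cyp450", 1))
  expect_true("URNSECGXFRDEDC-UHFFFAOYSA-N" %in% names(treeNodes(tr)))  # NAPQI
  napqi <- treeNodes(tr)[["URNSECGXFRDEDC-UHFFFAOYSA-N"]]
  expect_identical(molFormula(napqi), "C8H7NO2")

  ## water is inorganic: root-only tree, reason logged
  expect_message(tw <- runModule("O", "cyp450", 1), "inorganic")
  expect_length(treeNodes(tw), 1L)
  expect_identical(nrow(treeEdges(tw)), 0L)

  tp <- quietly_(runModule(fixtureMol("phenol"), "phaseII", 1))
  deltas <- vapply(setdiff(names(treeNodes(tp)), inchikey(fixtureMol("phenol"))),
                   function(k) exactMass(treeNodes(tp)[[k]]) -
                     exactMass(fixtureMol("phenol")), 0)
  expect_true(any(abs(deltas - 176.03209) < 1e-4))  # glucuronide
  expect_true(any(abs(deltas - 79.95682) < 1e-4))   # sulfate

  expect_error(runModule(fixtureMol("phenol"), "bogus", 1),
               class = "ParameterError")
})

test_that("glycerophospholipids route only through their pathway", {
  tr <- quietly_(runAllHuman(fixtureMol("gpl"), 1))
  expect_identical(unique(treeEdges(tr)$ruleId), "gpl_sn_hydrolysis")
  ## no CYP450- or UGT-catalyzed products
  expect_false(any(grepl("CYP|UGT|SULT", treeEdges(tr)$enzymes)))
})

test_that("allHuman is the filtered union of the four human modules", {
  m <- fixtureMol("epicatechin")
  tAll <- quietly_(runAllHuman(m, 1))
  tCyp <- quietly_(runModule(m, "cyp450", 1))
  tGut <- quietly_(runModule(m, "hgut", 1))
  tP2 <- quietly_(runModule(m, "phaseII", 1))
  expect_true(all(names(treeNodes(tCyp)) %in% names(treeNodes(tAll))))
  expect_gte(length(treeNodes(tAll)), length(treeNodes(tCyp)))
  ## epicatechin yields a phase II conjugate at one step under allHuman ...
  expect_true(any(vapply(treeNodes(tAll), function(n)
    abs(exactMass(n) - exactMass(m) - 176.03209) < 1e-4, NA)))
  ## ... and a gut microbial product (C-ring fission diarylpropanol)
  expect_true(any(treeEdges(tAll)$biosystem == "gut"))
  expect_true(all(names(treeNodes(tGut)) %in% names(treeNodes(tAll))))

  ## nsteps = 0 is the root alone
  expect_length(treeNodes(quietly_(runAllHuman(m, 0))), 1L)
})

test_that("superbio starts with hydrolysis, ends with terminal conjugation, depth <= 12", {
  ts <- quietly_(runSuperbio(fixtureMol("aspirin")))
  e <- treeEdges(ts)
  expect_gt(nrow(e), 0L)
  expect_identical(unique(e$ruleId[e$step == min(e$step)]), "ester_hydrolysis")
  expect_lte(max(e$step), superbioMaxSteps())
  expect_identical(superbioMaxSteps(), 12L)

  ## conjugation products are terminal: no edge leaves a conjugate
  kb <- humanKb()
  conjRules <- names(Filter(function(r)
    r@reactionType %in% c("Glucuronidation", "Sulfation", "Methylation",
                          "Acetylation"), kbRules(kb)))
  conjChildren <- unique(e$child[e$ruleId %in% conjRules])
  expect_false(any(e$parent %in% conjChildren))

  ## a molecule matching only conjugation rules fires in the final slots
  tb <- quietly_(runSuperbio(standardizeMolecule("CC(C)(C)O")))
  eb <- treeEdges(tb)
  expect_true(all(eb$step >= 10L))
  expect_true(all(kbRules(kb)[[eb$ruleId[1]]]@reactionType %in%
                    c("Glucuronidation", "Sulfation", "Methylation",
                      "Acetylation")))
})

test_that("superbio's metabolite set is contained in allHuman's", {
  ## the ordered pipeline is a restriction of the free union: every
  ## superbio chain of length L is reproducible by L allHuman rounds, so
  ## it suffices to compare against allHuman at the longest chain depth
  for (name in c("aspirin", "epicatechin")) {
    m <- fixtureMol(name)
    sb <- quietly_(runSuperbio(m))
    depth <- treeChainDepth(sb)
    expect_lte(depth, 12L)
    ah <- quietly_(runAllHuman(m, depth))
    expect_true(all(names(treeNodes(sb)) %in% names(treeNodes(ah))),
                info = name)
  }
})

test_that("envmicro honors its own precedence and multi-site co-products", {
  tr <- quietly_(runEnv(fixtureMol("triester"), 1))
  expect_gte(length(treeNodes(tr)) - 1L, 7L)  # 6 cleavage products + oxon

  ## nitro reduction dominates amide hydrolysis on 4-nitrobenzamide
  tn <- quietly_(runEnv(fixtureMol("nitrobenzamide"), 1))
  expect_identical(unique(treeEdges(tn)$ruleId), "env_nitro_reduction")

  ## no applicable rule -> root-only tree
  te <- quietly_(runEnv(fixtureMol("ethane"), 1))
  expect_length(treeNodes(te), 1L)
})

test_that("module runs are reproducible functions of their inputs", {
  m <- fixtureMol("methyl_parathion")
  a <- quietly_(runModule(m, "cyp450", 1))
  b <- quietly_(runModule(m, "cyp450", 1))
  expect_identical(treeToJson(a), treeToJson(b))
  expect_identical(annotateTree(a), annotateTree(b))
})
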