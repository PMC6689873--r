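# MS-driven metabolite identification.

test_that("ion-to-neutral conversion subtracts exactly the proton offset", {
  expect_equal(neutralMassFromIon(291.08631), 290.07904, tolerance = 1e-9)
  for (x in c(0.5, 10, 466.11113, 969.8669))
    expect_equal(neutralMassFromIon(x + 1.00727), x, tolerance = 1e-12)
  expect_error(neutralMassFromIon(1.0), class = "ParameterError")
  expect_error(neutralMassFromIon(291.08631, adduct = "[M+Na]+"),
               class = "ParameterError")
})

test_that("epicatechin glucuronides are identified by mass and by formula", {
  m <- fixtureMol("epicatechin")
  res <- quietly_(identifyMetabolites(m, masses = 466.11113, tolerance = 0.01,
                                      steps = 1, scope = "allHuman"))
  hits <- res$targets[[1]]$matches
  expect_gte(length(hits), 1L)
  for (h in hits) {
    expect_identical(molFormula(h$metabolite), "C21H22O12")
    expect_lte(abs(exactMass(h$metabolite) - 466.11113), 0.01)
    expect_identical(h$pathway$reaction[1], "O-glucuronidation")
    expect_identical(h$steps, 1L)
  }

  resF <- quietly_(identifyMetabolites(m, formulas = "C21H22O12", steps = 1,
                                       scope = "allHuman"))
  keysM <- sort(vapply(hits, function(h) inchikey(h$metabolite), ""))
  keysF <- sort(vapply(resF$targets[[1]]$matches,
                       function(h) inchikey(h$metabolite), ""))
  expect_identical(keysM, keysF)
})

test_that("unmatched targets yield empty match lists, not errors", {
  res <- quietly_(identifyMetabolites(fixtureMol("epicatechin"),
                                      masses = 9999.0, steps = 1))
  expect_length(res$targets[[1]]$matches, 0L)
  expect_error(identifyMetabolites(fixtureMol("epicatechin")),
               class = "ParameterError")
  expect_error(identifyMetabolites(fixtureMol("epicatechin"),
                                   masses = 300, tolerance = 0),
               class = "ParameterError")
})

test_that("matches obey the inclusive tolerance bound and none are missed", {
  m <- fixtureMol("phenol")
  tol <- 0.01
  targets <- c(270.07395, 173.99868, 110.03678)  # glucuronide, sulfate, catechols
  res <- quietly_(identifyMetabolites(m, masses = targets, tolerance = tol,
                                      steps = 2, scope = "allHuman"))
  tree <- quietly_(runAllHuman(m, 2))
  for (i in seq_along(targets)) {
    got <- sort(vapply(res$targets[[i]]$matches,
                       function(h) inchikey(h$metabolite), ""))
    for (h in res$targets[[i]]$matches)
      expect_lte(abs(exactMass(h$metabolite) - targets[i]), tol)
    ## brute-force scan of the fully expanded tree, earliest matching round
    nodes <- treeNodes(tree)
    byStep <- lapply(1:2, function(k) {
      e <- treeEdges(tree)
      firstStep <- vapply(setdiff(names(nodes), inchikey(m)), function(key)
        min(e$step[e$child == key]), 0)
      names(firstStep)[firstStep == k]
    })
    want <- character(0)
    for (k in 1:2) {
      hits <- byStep[[k]][vapply(byStep[[k]], function(key)
        abs(exactMass(nodes[[key]]) - targets[i]) <= tol, NA)]
      if (length(hits)) { want <- sort(hits); break }
    }
    expect_identical(got, want, info = sprintf("target %.5f", targets[i]))
  }
})

test_that("early stopping never changes already-satisfied matches", {
  m <- fixtureMol("phenol")
  one <- quietly_(identifyMetabolites(m, masses = 270.07395, steps = 1))
  two <- quietly_(identifyMetabolites(m, masses = 270.07395, steps = 2))
  k1 <- sort(vapply(one$targets[[1]]$matches,
                    function(h) inchikey(h$metabolite), ""))
  k2 <- sort(vapply(two$targets[[1]]$matches,
                    function(h) inchikey(h$metabolite), ""))
  expect_identical(k1, k2)
})

test_that("identification SDF output is ordered, annotated and byte-stable", {
  m <- fixtureMol("epicatechin")
  res <- quietly_(identifyMetabolites(m, masses = c(466.11113, 9999),
                                      steps = 1))
  f1 <- tempfile(fileext = ".sdf"); f2 <- tempfile(fileext = ".sdf")
  writeIdentification(res, f1)
  res2 <- quietly_(identifyMetabolites(m, masses = c(466.11113, 9999),
                                       steps = 1))
  writeIdentification(res2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  sdfset <- ChemmineR::read.SDFset(f1)
  expect_identical(length(sdfset), length(res$targets[[1]]$matches))
  db <- ChemmineR::datablock(sdfset)[[1]]
  expect_true(all(c("TargetType", "TargetValue", "InChIKey",
                    "MolecularFormula", "MonoisotopicMass", "MassDelta",
                    "StepCount", "Pathway") %in% names(db)))
  expect_match(db[["Pathway"]], "^1\\. O-glucuronidation \\[")

  ## a two-step match carries a two-line pathway in step order
  res2step <- quietly_(identifyMetabolites(fixtureMol("phenol"),
                                           masses = 286.06887, steps = 2))
  expect_gte(length(res2step$targets[[1]]$matches), 1L)
  ftwo <- tempfile(fileext = ".sdf")
  writeIdentification(res2step, ftwo)
  raw <- readLines(ftwo)
  start <- grep("^> <Pathway>$", raw)[1]
  stopLine <- start + which(raw[(start + 1):length(raw)] == "")[1] - 1L
  lines <- raw[(start + 1):stopLine]
  expect_length(lines, 2L)
  expect_match(lines[1], "^1\\. ")
  expect_match(lines[2], "^2\\. ")

  ## zero matches still produce a valid (empty) SDF
  res0 <- quietly_(identifyMetabolites(m, masses = 9999, steps = 1))
  f0 <- tempfile(fileext = ".sdf")
  writeIdentification(res0, f0)
  expect_true(file.exists(f0))
  expect_identical(length(readLines(f0)), 0L)
})
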