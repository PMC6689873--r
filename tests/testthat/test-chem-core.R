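# Molecule parsing, standardization, identifiers and structure I/O.

test_that("parseInput handles SMILES, InChI and SDF input with per-record errors", {
  p <- parseInput("CCO", format = "smiles")
  expect_length(p$structures, 1L)
  expect_identical(heavyAtomCount(standardizeMolecule(p$structures[[1]])), 3L)

  p <- parseInput("InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3", format = "inchi")
  m <- standardizeMolecule(p$structures[[1]])
  expect_identical(inchikey(m), "LFQSCWFLJHTTHZ-UHFFFAOYSA-N")

  expect_identical(parseInput("", format = "smiles"),
                   list(structures = list(), errors = list()))

  ## SDF with 3 valid records and 1 corrupt one: batch continues
  sdf <- tempfile(fileext = ".sdf")
  good <- vapply(c("CCO", "c1ccccc1", "CC(=O)O"), function(s)
    MetabolizR:::obMolBlock(s), "")
  corrupt <- paste("corrupt", "", "",
                   "  2  1  0  0  0  0  0  0  0  0999 V2000",
                   "garbage that is not an atom line",
                   "    0.0000    0.0000    0.0000 C   0  0",
                   "  1  2  1  0", "M  END", sep = "\n")
  writeLines(paste(c(good[1], "$$$$", corrupt, "$$$$", good[2], "$$$$",
                     good[3], "$$$$"), collapse = "\n"), sdf)
  p <- parseInput(sdf, format = "sdf")
  expect_length(p$structures, 3L)
  expect_length(p$errors, 1L)
  expect_identical(p$errors[[1]]$index, 2L)
})

test_that("standardization neutralizes charges with nitro/zwitterion exceptions", {
  expect_identical(molFormula(fixtureMol("benzene")), "C6H6")

  phenolate <- standardizeMolecule("[O-]c1ccccc1")
  expect_identical(molFormula(phenolate), "C6H6O")
  expect_identical(inchikey(phenolate), inchikey(fixtureMol("phenol")))

  nitro <- standardizeMolecule("[O-][N+](=O)c1ccccc1")
  expect_identical(molFormula(nitro), "C6H5NO2")
  expect_match(smiles(nitro), "\\[N\\+\\]")   # charge-separated form kept

  ## zwitterionic phosphocholine: internally balanced, left as supplied
  gpl <- fixtureMol("gpl")
  expect_match(smiles(gpl), "\\[N\\+\\]")
  expect_match(smiles(gpl), "\\[O-\\]")

  expect_error(standardizeMolecule("CCO.CC"), class = "MixtureRejected")
  expect_error(standardizeMolecule("O"), class = "InorganicRejected")
  expect_error(standardizeMolecule("not-a-smiles(("), class = "InvalidStructure")
})

test_that("standardization is idempotent by InChIKey", {
  for (smi in c("[O-]c1ccccc1", "CC(=O)Nc1ccc(O)cc1", "C[NH3+].[Cl-]")) {
    m1 <- tryCatch(standardizeMolecule(smi), error = function(e) NULL)
    if (is.null(m1)) next  # the salt is rejected as a mixture
    m2 <- standardizeMolecule(smiles(m1))
    expect_identical(inchikey(m1), inchikey(m2))
  }
})

test_that("monoisotopic masses match elementwise sums to 1e-5", {
  expect_equal(monoisotopicMass("H2O"), 18.01056, tolerance = 1e-5)
  expect_equal(monoisotopicMass("C15H14O6"), 290.07904, tolerance = 1e-5)
  ## glucuronide = aglycone + glucuronyl shift
  expect_equal(monoisotopicMass("C21H22O12"), 466.11113, tolerance = 1e-5)
  expect_equal(monoisotopicMass("C21H22O12") - monoisotopicMass("C15H14O6"),
               176.03209, tolerance = 1e-5)
  expect_error(monoisotopicMass("C2Qq4"), class = "FormulaError")
  expect_error(monoisotopicMass("Xx2"), class = "FormulaError")
})

test_that("formula-derived mass agrees with atomwise structure mass to 1e-4", {
  for (name in c("benzene", "acetaminophen", "epicatechin", "nicotine",
                 "methyl_parathion", "gpl")) {
    m <- fixtureMol(name)
    obMass <- ChemmineOB::exactMass_OB(
      ChemmineOB::forEachMol("SMILES", paste0(smiles(m), "\n"), identity))
    expect_equal(exactMass(m), obMass, tolerance = 1e-4, info = name)
  }
})

test_that("write/parse round trip preserves InChIKeys on random fixtures", {
  smis <- randomFixtureMolecules(12, seed = 11)
  for (s in smis) {
    m <- standardizeMolecule(s)
    g <- m@graph
    rewritten <- MetabolizR:::obCanonicalSmiles(MetabolizR:::writeSmilesGraph(g))
    expect_identical(MetabolizR:::obInChIKey(rewritten), inchikey(m), info = s)
  }
})

test_that("structure writers emit the frozen annotation schema deterministically", {
  tr <- quietly_(runModule(fixtureMol("phenol"), "phaseII", 1))
  ann <- annotateTree(tr)
  expect_identical(names(ann), annotationColumns())
  expect_identical(ann$MetaboliteID[1], "BTM0000")
  expect_identical(ann$ParentID[1], "")

  d <- tempfile(); dir.create(d)
  f1 <- file.path(d, "a.csv"); f2 <- file.path(d, "b.csv")
  writeStructures(ann, "csv", f1)
  writeStructures(ann, "csv", f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  s1 <- file.path(d, "a.sdf")
  writeStructures(ann, "sdf", s1, tree = tr)
  sdfset <- ChemmineR::read.SDFset(s1)
  expect_identical(length(sdfset), nrow(ann))
  blocks <- ChemmineR::datablock(sdfset)
  expect_true(all(vapply(blocks, function(b)
    all(c("MetaboliteID", "InChI", "InChIKey", "MolecularFormula",
          "MonoisotopicMass", "ReactionType", "Biosystem", "ParentID",
          "ParentInChIKey", "Synonyms") %in% names(b)), NA)))

  ## an empty tree still yields a valid header-only CSV
  tr0 <- quietly_(runModule(fixtureMol("ethane"), "cyp450", 1))
  f0 <- file.path(d, "empty.csv")
  writeStructures(annotateTree(tr0), "csv", f0)
  got <- utils::read.csv(f0)
  expect_identical(nrow(got), 1L)  # root row only
  expect_identical(names(got), annotationColumns())
})
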