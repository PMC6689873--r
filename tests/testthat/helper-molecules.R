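# Shared fixture molecules, standardized lazily and cached for the whole
# test run (OpenBabel conversions are memoised inside the package too).

.molCache <- new.env(parent = emptyenv())

fixtureMol <- function(name) {
  if (!is.null(.molCache[[name]])) return(.molCache[[name]])
  smi <- switch(name,
    benzene = "c1ccccc1",
    phenol = "Oc1ccccc1",
    catechol = "Oc1ccccc1O",
    aniline = "Nc1ccccc1",
    ethane = "CC",
    cyclohexane = "C1CCCCC1",
    ethylbenzene = "CCc1ccccc1",
    acetaminophen = "CC(=O)Nc1ccc(O)cc1",
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    nicotine = "CN1CCCC1c1cccnc1",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    epicatechin = "Oc1cc(O)c2CC(O)C(Oc2c1)c1ccc(O)c(O)c1",
    kaempferide_glucoside =
      "COc1ccc(cc1)c1oc2cc(OC)cc(O)c2c(=O)c1OC1OC(CO)C(O)C(O)C1O",
    styrene_oxide = "C1(c2ccccc2)CO1",
    methyl_parathion = "CCOP(=S)(OC)Oc1ccc(cc1)[N+](=O)[O-]",
    triester = "CCOP(=S)(OC)Oc1ccccc1",
    nitrobenzene = "O=[N+]([O-])c1ccccc1",
    n_methylbenzamide = "O=C(NC)c1ccccc1",
    nitrobenzamide = "NC(=O)c1ccc(cc1)[N+](=O)[O-]",
    gpl = "CCCC(=O)OCC(COP(=O)([O-])OCC[N+](C)(C)C)OC(=O)CCC",
    acyl_coa = "CC(=O)SCCNC(=O)CCNC(=O)C(O)C(C)(C)CO",
    ethylamine = "CCN",
    acetic_acid = "CC(O)=O",
    stop("unknown fixture molecule: ", name))
  m <- standardizeMolecule(smi, label = name)
  assign(name, m, envir = .molCache)
  m
}

humanKb <- function() defaultKnowledgebase()
envKb <- function() envKnowledgebase()

# suppress the per-molecule filter log lines in tests that don't assert them
quietly_ <- function(expr) suppressMessages(suppressWarnings(expr))

# longest root-to-leaf chain (in edges) of a metabolic tree
treeChainDepth <- function(tree) {
  e <- treeEdges(tree)
  if (!nrow(e)) return(0L)
  depth <- stats::setNames(0L, inchikey(rootMolecule(tree)))
  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > nrow(e) + 1L) break   # guard against convergence cycles
    changed <- FALSE
    for (i in seq_len(nrow(e))) {
      p <- e$parent[i]; ch <- e$child[i]
      if (p %in% names(depth)) {
        nd <- depth[[p]] + 1L
        if (!(ch %in% names(depth)) || nd > depth[[ch]]) {
          if (!(ch %in% names(depth)) || nd > depth[[ch]]) {
            depth[ch] <- max(nd, depth[ch], na.rm = TRUE)
            changed <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  max(depth)
}

# run fn under a temporary RNG seed, restoring the caller's stream
.withSeedHelper <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fn()
}
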