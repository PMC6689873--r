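## Fixture and synthetic-molecule generation. The fixture catalog spans
## every packaged rule's applicability class plus negative controls; the
## random generators produce seeded, structurally valid decorated
## scaffolds used for property-style tests and the phase II harness.

#' Fixture molecule catalog
#'
#' Named test molecules covering every rule of the packaged human/gut and
#' environmental packs, plus negative controls matching no rule.
#'
#' @return data.frame(name, smiles, pack, rules) where \code{rules} is a
#'   comma-separated list of pack rules expected to apply.
#' @export
fixtureMolecules <- function() {
  rows <- list(
    c("benzene", "c1ccccc1", "human_gut", "arom_hydroxylation"),
    c("ethylbenzene", "CCc1ccccc1", "human_gut",
      "arom_hydroxylation,benzylic_hydroxylation"),
    c("acetaminophen", "CC(=O)Nc1ccc(O)cc1", "human_gut",
      "arom_hydroxylation,quinoneimine_oxidation,o_glucuronidation,o_sulfation"),
    c("nicotine", "CN1CCCC1c1cccnc1", "human_gut",
      "arom_hydroxylation,tert_amine_n_demethylation"),
    c("aspirin", "CC(=O)Oc1ccccc1C(=O)O", "human_gut",
      "arom_hydroxylation,ester_hydrolysis,o_glucuronidation"),
    c("styrene oxide", "C1(c2ccccc2)CO1", "human_gut",
      "arom_hydroxylation,epoxide_hydrolysis"),
    c("methyl parathion", "CCOP(=S)(OC)Oc1ccc(cc1)[N+](=O)[O-]", "human_gut",
      "arom_hydroxylation,odearylation_phosphorothioate,oxidative_desulfurization"),
    c("phenol", "Oc1ccccc1", "human_gut",
      "arom_hydroxylation,o_glucuronidation,o_sulfation"),
    c("catechol", "Oc1ccccc1O", "human_gut",
      "o_glucuronidation,o_sulfation,catechol_o_methylation"),
    c("aniline", "Nc1ccccc1", "human_gut",
      "arom_hydroxylation,arylamine_n_acetylation"),
    c("dibutyryl glycerophosphocholine",
      "CCCC(=O)OCC(COP(=O)([O-])OCC[N+](C)(C)C)OC(=O)CCC", "human_gut",
      "gpl_sn_hydrolysis"),
    c("kaempferol 7,4'-dimethyl ether 3-glucoside",
      "COc1ccc(cc1)c1oc2cc(OC)cc(O)c2c(=O)c1OC1OC(CO)C(O)C(O)C1O", "human_gut",
      "o_glucuronidation,o_sulfation,gut_o_deglycosylation,gut_o_demethylation_c7,gut_o_demethylation"),
    c("epicatechin", "Oc1cc(O)c2CC(O)C(Oc2c1)c1ccc(O)c(O)c1", "human_gut",
      "o_glucuronidation,o_sulfation,catechol_o_methylation,gut_c_ring_fission"),
    c("ethane", "CC", "negative", ""),
    c("cyclohexane", "C1CCCCC1", "negative", ""),
    c("mixed phosphorothioate triester", "CCOP(=S)(OC)Oc1ccccc1", "env",
      "env_pte_hydrolysis,env_desulfurization"),
    c("nitrobenzene", "O=[N+]([O-])c1ccccc1", "env", "env_nitro_reduction"),
    c("N-methylbenzamide", "O=C(NC)c1ccccc1", "env", "env_amide_hydrolysis"),
    c("4-nitrobenzamide", "NC(=O)c1ccc(cc1)[N+](=O)[O-]", "env",
      "env_nitro_reduction,env_amide_hydrolysis")
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("name", "smiles", "pack", "rules")
  out
}

#' Brute-force product enumeration for one (molecule, rule) pair
#'
#' Enumerates every substructure-match embedding of the rule's reactant
#' pattern, applies the transform at each embedding, canonicalizes every
#' resulting fragment, and deduplicates by InChIKey. This is the reference
#' enumeration that \code{\link{applyRule}} must reproduce.
#'
#' @param mol a \linkS4class{Molecule}.
#' @param rule a \linkS4class{BiotransformationRule}.
#' @return sorted character vector of product InChIKeys (substrate
#'   excluded).
#' @export
bruteForceProducts <- function(mol, rule) {
  g <- mol@graph
  embeddings <- matchSmarts(g, rule@compiled$reactant)
  keys <- character(0)
  for (m in embeddings) {
    frags <- applySmirksAt(g, rule@compiled, m)
    for (f in frags) {
      smi <- tryCatch(writeSmilesGraph(f), error = function(e) NA_character_)
      if (is.na(smi)) next
      can <- obCanonicalSmiles(smi)
      if (is.na(can)) next
      ik <- obInChIKey(can)
      if (!is.na(ik) && ik != mol@inchikey) keys <- c(keys, ik)
    }
  }
  sort(unique(keys))
}

## run fn with a private RNG stream so generators do not disturb the
## caller's RNG state
.withSeed <- function(seed, fn) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
         else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

## decoration strings attach to the scaffold through their final atom
.POSITIVE_DECORATIONS <- c("O", "N", "OC(=O)", "OC", "S", "CN", "OCC",
                           "NC(=O)")
.NEGATIVE_SCAFFOLDS <- c("CCCCCC", "CCCCCCCC", "CCC(C)CC", "CC(C)CC(C)C",
                         "C1CCCCC1", "C1CCCC1", "CCOCC", "CCCOCCC",
                         "CCc1ccccc1", "Cc1ccccc1C", "CCCCc1ccccc1",
                         "C1CCCCC1CC", "CCOC(C)C", "CC(C)OC(C)C")

#' Seeded random fixture molecules
#'
#' Generates structurally valid decorated scaffolds: aromatic/aliphatic
#' cores carrying zero or more substituents. With \code{conjugatable =
#' TRUE} every molecule carries at least one phase II-conjugatable motif
#' (hydroxyl, amine, carboxyl, thiol); with \code{FALSE} none does
#' (alkanes, aliphatic ethers, alkylbenzenes).
#'
#' @param n number of molecules.
#' @param seed RNG seed.
#' @param conjugatable generate motif-bearing molecules (TRUE), plain ones
#'   (FALSE), or a mixture (NA, default).
#' @return character vector of n canonical SMILES.
#' @export
randomFixtureMolecules <- function(n, seed = 42L, conjugatable = NA) {
  .withSeed(seed, function() {
    out <- character(0)
    tries <- 0L
    while (length(out) < n && tries < n * 50L) {
      tries <- tries + 1L
      wantPos <- if (is.na(conjugatable)) stats::runif(1) < 0.5 else conjugatable
      smi <- if (wantPos) {
        deco <- sample(.POSITIVE_DECORATIONS, 1L)
        tl <- sample(c("", "C", "CC", "CCC", "CCCC", "C(C)C"), 1L)
        switch(sample(4L, 1L),
          if (nzchar(tl)) sprintf("%sc1ccc(%s)cc1", deco, tl) else
            paste0(deco, "c1ccccc1"),
          sprintf("%sc1ccc2ccccc2c1", deco),
          if (nzchar(tl)) sprintf("%sC1CCC(%s)CC1", deco, tl) else
            paste0(deco, "C1CCCCC1"),
          paste0(deco, "c1ccncc1"))
      } else {
        sample(.NEGATIVE_SCAFFOLDS, 1L)
      }
      smi <- tryCatch({
        can <- obCanonicalSmiles(smi)
        if (is.na(can)) NA_character_ else can
      }, error = function(e) NA_character_)
      if (is.na(smi)) next
      out <- c(out, smi)
    }
    out[seq_len(min(n, length(out)))]
  })
}

#' Synthetic separable phase II training set
#'
#' Labeled molecules for the phase II harness: label 1 molecules carry
#' conjugatable motifs by construction, label 0 molecules carry none, so
#' the classes are separable from the structural feature flags. The set
#' emulates the shape of a curated substrate/non-substrate collection, not
#' its chemistry: real training data are not separable, so harness scores
#' on this set say nothing about real-data accuracy.
#'
#' @param n total number of molecules (split roughly half and half).
#' @param seed RNG seed.
#' @return list(mols = list of \linkS4class{Molecule}, labels = 0/1
#'   integer vector).
#' @export
syntheticPhase2Set <- function(n = 120L, seed = 7L) {
  nPos <- ceiling(n / 2); nNeg <- n - nPos
  pos <- randomFixtureMolecules(nPos, seed = seed, conjugatable = TRUE)
  neg <- randomFixtureMolecules(nNeg, seed = seed + 1L, conjugatable = FALSE)
  smis <- c(pos, neg)
  labels <- c(rep(1L, length(pos)), rep(0L, length(neg)))
  mols <- lapply(smis, function(s)
    tryCatch(standardizeMolecule(s), error = function(e) NULL))
  keep <- !vapply(mols, is.null, NA)
  list(mols = mols[keep], labels = labels[keep])
}

#' Generate the deterministic fixture set
#'
#' The fixture catalog plus seeded random molecules, together with
#' expected-product manifests computed by the brute-force oracle for
#' every (fixture molecule, applicable rule) pair. Identical seeds yield
#' identical manifests.
#'
#' @param seed RNG seed for the random component.
#' @param nRandom number of random molecules to include.
#' @return list(catalog, random, manifests); \code{manifests} is a named
#'   list \code{"<name>|<ruleId>"} -> sorted product InChIKeys.
#' @export
generateFixtures <- function(seed = 42L, nRandom = 20L) {
  catalog <- fixtureMolecules()
  kbH <- defaultKnowledgebase()
  kbE <- envKnowledgebase()
  manifests <- list()
  for (i in seq_len(nrow(catalog))) {
    ruleIds <- strsplit(catalog$rules[i], ",", fixed = TRUE)[[1]]
    ruleIds <- ruleIds[nzchar(ruleIds)]
    if (!length(ruleIds)) next
    mol <- standardizeMolecule(catalog$smiles[i])
    for (rid in ruleIds) {
      rule <- kbH@rules[[rid]] %||% kbE@rules[[rid]]
      if (is.null(rule)) next
      manifests[[paste0(catalog$name[i], "|", rid)]] <-
        bruteForceProducts(mol, rule)
    }
  }
  list(catalog = catalog,
       random = randomFixtureMolecules(nRandom, seed = seed),
       manifests = manifests)
}
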