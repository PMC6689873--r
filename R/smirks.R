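## SMIRKS reaction-transform engine.
##
## A rule's SMIRKS is "reactant>>product" where the reactant side is a
## connected pattern in the supported SMARTS subset with every atom mapped,
## and the product side is a SMILES-like template (possibly several
## dot-separated fragments) whose atoms are either mapped (survivors) or
## unmapped (newly created). Semantics:
##   * mapped reactant atoms absent from the product are deleted;
##   * unmapped product atoms are created with the written element,
##     aromaticity, charge and H specification;
##   * mapped product atoms keep the substrate atom's element; their charge
##     is set to the written charge (0 when unwritten), their hydrogens are
##     re-derived from valence, and their aromatic flag follows the product
##     symbol when it is written as a concrete element symbol ([*:n] keeps
##     the substrate flag);
##   * bonds between two mapped atoms that exist on the reactant side but
##     not on the product side are deleted; product bonds are created or
##     their order rewritten as needed.
## After application the edited graph is split into connected fragments;
## fragments with fewer than `minFragment` heavy atoms (lone leaving atoms)
## are discarded.

compileSmirks <- function(smirks) {
  parts <- strsplit(smirks, ">>", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop(smartsError(sprintf("SMIRKS must have exactly one '>>': '%s'", smirks)))
  reactant <- compileSmartsPattern(parts[1])
  rmaps <- vapply(reactant$atoms, function(a) a$map, 0L)
  if (anyNA(rmaps))
    stop(smartsError(sprintf("all reactant atoms must be atom-mapped: '%s'", smirks)))
  if (anyDuplicated(rmaps))
    stop(smartsError(sprintf("duplicate atom map on reactant side: '%s'", smirks)))
  product <- parseSmilesGraph(parts[2], allowDots = TRUE)
  pmaps <- product$atoms$map
  if (anyDuplicated(pmaps[!is.na(pmaps)]))
    stop(smartsError(sprintf("duplicate atom map on product side: '%s'", smirks)))
  extra <- setdiff(pmaps[!is.na(pmaps)], rmaps)
  if (length(extra))
    stop(smartsError(sprintf("product maps %s missing from reactant side: '%s'",
                             paste(extra, collapse = ","), smirks)))
  newAtoms <- which(is.na(pmaps))
  if (any(product$atoms$element[newAtoms] == "*" |
          is.na(product$atoms$aromatic[newAtoms])))
    stop(smartsError(sprintf(
      "unmapped product atoms must use concrete element symbols: '%s'", smirks)))
  structure(list(reactant = reactant, product = product,
                 rmaps = rmaps, smirks = smirks),
            class = "smirksRule")
}

## Apply a compiled SMIRKS at one embedding. `mapping` is the integer
## vector from matchSmarts (reactant pattern atom -> substrate atom).
## Returns a list of product fragment molgraphs.
applySmirksAt <- function(g, rule, mapping, minFragment = 2L) {
  rmaps <- rule$rmaps
  prod <- rule$product
  pmaps <- prod$atoms$map
  molFor <- stats::setNames(mapping, rmaps)   # map number -> substrate atom

  atoms <- g$atoms
  bonds <- g$bonds
  natoms0 <- nrow(atoms)
  touched <- logical(natoms0)

  ## 1. create new (unmapped) product atoms
  prodTarget <- integer(nrow(prod$atoms))     # product atom -> edited-graph atom
  for (i in seq_len(nrow(prod$atoms))) {
    if (is.na(pmaps[i])) {
      atoms <- rbind(atoms, data.frame(
        element = prod$atoms$element[i], aromatic = prod$atoms$aromatic[i],
        charge = prod$atoms$charge[i], hcount = prod$atoms$hcount[i],
        chiral = "", map = NA_integer_,
        stringsAsFactors = FALSE)[, names(atoms), drop = FALSE])
      prodTarget[i] <- nrow(atoms)
    } else {
      prodTarget[i] <- molFor[[as.character(pmaps[i])]]
    }
  }

  ## 2. rewrite mapped survivor atoms
  for (i in seq_len(nrow(prod$atoms))) {
    if (is.na(pmaps[i])) next
    t <- prodTarget[i]
    atoms$charge[t] <- prod$atoms$charge[i]
    atoms$hcount[t] <- NA_integer_
    atoms$chiral[t] <- ""
    if (prod$atoms$element[i] != "*" && !is.na(prod$atoms$aromatic[i]))
      atoms$aromatic[t] <- prod$atoms$aromatic[i]
    touched[t] <- TRUE
  }

  ## 3. deletions: mapped reactant atoms absent from the product
  dead <- unname(molFor[as.character(setdiff(rmaps, pmaps[!is.na(pmaps)]))])

  dropBond <- function(bonds, i, j) {
    keep <- !((bonds$a1 == i & bonds$a2 == j) | (bonds$a1 == j & bonds$a2 == i))
    bonds[keep, , drop = FALSE]
  }

  ## 4. reactant-side bonds between two surviving mapped atoms that the
  ## product omits are broken
  rb <- rule$reactant$bonds
  survivors <- pmaps[!is.na(pmaps)]
  if (nrow(rb)) for (k in seq_len(nrow(rb))) {
    m1 <- rmaps[rb$a1[k]]; m2 <- rmaps[rb$a2[k]]
    if (!(m1 %in% survivors) || !(m2 %in% survivors)) next
    p1 <- which(pmaps == m1); p2 <- which(pmaps == m2)
    hasProdBond <- any((prod$bonds$a1 == p1 & prod$bonds$a2 == p2) |
                       (prod$bonds$a1 == p2 & prod$bonds$a2 == p1))
    if (!hasProdBond) {
      t1 <- molFor[[as.character(m1)]]; t2 <- molFor[[as.character(m2)]]
      bonds <- dropBond(bonds, t1, t2)
      touched[t1] <- TRUE; touched[t2] <- TRUE
    }
  }

  ## 5. product bonds: create or rewrite
  if (nrow(prod$bonds)) for (k in seq_len(nrow(prod$bonds))) {
    t1 <- prodTarget[prod$bonds$a1[k]]
    t2 <- prodTarget[prod$bonds$a2[k]]
    ord <- prod$bonds$order[k]; arom <- prod$bonds$aromatic[k]
    hit <- which((bonds$a1 == t1 & bonds$a2 == t2) |
                 (bonds$a1 == t2 & bonds$a2 == t1))
    if (length(hit)) {
      if (bonds$order[hit[1]] != ord || bonds$aromatic[hit[1]] != arom) {
        bonds$order[hit[1]] <- ord
        bonds$aromatic[hit[1]] <- arom
        if (t1 <= natoms0) touched[t1] <- TRUE
        if (t2 <= natoms0) touched[t2] <- TRUE
      }
    } else {
      bonds <- rbind(bonds, data.frame(a1 = t1, a2 = t2, order = ord,
                                       aromatic = arom))
      if (t1 <= natoms0) touched[t1] <- TRUE
      if (t2 <= natoms0) touched[t2] <- TRUE
    }
  }

  ## 6. delete dead atoms and their bonds; also forget stored H counts on
  ## atoms adjacent to a deletion (their valence changed)
  if (length(dead)) {
    for (d in dead) {
      nb <- c(bonds$a2[bonds$a1 == d], bonds$a1[bonds$a2 == d])
      touched[nb[nb <= natoms0]] <- TRUE
      bonds <- bonds[bonds$a1 != d & bonds$a2 != d, , drop = FALSE]
    }
  }
  touchedFull <- c(touched, rep(FALSE, nrow(atoms) - natoms0))
  atoms$hcount[touchedFull] <- NA_integer_

  gNew <- mgNew(atoms, bonds)
  keep <- setdiff(seq_len(nrow(atoms)), dead)
  gNew <- mgSubgraph(gNew, keep)

  frags <- mgSplit(gNew)
  Filter(function(f) mgHeavyAtoms(f) >= minFragment, frags)
}

## Apply at every embedding. Returns list of per-site product fragment
## lists (one entry per embedding, in match order).
applySmirksAll <- function(g, rule, minFragment = 2L) {
  ctx <- mgMatchContext(g)
  hits <- matchSmarts(g, rule$reactant, ctx)
  lapply(hits, function(m) applySmirksAt(g, rule, m, minFragment))
}
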