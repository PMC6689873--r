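## Internal molecular graph representation.
##
## A "molgraph" is a list(atoms=, bonds=) where
##   atoms: data.frame(element, aromatic, charge, hcount, chiral)
##          hcount NA means "derive implicit hydrogens from valence rules"
##   bonds: data.frame(a1, a2, order, aromatic)
## Hydrogens are always implicit; explicit [H] atoms from input are folded
## into hcount at parse time.

.ALLOWED_VALENCE <- list(
  B = 3L, C = 4L, N = 3L, O = 2L, F = 1L, Si = 4L, P = c(3L, 5L),
  S = c(2L, 4L, 6L), Cl = 1L, Br = 1L, I = 1L, Se = c(2L, 4L, 6L),
  Na = 1L, K = 1L, Mg = 2L, Ca = 2L, Fe = 0L, Zn = 0L
)

.ELEMENT_NUMBER <- c(
  H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L, Mg = 12L,
  Si = 14L, P = 15L, S = 16L, Cl = 17L, K = 19L, Ca = 20L, Fe = 26L,
  Zn = 30L, Se = 34L, Br = 35L, I = 53L
)

mgNew <- function(atoms, bonds) {
  if (is.null(atoms$chiral)) atoms$chiral <- rep("", nrow(atoms))
  structure(list(atoms = atoms, bonds = bonds), class = "molgraph")
}

mgEmptyBonds <- function() {
  data.frame(a1 = integer(0), a2 = integer(0), order = integer(0),
             aromatic = logical(0))
}

mgNumAtoms <- function(g) nrow(g$atoms)

## adjacency: list of integer vectors of neighbour atom indices
mgAdjacency <- function(g) {
  n <- mgNumAtoms(g)
  adj <- vector("list", n)
  if (nrow(g$bonds)) {
    for (k in seq_len(nrow(g$bonds))) {
      i <- g$bonds$a1[k]; j <- g$bonds$a2[k]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  adj
}

## index of bond between i and j, or NA
mgBondBetween <- function(g, i, j) {
  hit <- which((g$bonds$a1 == i & g$bonds$a2 == j) |
               (g$bonds$a1 == j & g$bonds$a2 == i))
  if (length(hit)) hit[1] else NA_integer_
}

## heavy-atom degree per atom
mgDegree <- function(g) {
  n <- mgNumAtoms(g)
  tabulate(c(g$bonds$a1, g$bonds$a2), nbins = n)
}

## Sum of bond orders per atom; aromatic bonds count 1 here, with an extra
## +1 pi increment applied for aromatic C/N/P in mgHydrogens.
mgBondOrderSum <- function(g) {
  n <- mgNumAtoms(g)
  s <- numeric(n)
  if (nrow(g$bonds)) {
    ord <- ifelse(g$bonds$aromatic, 1L, g$bonds$order)
    for (k in seq_len(nrow(g$bonds))) {
      s[g$bonds$a1[k]] <- s[g$bonds$a1[k]] + ord[k]
      s[g$bonds$a2[k]] <- s[g$bonds$a2[k]] + ord[k]
    }
  }
  s
}

## Total hydrogen count per atom (explicit hcount wins, otherwise derived
## from standard valence rules adjusted for charge and aromaticity).
mgHydrogens <- function(g) {
  n <- mgNumAtoms(g)
  bsum <- mgBondOrderSum(g)
  out <- integer(n)
  for (i in seq_len(n)) {
    a <- g$atoms[i, ]
    if (!is.na(a$hcount)) { out[i] <- a$hcount; next }
    el <- a$element
    vals <- .ALLOWED_VALENCE[[el]]
    if (is.null(vals)) { out[i] <- 0L; next }
    extra <- if (isTRUE(a$aromatic) && el %in% c("C", "N", "P")) 1L else 0L
    need <- bsum[i] + extra
    vals <- vals + a$charge * (if (el %in% c("N", "P")) 1L else
                               if (el %in% c("O", "S", "Se")) 1L else 0L)
    vals <- vals[vals >= need]
    out[i] <- if (length(vals)) as.integer(min(vals) - need) else 0L
  }
  out
}

## molecular formula (element counts including hydrogens)
mgFormulaCounts <- function(g) {
  counts <- table(g$atoms$element)
  out <- stats::setNames(as.integer(counts), names(counts))
  h <- sum(mgHydrogens(g))
  out["H"] <- (if ("H" %in% names(out)) out[["H"]] else 0L) + h
  out[out > 0L]
}

mgFormula <- function(g) hillFormula(mgFormulaCounts(g))

mgHeavyAtoms <- function(g) sum(g$atoms$element != "H")

mgIgraph <- function(g) {
  igraph::graph_from_data_frame(
    d = if (nrow(g$bonds)) g$bonds[, c("a1", "a2")] else
      data.frame(a1 = integer(0), a2 = integer(0)),
    directed = FALSE,
    vertices = data.frame(name = seq_len(mgNumAtoms(g))))
}

## component membership vector
mgComponents <- function(g) {
  if (mgNumAtoms(g) == 0L) return(integer(0))
  igraph::components(mgIgraph(g))$membership
}

## logical per atom / per bond: part of a ring
mgRingInfo <- function(g) {
  n <- mgNumAtoms(g)
  if (!nrow(g$bonds))
    return(list(atom = logical(n), bond = logical(0)))
  ig <- mgIgraph(g)
  br <- igraph::bridges(ig)
  bond_in_ring <- !(seq_len(nrow(g$bonds)) %in% as.integer(br))
  atom_in_ring <- logical(n)
  ring_bonds <- which(bond_in_ring)
  atom_in_ring[unique(c(g$bonds$a1[ring_bonds], g$bonds$a2[ring_bonds]))] <- TRUE
  list(atom = atom_in_ring, bond = bond_in_ring)
}

## extract the induced subgraph on a set of atoms (renumbered)
mgSubgraph <- function(g, keep) {
  keep <- sort(keep)
  remap <- integer(mgNumAtoms(g))
  remap[keep] <- seq_along(keep)
  atoms <- g$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  bsel <- g$bonds$a1 %in% keep & g$bonds$a2 %in% keep
  bonds <- g$bonds[bsel, , drop = FALSE]
  bonds$a1 <- remap[bonds$a1]
  bonds$a2 <- remap[bonds$a2]
  rownames(bonds) <- NULL
  mgNew(atoms, bonds)
}

## split into connected components, largest first is NOT guaranteed;
## returns list of molgraphs in component order
mgSplit <- function(g) {
  memb <- mgComponents(g)
  lapply(seq_len(max(memb)), function(k) mgSubgraph(g, which(memb == k)))
}
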