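## filters: CYP450 substrate pre-filter (+ pluggable reactivity classifier)
## and the phase II filter (rule-based pre-filter, 32-descriptor
## featurizer, random-forest harness).

.CYP_ISOZYMES <- c("1A2", "2A6", "2B6", "2C8", "2C9", "2C18/2C19", "2D6",
                   "2E1", "3A4")

.filterConfig <- function(which = c("phase2", "cyp")) {
  which <- match.arg(which)
  opt <- paste0("metabolizr.config.", which)
  cfg <- getOption(opt)
  if (!is.null(cfg)) return(cfg)
  file <- if (which == "phase2") "phase2_filter.json" else "cyp_filter.json"
  cfg <- jsonlite::read_json(system.file("extdata", file,
                                         package = "MetabolizR",
                                         mustWork = TRUE))
  do.call(options, stats::setNames(list(cfg), opt))
  cfg
}

## organic-substructure policy: at least one carbon bearing a hydrogen or
## bonded to another carbon (CO2, carbonates etc. count as inorganic)
.hasOrganicSubstructure <- function(mol) {
  g <- mol@graph
  cs <- which(g$atoms$element == "C")
  if (!length(cs)) return(FALSE)
  hyd <- mgHydrogens(g)
  if (any(hyd[cs] > 0L)) return(TRUE)
  for (i in cs) {
    nb <- c(g$bonds$a2[g$bonds$a1 == i], g$bonds$a1[g$bonds$a2 == i])
    if (any(g$atoms$element[nb] == "C")) return(TRUE)
  }
  FALSE
}

#' CYP450 substrate pre-filter
#'
#' Heuristic eligibility filter for CYP450-mediated metabolism: inorganic
#' compounds (no C-H or C-C bond) and configured excluded classes
#' (glycero- and glycerophospholipids) are out of scope. Eligible
#' molecules receive a per-isozyme reactivity map over the nine major
#' isozymes from the plugged classifier; the default classifier is
#' permissive (all nine TRUE).
#'
#' @param mol a \linkS4class{Molecule}.
#' @param classifier NULL (permissive default) or a
#'   \code{function(mol)} returning a named logical vector over the nine
#'   isozymes.
#' @return list with elements \code{eligible} (logical), \code{reason}
#'   (character, non-empty when ineligible) and \code{reactivity} (named
#'   logical over the isozymes, NULL when ineligible), of class
#'   \code{"CypFilterDecision"}.
#' @export
cypPrefilter <- function(mol, classifier = NULL) {
  stopifnot(is(mol, "Molecule"))
  decision <- function(eligible, reason, reactivity = NULL)
    structure(list(eligible = eligible, reason = reason,
                   reactivity = reactivity), class = "CypFilterDecision")
  if (!.hasOrganicSubstructure(mol))
    return(decision(FALSE, "inorganic (no C-H or C-C substructure)"))
  cfg <- .filterConfig("cyp")
  for (cl in cfg$excluded_classes) {
    if (isTRUE(obSmartsCount(mol@smiles, cl$smarts) > 0L))
      return(decision(FALSE, sprintf("excluded class: %s", cl$name)))
  }
  reactivity <- if (is.null(classifier)) {
    stats::setNames(rep(TRUE, length(.CYP_ISOZYMES)), .CYP_ISOZYMES)
  } else {
    r <- classifier(mol)
    if (!is.logical(r) || length(r) != length(.CYP_ISOZYMES))
      stop(parameterError("classifier must return 9 logical values"))
    stats::setNames(as.logical(r), .CYP_ISOZYMES)
  }
  decision(TRUE, "", reactivity)
}

#' @export
print.CypFilterDecision <- function(x, ...) {
  if (x$eligible) {
    cat("CYP450 substrate filter: eligible\n")
    cat("  reactive isozymes:",
        paste(names(x$reactivity)[x$reactivity], collapse = ", "), "\n")
  } else {
    cat("CYP450 substrate filter: ineligible --", x$reason, "\n")
  }
  invisible(x)
}

#' Phase II rule-based pre-filter
#'
#' FALSE when the molecule belongs to an excluded class (ether lipids,
#' glycerolipids, glycerophospholipids, sphingolipids, acyl-CoA
#' conjugates), weighs more than 900 Da, or carries none of the packaged
#' 64 conjugatable structural motifs; TRUE otherwise. Pure predicate.
#'
#' @param mol a \linkS4class{Molecule}.
#' @return logical(1).
#' @export
phase2Prefilter <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  cfg <- .filterConfig("phase2")
  if (mol@exactMass > cfg$max_mass) return(FALSE)
  for (cl in cfg$excluded_classes)
    if (isTRUE(obSmartsCount(mol@smiles, cl$smarts) > 0L)) return(FALSE)
  for (motif in cfg$motifs)
    if (isTRUE(obSmartsCount(mol@smiles, motif$smarts) > 0L)) return(TRUE)
  FALSE
}

#' Number of motifs in the packaged phase II gate
#' @return integer count of the packaged conjugatable-motif SMARTS list.
#' @export
phase2MotifCount <- function() length(.filterConfig("phase2")$motifs)

## ring counts from the cyclomatic number (bonds - atoms + components)
.ringCounts <- function(g) {
  total <- nrow(g$bonds) - mgNumAtoms(g) + max(c(mgComponents(g), 0L))
  arom_atoms <- which(g$atoms$aromatic)
  arom_bonds <- g$bonds[g$bonds$aromatic, , drop = FALSE]
  if (!length(arom_atoms)) return(c(total = total, aromatic = 0L))
  sub <- mgSubgraph(mgNew(g$atoms, arom_bonds), arom_atoms)
  ncomp <- if (mgNumAtoms(sub)) max(mgComponents(sub)) else 0L
  arom <- nrow(sub$bonds) - mgNumAtoms(sub) + ncomp
  c(total = as.integer(total), aromatic = as.integer(max(arom, 0L)))
}

.ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Phase II feature vector (32 descriptors)
#'
#' Nine constitutional descriptors / molecular properties (monoisotopic
#' mass, ALogP, H-bond donors and acceptors, rotatable bonds, heavy atoms,
#' ring and aromatic ring counts, TPSA) followed by 23 binary structural
#' flags, including the amine and carboxyl SMARTS used verbatim by the
#' published descriptor set. Deterministic and invariant to atom ordering.
#'
#' @param mol a \linkS4class{Molecule}.
#' @return named numeric vector of length 32 (the last 23 entries are 0/1).
#' @export
phase2Features <- function(mol) {
  stopifnot(is(mol, "Molecule"))
  cfg <- .filterConfig("phase2")
  ref <- .obMolRef(mol@smiles)
  props <- if (!is.null(ref))
    tryCatch(ChemmineOB::prop_OB(ref), error = function(e) NULL) else NULL
  hbd <- if (!is.null(props)) as.numeric(props$HBD) else 0
  hba <- if (!is.null(props)) as.numeric(props$HBA2) else 0
  tpsa <- if (!is.null(props)) as.numeric(props$TPSA) else 0
  rot <- obSmartsCount(mol@smiles, .ROTATABLE_SMARTS, unique = TRUE)
  rings <- .ringCounts(mol@graph)
  constitutional <- c(
    exact_mass = mol@exactMass,
    alogp = mol@alogp,
    hbond_donors = hbd,
    hbond_acceptors = hba,
    rotatable_bonds = as.numeric(rot),
    heavy_atoms = as.numeric(heavyAtomCount(mol)),
    ring_count = as.numeric(rings[["total"]]),
    aromatic_ring_count = as.numeric(rings[["aromatic"]]),
    tpsa = tpsa)
  flags <- vapply(cfg$structural_features, function(feat)
    as.numeric(isTRUE(obSmartsCount(mol@smiles, feat$smarts) > 0L)), 0)
  names(flags) <- vapply(cfg$structural_features, `[[`, "", "name")
  c(constitutional, flags)
}

## feature matrix for a list of molecules
.phase2FeatureMatrix <- function(mols) {
  mat <- t(vapply(mols, phase2Features,
                  numeric(9L + length(.filterConfig("phase2")$structural_features))))
  rownames(mat) <- NULL
  mat
}

#' Train the phase II substrate classifier
#'
#' Random forest over \code{\link{phase2Features}} with a fixed seed.
#' The trained model is consumed by \code{\link{predictPhase2}} (class
#' probability, decision threshold 0.5). Without a trained model the
#' phaseII transformer falls back to pre-filter-only gating.
#'
#' @param mols list of \linkS4class{Molecule}.
#' @param labels logical or 0/1 vector: is the molecule a phase II
#'   substrate?
#' @param seed RNG seed for the forest.
#' @param ntree number of trees.
#' @return list(model, featureNames, seed) of class \code{"Phase2Model"}.
#' @export
trainPhase2Model <- function(mols, labels, seed = 1L, ntree = 200L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop(trainingError("training set must contain both classes"))
  if (length(mols) != length(labels))
    stop(parameterError("mols and labels must have equal length"))
  x <- .phase2FeatureMatrix(mols)
  y <- factor(labels, levels = c(0L, 1L))
  set.seed(seed)
  model <- randomForest::randomForest(x = x, y = y, ntree = ntree)
  structure(list(model = model, featureNames = colnames(x), seed = seed),
            class = "Phase2Model")
}

#' @rdname trainPhase2Model
#' @param mol a \linkS4class{Molecule} to score.
#' @param fit a \code{"Phase2Model"}.
#' @return \code{predictPhase2}: probability that the molecule is a phase
#'   II substrate.
#' @export
predictPhase2 <- function(mol, fit) {
  stopifnot(inherits(fit, "Phase2Model"))
  x <- matrix(phase2Features(mol), nrow = 1L,
              dimnames = list(NULL, fit$featureNames))
  as.numeric(stats::predict(fit$model, x, type = "prob")[, "1"])
}

## weighted (by class support) F1 of a binary confusion
.weightedF1 <- function(truth, pred) {
  classes <- sort(unique(truth))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (tp == 0L) return(0)
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    2 * p * r / (p + r)
  }, 0)
  w <- vapply(classes, function(cl) sum(truth == cl), 0)
  sum(f1 * w) / sum(w)
}

#' Cross-validated evaluation of the phase II classifier
#'
#' k-fold cross-validation reporting the weighted F1 measure (threshold
#' 0.5) and the ROC area.
#'
#' @param mols list of \linkS4class{Molecule}.
#' @param labels 0/1 or logical labels.
#' @param folds number of folds (default 10).
#' @param seed RNG seed controlling fold assignment and forests.
#' @param ntree trees per forest.
#' @return list(weighted_f1, roc_auc, folds).
#' @export
evalPhase2CV <- function(mols, labels, folds = 10L, seed = 1L, ntree = 200L) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop(trainingError("evaluation set must contain both classes"))
  x <- .phase2FeatureMatrix(mols)
  y <- factor(labels, levels = c(0L, 1L))
  n <- length(labels)
  set.seed(seed)
  fold <- sample(rep(seq_len(folds), length.out = n))
  prob <- numeric(n)
  for (k in seq_len(folds)) {
    tr <- fold != k
    if (length(unique(labels[tr])) < 2L)
      stop(trainingError("a CV fold lost one of the classes; use more data"))
    set.seed(seed + k)
    m <- randomForest::randomForest(x = x[tr, , drop = FALSE], y = y[tr],
                                    ntree = ntree)
    prob[!tr] <- stats::predict(m, x[!tr, , drop = FALSE],
                                type = "prob")[, "1"]
  }
  pred <- as.integer(prob >= 0.5)
  auc <- as.numeric(pROC::auc(pROC::roc(labels, prob, quiet = TRUE,
                                        direction = "<", levels = c(0L, 1L))))
  list(weighted_f1 = .weightedF1(labels, pred), roc_auc = auc, folds = folds)
}
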