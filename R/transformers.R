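## transformers: the five prediction modules, the human super-transformer
## (allHuman) and the ordered 12-slot superbio pipeline.

.HUMAN_MODULES <- c("ecbased", "cyp450", "phaseII", "hgut")
.ALL_MODULE_OPTIONS <- c(.HUMAN_MODULES, "envmicro", "allHuman", "superbio")
.CONJUGATION_TYPES <- c("Glucuronidation", "Sulfation", "Methylation",
                        "Acetylation")

## The ordered superbio slot sequence: slot = module + optional
## reaction-type restriction. Starts with hydrolysis, ends with
## conjugation; gut deconjugation runs early (deconjugation precedes any
## other transformation of absorbed polyphenols).
.SUPERBIO_SLOTS <- list(
  list(module = "ecbased", types = "Hydrolysis"),
  list(module = "hgut",    types = "Deglycosylation"),
  list(module = "hgut",    types = c("Reduction", "Ring cleavage")),
  list(module = "ecbased", types = "Oxidation"),
  list(module = "cyp450",  types = NULL),
  list(module = "ecbased", types = NULL),
  list(module = "cyp450",  types = NULL),
  list(module = "hgut",    types = NULL),
  list(module = "ecbased", types = NULL),
  list(module = "phaseII", types = c("Methylation", "Acetylation")),
  list(module = "phaseII", types = "Sulfation"),
  list(module = "phaseII", types = "Glucuronidation")
)

## Per-substrate candidate generation for one module, with the module's
## filter chain applied. Returns list of Biotransformation (precedence NOT
## applied here when applyPrecedence = FALSE).
.moduleCandidates <- function(mol, moduleId, kb, step,
                              applyPrecedence = TRUE, reactionTypes = NULL,
                              phase2Model = NULL, cypClassifier = NULL) {
  if (moduleId == "cyp450") {
    dec <- cypPrefilter(mol, cypClassifier)
    if (!dec$eligible) {
      message(sprintf("cyp450 filter: %s not expanded (%s)",
                      mol@inchikey, dec$reason))
      return(list())
    }
    if (!any(dec$reactivity)) return(list())
  }
  if (moduleId == "phaseII") {
    if (!phase2Prefilter(mol)) {
      message(sprintf("phaseII filter: %s not expanded (pre-filter)",
                      mol@inchikey))
      return(list())
    }
    if (!is.null(phase2Model) &&
        predictPhase2(mol, phase2Model) < 0.5) {
      message(sprintf("phaseII filter: %s not expanded (classifier)",
                      mol@inchikey))
      return(list())
    }
  }
  candidateBiotransformations(mol, moduleId, kb,
                              applyPrecedence = applyPrecedence,
                              step = step, reactionTypes = reactionTypes)
}

.asMolecule <- function(mol) {
  if (is(mol, "Molecule")) return(mol)
  standardizeMolecule(mol)
}

#' Run a single prediction module
#'
#' Expands a metabolic tree under one of the five transformer modules.
#' The cyp450 module consults the CYP450 substrate filter, and the phaseII
#' module its rule-based pre-filter (plus the trained classifier when one
#' is supplied) before expanding each substrate; filtered-out substrates
#' yield a root-only tree with a logged reason.
#'
#' @param mol a \linkS4class{Molecule} or a structure string.
#' @param moduleId one of \code{"ecbased"}, \code{"cyp450"},
#'   \code{"phaseII"}, \code{"hgut"}, \code{"envmicro"}, or the
#'   super-transformer options \code{"allHuman"} and \code{"superbio"}
#'   (dispatched to \code{\link{runAllHuman}} / \code{\link{runSuperbio}}).
#' @param nsteps number of biotransformation steps.
#' @param kb knowledgebase; defaults to the packaged human/gut pack, or the
#'   packaged environmental pack for \code{envmicro}.
#' @param phase2Model optional trained \code{"Phase2Model"}.
#' @param cypClassifier optional CYP450 reactivity classifier.
#' @return A \linkS4class{MetabolicTree}.
#' @examples
#' \donttest{
#' tr <- runModule(molecule("CC(=O)Nc1ccc(O)cc1"), "cyp450", nsteps = 1)
#' treeEdges(tr)[, c("child", "ruleName")]
#' }
#' @export
runModule <- function(mol, moduleId, nsteps = 1L, kb = NULL,
                      phase2Model = NULL, cypClassifier = NULL) {
  if (!is.character(moduleId) || length(moduleId) != 1L ||
      !moduleId %in% .ALL_MODULE_OPTIONS)
    stop(parameterError(sprintf(
      "unknown module '%s' (options: %s)", as.character(moduleId)[1],
      paste(.ALL_MODULE_OPTIONS, collapse = ", "))))
  if (moduleId == "allHuman")
    return(runAllHuman(mol, nsteps, kb, phase2Model, cypClassifier))
  if (moduleId == "superbio")
    return(runSuperbio(mol, kb, phase2Model, cypClassifier))
  if (is.null(kb))
    kb <- if (moduleId == "envmicro") envKnowledgebase() else
      defaultKnowledgebase()
  mol <- .rootForModule(mol, moduleId)
  predictTree(mol, moduleId, nsteps, kb, candidateFun = function(m, step)
    .moduleCandidates(m, moduleId, kb, step,
                      phase2Model = phase2Model,
                      cypClassifier = cypClassifier))
}

## Accept inorganic roots (e.g. water under cyp450): they cannot become
## standard molecules, but the module contract is a root-only tree with a
## logged reason, so build the root with the internal constructor.
.rootForModule <- function(mol, moduleId) {
  if (is(mol, "Molecule")) return(mol)
  tryCatch(standardizeMolecule(mol), InorganicRejected = function(e) {
    message(sprintf("%s: inorganic input; returning root-only tree", moduleId))
    can <- obCanonicalSmiles(mol)
    if (is.na(can)) stop(invalidStructure("unparseable structure"))
    .moleculeFromCanonical(can)
  })
}

#' Run all four human transformers at every step (allHuman)
#'
#' At each step the union of ecbased, cyp450, phaseII and hgut candidates
#' (each gated by its own filters) expands the frontier; relative
#' reasoning is applied across the union, and products are deduplicated
#' across modules by InChIKey.
#'
#' @inheritParams runModule
#' @return A \linkS4class{MetabolicTree} with scope \code{"allHuman"}.
#' @export
runAllHuman <- function(mol, nsteps = 1L, kb = NULL, phase2Model = NULL,
                        cypClassifier = NULL) {
  if (is.null(kb)) kb <- defaultKnowledgebase()
  mol <- .asMolecule(mol)
  candidateFun <- function(m, step) {
    cands <- list()
    for (mod in .HUMAN_MODULES)
      cands <- c(cands, .moduleCandidates(m, mod, kb, step,
                                          applyPrecedence = FALSE,
                                          phase2Model = phase2Model,
                                          cypClassifier = cypClassifier))
    filterByPrecedence(cands, kb@precedence)
  }
  predictTree(mol, "allHuman", nsteps, kb, candidateFun = candidateFun)
}

#' Run the ordered human super-transformer (superbio)
#'
#' Executes the fixed 12-slot sequence (each slot a module plus an
#' optional reaction-type restriction), starting with hydrolysis of the
#' query molecule (if applicable) and ending with phase II conjugation of
#' its metabolites. A slot is skipped when nothing applies; edge step
#' indices reflect slot order; conjugation products are terminal (a single
#' conjugation step is simulated).
#'
#' @inheritParams runModule
#' @return A \linkS4class{MetabolicTree} with scope \code{"superbio"};
#'   maximum step index is 12.
#' @export
runSuperbio <- function(mol, kb = NULL, phase2Model = NULL,
                        cypClassifier = NULL) {
  if (is.null(kb)) kb <- defaultKnowledgebase()
  mol <- .asMolecule(mol)
  nodes <- stats::setNames(list(mol), mol@inchikey)
  edges <- .emptyEdges()
  ## bornAt: slot at which a molecule appeared (root: 0); a molecule is
  ## only expanded by slots after its creation; conjugates are terminal
  bornAt <- stats::setNames(0L, mol@inchikey)
  terminal <- stats::setNames(FALSE, mol@inchikey)

  for (slot in seq_along(.SUPERBIO_SLOTS)) {
    cfgSlot <- .SUPERBIO_SLOTS[[slot]]
    pool <- names(nodes)[bornAt < slot & !terminal]
    for (key in sort(pool)) {
      m <- nodes[[key]]
      cands <- .moduleCandidates(m, cfgSlot$module, kb, slot,
                                 applyPrecedence = FALSE,
                                 reactionTypes = cfgSlot$types,
                                 phase2Model = phase2Model,
                                 cypClassifier = cypClassifier)
      cands <- filterByPrecedence(cands, kb@precedence)
      for (bt in cands) {
        isConj <- kb@rules[[bt@ruleId]]@reactionType %in% .CONJUGATION_TYPES
        for (p in bt@products) {
          pk <- p@inchikey
          if (!pk %in% names(nodes)) {
            nodes[[pk]] <- p
            bornAt[pk] <- slot
            terminal[pk] <- isConj
          }
          dup <- edges$parent == key & edges$child == pk &
                 edges$ruleId == bt@ruleId
          if (!any(dup))
            edges <- rbind(edges, data.frame(
              parent = key, child = pk, ruleId = bt@ruleId,
              ruleName = bt@ruleName,
              enzymes = paste(bt@enzymes, collapse = "; "),
              biosystem = bt@biosystem, step = slot,
              stringsAsFactors = FALSE))
        }
      }
    }
  }
  edges <- edges[order(edges$step, edges$ruleId, edges$child, edges$parent), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodeOrder <- c(mol@inchikey, sort(setdiff(names(nodes), mol@inchikey)))
  new("MetabolicTree", root = mol, nodes = nodes[nodeOrder], edges = edges,
      nsteps = length(.SUPERBIO_SLOTS), scope = "superbio")
}

#' Run the environmental microbial transformer
#'
#' Environmental rule subset with its own precedence set (relative
#' reasoning on), predicting all microbial transformations (aerobic and
#' anaerobic consensus rules).
#'
#' @inheritParams runModule
#' @return A \linkS4class{MetabolicTree} with scope \code{"envmicro"}.
#' @export
runEnv <- function(mol, nsteps = 1L, kb = NULL) {
  if (is.null(kb)) kb <- envKnowledgebase()
  runModule(mol, "envmicro", nsteps, kb)
}

#' The module option strings accepted by the engine and the CLI
#' @return character vector of module ids.
#' @export
moduleOptions <- function() .ALL_MODULE_OPTIONS

#' Maximum depth of the superbio pipeline
#' @return integer: the number of slots in the ordered superbio sequence.
#' @export
superbioMaxSteps <- function() length(.SUPERBIO_SLOTS)
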