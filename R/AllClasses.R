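#' @import methods
NULL

#' Standardized small molecule
#'
#' A validated, standardized structure: a single connected organic molecule
#' with perceived aromaticity, neutralized functional-group charges (except
#' internally balanced groups such as nitro), canonical identifiers, Hill
#' formula, monoisotopic mass and an additive logP estimate.
#'
#' @slot smiles canonical SMILES.
#' @slot inchi standard InChI.
#' @slot inchikey standard InChIKey (used as the identity for deduplication
#'   throughout the package).
#' @slot formula Hill-order molecular formula.
#' @slot exactMass monoisotopic mass in Da.
#' @slot alogp additive logP estimate (unitless).
#' @slot label optional user-supplied identifier.
#' @slot graph internal molecular graph (atoms/bonds), not part of the API.
#' @exportClass Molecule
setClass("Molecule", representation(
  smiles = "character",
  inchi = "character",
  inchikey = "character",
  formula = "character",
  exactMass = "numeric",
  alogp = "numeric",
  label = "character",
  graph = "list"
))

setValidity("Molecule", function(object) {
  msgs <- character(0)
  if (length(object@smiles) != 1L || !nzchar(object@smiles))
    msgs <- c(msgs, "smiles must be a non-empty string")
  if (length(object@inchikey) != 1L ||
      !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", object@inchikey))
    msgs <- c(msgs, "inchikey must be a standard 27-character InChIKey")
  g <- object@graph
  if (length(g)) {
    memb <- mgComponents(g)
    if (length(memb) && max(memb) != 1L)
      msgs <- c(msgs, "molecule must have exactly one connected component")
  }
  if (length(msgs)) msgs else TRUE
})

#' Biotransformation rule
#'
#' One generic metabolic reaction: an atom-mapped SMIRKS transform plus
#' separately encoded applicability constraints (required/forbidden SMARTS
#' and property predicates), the catalyzing enzymes, the biosystems in
#' which it operates, and a priority tier for absolute reasoning.
#'
#' @slot id rule identifier (unique within a knowledgebase).
#' @slot name human-readable reaction name.
#' @slot smirks the atom-mapped transform.
#' @slot compiled compiled transform (internal).
#' @slot constraints list of constraint descriptors.
#' @slot enzymes character vector of enzyme ids.
#' @slot biosystems subset of c("human", "gut", "env").
#' @slot modules prediction modules the rule belongs to.
#' @slot reactionType free-text reaction type.
#' @slot priorityTier integer >= 0; all packaged rules share tier 0.
#' @slot massDelta declared stoichiometric formula delta of the principal
#'   product (e.g. "+C6H8O6"), used by mass-balance tests.
#' @exportClass BiotransformationRule
setClass("BiotransformationRule", representation(
  id = "character",
  name = "character",
  smirks = "character",
  compiled = "list",
  constraints = "list",
  enzymes = "character",
  biosystems = "character",
  modules = "character",
  reactionType = "character",
  priorityTier = "integer",
  massDelta = "character"
))

setValidity("BiotransformationRule", function(object) {
  msgs <- character(0)
  if (!length(object@biosystems))
    msgs <- c(msgs, "biosystems must be non-empty")
  if (!all(object@biosystems %in% c("human", "gut", "env")))
    msgs <- c(msgs, "biosystems must be a subset of human/gut/env")
  if (length(object@priorityTier) != 1L || object@priorityTier < 0L)
    msgs <- c(msgs, "priorityTier must be a single integer >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Reaction knowledgebase
#'
#' Rules, enzymes, precedence (relative-reasoning) relations, chemical
#' class-pathway associations and curated biotransformation records loaded
#' from a JSON rule pack.
#'
#' @slot rules named list of \linkS4class{BiotransformationRule}.
#' @slot enzymes data.frame(id, name, ec, family).
#' @slot precedence data.frame(dominant, suppressed, biosystem).
#' @slot pathways list of pathway descriptors.
#' @slot records list of curated biotransformation records.
#' @slot source path the pack was loaded from.
#' @exportClass Knowledgebase
setClass("Knowledgebase", representation(
  rules = "list",
  enzymes = "data.frame",
  precedence = "data.frame",
  pathways = "list",
  records = "list",
  source = "character"
))

#' A single applied biotransformation
#'
#' One reaction event: a substrate converted by a rule into one or more
#' product molecules, with enzyme and biosystem provenance.
#'
#' @slot substrate InChIKey of the substrate.
#' @slot products list of \linkS4class{Molecule}.
#' @slot ruleId id of the applied rule.
#' @slot ruleName name of the applied rule.
#' @slot enzymes enzyme ids.
#' @slot biosystem biosystem in which the reaction occurred.
#' @slot step step index (>= 1) within a metabolic tree.
#' @exportClass Biotransformation
setClass("Biotransformation", representation(
  substrate = "character",
  products = "list",
  ruleId = "character",
  ruleName = "character",
  enzymes = "character",
  biosystem = "character",
  step = "integer"
))

setValidity("Biotransformation", function(object) {
  msgs <- character(0)
  if (!length(object@products))
    msgs <- c(msgs, "a biotransformation must have >= 1 product")
  keys <- vapply(object@products, function(p) p@inchikey, "")
  if (any(keys == object@substrate))
    msgs <- c(msgs, "products must differ from the substrate")
  if (length(msgs)) msgs else TRUE
})

#' Metabolic tree
#'
#' Rooted multi-parent graph of predicted metabolites. Nodes are keyed by
#' InChIKey; edges carry the rule, enzymes, biosystem and step index that
#' produced the child from the parent.
#'
#' @slot root the query \linkS4class{Molecule}.
#' @slot nodes named list of \linkS4class{Molecule}, keyed by InChIKey
#'   (includes the root).
#' @slot edges data.frame(parent, child, ruleId, ruleName, enzymes,
#'   biosystem, step).
#' @slot nsteps number of expansion rounds performed.
#' @slot scope module scope the tree was built under.
#' @exportClass MetabolicTree
setClass("MetabolicTree", representation(
  root = "Molecule",
  nodes = "list",
  edges = "data.frame",
  nsteps = "integer",
  scope = "character"
))

setValidity("MetabolicTree", function(object) {
  msgs <- character(0)
  rk <- object@root@inchikey
  if (!rk %in% names(object@nodes))
    msgs <- c(msgs, "root must be among the nodes")
  nonroot <- setdiff(names(object@nodes), rk)
  if (length(nonroot) && nrow(object@edges)) {
    ## every non-root node reachable from the root
    reach <- rk
    repeat {
      nxt <- unique(object@edges$child[object@edges$parent %in% reach])
      new <- setdiff(nxt, reach)
      if (!length(new)) break
      reach <- c(reach, new)
    }
    if (!all(nonroot %in% reach))
      msgs <- c(msgs, "all non-root nodes must be reachable from the root")
  } else if (length(nonroot)) {
    msgs <- c(msgs, "non-root nodes present but no edges")
  }
  if (anyDuplicated(names(object@nodes)))
    msgs <- c(msgs, "duplicate InChIKey among nodes")
  if (length(msgs)) msgs else TRUE
})
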