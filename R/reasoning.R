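## reasoning: rule application, relative reasoning (precedence), and
## multi-step metabolic tree enumeration.

.SCOPE_BIOSYSTEM <- c(ecbased = "human", cyp450 = "human", phaseII = "human",
                      hgut = "gut", envmicro = "env")

#' Apply one biotransformation rule to a molecule
#'
#' The SMIRKS transform is applied at every matching site. Each site's full
#' product set is kept (including small by-products such as formaldehyde),
#' every product is standardized, products are deduplicated by InChIKey
#' across sites, and products identical to the substrate are dropped.
#' Products that cannot be sanitized are skipped with a warning.
#'
#' @param mol a \linkS4class{Molecule}; \code{ruleApplies(mol, rule)} should
#'   be TRUE (otherwise the result is simply NULL).
#' @param rule a \linkS4class{BiotransformationRule}.
#' @param biosystem biosystem recorded on the resulting event (defaults to
#'   the rule's first biosystem).
#' @param step step index recorded on the resulting event.
#' @return A \linkS4class{Biotransformation}, or NULL when no valid product
#'   remains.
#' @export
applyRule <- function(mol, rule, biosystem = rule@biosystems[1], step = 1L) {
  stopifnot(is(mol, "Molecule"), is(rule, "BiotransformationRule"))
  sites <- applySmirksAll(mol@graph, rule@compiled)
  products <- list()
  for (frags in sites) {
    for (f in frags) {
      smi <- tryCatch(writeSmilesGraph(f), error = function(e) NA_character_)
      can <- if (is.na(smi)) NA_character_ else obCanonicalSmiles(smi)
      if (is.na(can)) {
        warning(sprintf("rule '%s': skipping unsanitizable product of %s",
                        rule@id, mol@inchikey), call. = FALSE)
        next
      }
      pm <- tryCatch(.moleculeFromCanonical(can), error = function(e) NULL)
      if (is.null(pm)) {
        warning(sprintf("rule '%s': skipping unsanitizable product '%s'",
                        rule@id, can), call. = FALSE)
        next
      }
      if (pm@inchikey == mol@inchikey) next
      if (!pm@inchikey %in% names(products)) products[[pm@inchikey]] <- pm
    }
  }
  if (!length(products)) return(NULL)
  products <- products[order(names(products))]
  new("Biotransformation",
      substrate = mol@inchikey, products = unname(products),
      ruleId = rule@id, ruleName = rule@name, enzymes = rule@enzymes,
      biosystem = biosystem, step = as.integer(step))
}

#' Relative reasoning: suppress dominated reactions
#'
#' Given the candidate biotransformations of one substrate at one step, a
#' precedence pair (dominant > suppressed) removes every candidate using
#' the suppressed rule whenever a retained candidate uses the dominant
#' rule. Chains are honored by processing the precedence graph restricted
#' to the present rules in topological order; a cycle among co-applicable
#' rules raises a ReasoningError.
#'
#' @param candidates list of \linkS4class{Biotransformation} (one substrate,
#'   one step).
#' @param precedence data.frame(dominant, suppressed[, biosystem]).
#' @return The retained candidates, in the input order.
#' @export
filterByPrecedence <- function(candidates, precedence) {
  if (!length(candidates) || is.null(precedence) || !nrow(precedence))
    return(candidates)
  ids <- vapply(candidates, function(b) b@ruleId, "")
  present <- unique(ids)
  prec <- precedence[precedence$dominant %in% present &
                     precedence$suppressed %in% present, , drop = FALSE]
  if (!nrow(prec)) return(candidates)

  ## topological order over dominant -> suppressed edges among present rules
  indeg <- stats::setNames(integer(length(present)), present)
  for (i in seq_len(nrow(prec))) indeg[prec$suppressed[i]] <-
    indeg[prec$suppressed[i]] + 1L
  queue <- sort(names(indeg)[indeg == 0L])
  topo <- character(0)
  indeg2 <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    topo <- c(topo, v)
    succ <- prec$suppressed[prec$dominant == v]
    for (w in succ) {
      indeg2[w] <- indeg2[w] - 1L
      if (indeg2[w] == 0L) queue <- sort(c(queue, w))
    }
  }
  if (length(topo) < length(present))
    stop(reasoningError(
      "precedence cycle among co-applicable rules; fix the rule pack"))

  retained <- character(0)
  for (v in topo) {
    dominators <- prec$dominant[prec$suppressed == v]
    if (!length(intersect(dominators, retained))) retained <- c(retained, v)
  }
  candidates[ids %in% retained]
}

## module-scope rule selection incl. chemical class-pathway gates
.rulesForScope <- function(mol, scope, kb) {
  rules <- Filter(function(r) scope %in% r@modules, kb@rules)
  if (!length(rules)) return(list())
  ## pathway gating: a molecule matching a 'restrict' class gate only sees
  ## rules catalyzed by that pathway's enzymes; 'exclude' gates remove the
  ## pathway's rules instead
  restrictEnz <- character(0); restricted <- FALSE
  excludeEnz <- character(0)
  for (pw in kb@pathways) {
    for (gt in pw$class_gates) {
      hit <- isTRUE(obSmartsCount(mol@smiles, gt$smarts) > 0L)
      if (!hit) next
      if (identical(gt$mode, "restrict")) {
        restricted <- TRUE
        restrictEnz <- union(restrictEnz, pw$enzymes)
      } else {
        excludeEnz <- union(excludeEnz, pw$enzymes)
      }
    }
  }
  if (restricted)
    rules <- Filter(function(r) length(intersect(r@enzymes, restrictEnz)) > 0L,
                    rules)
  if (length(excludeEnz))
    rules <- Filter(function(r) !length(intersect(r@enzymes, excludeEnz)),
                    rules)
  rules
}

#' Candidate biotransformations of a molecule under a module scope
#'
#' Evaluates all rules bound to the given module, honors chemical
#' class-pathway gates (class-restricted molecules only see their
#' pathway's rules), applies relative reasoning, and returns the retained
#' events in deterministic order (rule id, then product InChIKey).
#'
#' @param mol a \linkS4class{Molecule}.
#' @param scope one of \code{"ecbased"}, \code{"cyp450"}, \code{"phaseII"},
#'   \code{"hgut"}, \code{"envmicro"}.
#' @param kb a \linkS4class{Knowledgebase}.
#' @param applyPrecedence apply relative reasoning (TRUE for single-module
#'   use; the human super-transformers apply it across the module union
#'   instead).
#' @param step step index recorded on the events.
#' @param reactionTypes optional restriction to a set of reaction types.
#' @return list of \linkS4class{Biotransformation}.
#' @export
candidateBiotransformations <- function(mol, scope, kb = defaultKnowledgebase(),
                                        applyPrecedence = TRUE, step = 1L,
                                        reactionTypes = NULL) {
  scope <- match.arg(scope, names(.SCOPE_BIOSYSTEM))
  rules <- .rulesForScope(mol, scope, kb)
  if (!is.null(reactionTypes))
    rules <- Filter(function(r) r@reactionType %in% reactionTypes, rules)
  rules <- rules[order(vapply(rules, function(r) r@id, ""))]
  out <- list()
  for (r in rules) {
    if (!ruleApplies(mol, r)) next
    bt <- applyRule(mol, r, biosystem = .SCOPE_BIOSYSTEM[[scope]], step = step)
    if (!is.null(bt)) out[[length(out) + 1L]] <- bt
  }
  if (applyPrecedence) out <- filterByPrecedence(out, kb@precedence)
  out
}

#' Predict a metabolic tree
#'
#' Breadth-first enumeration: each round expands only the molecules first
#' produced in the previous round; a molecule is never re-expanded
#' (visited-set on InChIKey); a product converging onto an existing node
#' gains an additional parent edge rather than a duplicate node.
#'
#' @param mol the root \linkS4class{Molecule}.
#' @param scope module scope label stored on the tree.
#' @param nsteps number of expansion rounds (>= 0).
#' @param kb a \linkS4class{Knowledgebase}.
#' @param candidateFun function(mol, step) returning the candidate
#'   biotransformations of one molecule; defaults to
#'   \code{candidateBiotransformations} under \code{scope}. The transformer
#'   modules inject their filter chains and module unions here.
#' @param maxSteps hard cap on nsteps (ParameterError beyond it).
#' @return A \linkS4class{MetabolicTree}.
#' @export
predictTree <- function(mol, scope, nsteps, kb = defaultKnowledgebase(),
                        candidateFun = NULL, maxSteps = 12L) {
  stopifnot(is(mol, "Molecule"))
  if (!is.numeric(nsteps) || length(nsteps) != 1L || is.na(nsteps) ||
      nsteps < 0 || nsteps != floor(nsteps))
    stop(parameterError("nsteps must be a single integer >= 0"))
  if (nsteps > maxSteps)
    stop(parameterError(sprintf("nsteps (%d) exceeds the hard cap of %d",
                                as.integer(nsteps), maxSteps)))
  nsteps <- as.integer(nsteps)
  if (is.null(candidateFun))
    candidateFun <- function(m, step)
      candidateBiotransformations(m, scope, kb, step = step)

  nodes <- stats::setNames(list(mol), mol@inchikey)
  edges <- .emptyEdges()
  frontier <- list(mol)
  visited <- mol@inchikey

  for (step in seq_len(nsteps)) {
    if (!length(frontier)) break
    frontier <- frontier[order(vapply(frontier, function(m) m@inchikey, ""))]
    newKeys <- character(0)
    for (m in frontier) {
      cands <- candidateFun(m, step)
      for (bt in cands) {
        for (p in bt@products) {
          key <- p@inchikey
          if (!key %in% names(nodes)) {
            nodes[[key]] <- p
            newKeys <- c(newKeys, key)
          }
          dup <- edges$parent == m@inchikey & edges$child == key &
                 edges$ruleId == bt@ruleId
          if (!any(dup)) {
            edges <- rbind(edges, data.frame(
              parent = m@inchikey, child = key, ruleId = bt@ruleId,
              ruleName = bt@ruleName,
              enzymes = paste(bt@enzymes, collapse = "; "),
              biosystem = bt@biosystem, step = step,
              stringsAsFactors = FALSE))
          }
        }
      }
    }
    newKeys <- setdiff(unique(newKeys), visited)
    visited <- c(visited, newKeys)
    frontier <- nodes[newKeys]
  }

  edges <- edges[order(edges$step, edges$ruleId, edges$child, edges$parent), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  nodeOrder <- c(mol@inchikey, sort(setdiff(names(nodes), mol@inchikey)))
  new("MetabolicTree", root = mol, nodes = nodes[nodeOrder], edges = edges,
      nsteps = nsteps, scope = scope)
}

.emptyEdges <- function() data.frame(
  parent = character(0), child = character(0), ruleId = character(0),
  ruleName = character(0), enzymes = character(0), biosystem = character(0),
  step = integer(0), stringsAsFactors = FALSE)

#' MetabolicTree accessors
#' @param x a \linkS4class{MetabolicTree}.
#' @return \code{treeNodes}: named list of \linkS4class{Molecule};
#'   \code{treeEdges}: the provenance edge table; \code{rootMolecule}: the
#'   root \linkS4class{Molecule}.
#' @name MetabolicTree-accessors
NULL

#' @rdname MetabolicTree-accessors
#' @export
setMethod("treeNodes", "MetabolicTree", function(x) x@nodes)
#' @rdname MetabolicTree-accessors
#' @export
setMethod("treeEdges", "MetabolicTree", function(x) x@edges)
#' @rdname MetabolicTree-accessors
#' @export
setMethod("rootMolecule", "MetabolicTree", function(x) x@root)

setMethod("show", "MetabolicTree", function(object) {
  cat("MetabolicTree (scope ", object@scope, ", ", object@nsteps,
      " step", if (object@nsteps != 1L) "s", ")\n", sep = "")
  cat("  root: ", object@root@smiles, " [", object@root@inchikey, "]\n",
      sep = "")
  cat(" ", length(object@nodes) - 1L, "metabolites,", nrow(object@edges),
      "edges\n")
})

#' Serialize a metabolic tree to JSON
#'
#' Nodes (with identifiers, formula, mass, logP) and provenance edges, in
#' deterministic order; consumed by the CLI and the identification writer.
#'
#' @param tree a \linkS4class{MetabolicTree}.
#' @param path optional output path; when NULL the JSON string is returned.
#' @return \code{path} (invisibly) or the JSON string.
#' @export
treeToJson <- function(tree, path = NULL) {
  stopifnot(is(tree, "MetabolicTree"))
  nodes <- lapply(tree@nodes, function(m) list(
    inchikey = m@inchikey, smiles = m@smiles, inchi = m@inchi,
    formula = m@formula, monoisotopic_mass = round(m@exactMass, 5),
    alogp = round(m@alogp, 4)))
  doc <- list(scope = tree@scope, nsteps = tree@nsteps,
              root = tree@root@inchikey,
              nodes = unname(nodes), edges = tree@edges)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(as.character(json), path)
  invisible(path)
}
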