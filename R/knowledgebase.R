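## knowledgebase: JSON rule-pack loading, validation and serialization.

.RULE_FIELDS <- c("id", "name", "smirks", "enzymes", "biosystems", "modules",
                  "reaction_type")
.MODULE_IDS <- c("ecbased", "cyp450", "phaseII", "hgut", "envmicro")

#' Load a biotransformation rule pack
#'
#' Reads a JSON rule pack (rules with SMIRKS transforms and separately
#' encoded constraints, enzymes, precedence relations, chemical
#' class-pathway associations, and curated biotransformation records),
#' compiles every SMIRKS/SMARTS, and resolves all cross-references.
#'
#' @param path path to the JSON document.
#' @return A \linkS4class{Knowledgebase}.
#' @seealso \code{\link{defaultKnowledgebase}}, \code{\link{validateKnowledgebase}}
#' @export
loadRulePack <- function(path) {
  if (!file.exists(path))
    stop(schemaError(sprintf("rule pack '%s' not found", path)))
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop(schemaError(
                    sprintf("not valid JSON: %s", conditionMessage(e)))))
  for (key in c("rules", "enzymes"))
    if (is.null(doc[[key]]))
      stop(schemaError("missing required key", pointer = paste0("/", key)))

  enzymes <- do.call(rbind, lapply(seq_along(doc$enzymes), function(i) {
    e <- doc$enzymes[[i]]
    if (is.null(e$id))
      stop(schemaError("enzyme without id", pointer = sprintf("/enzymes/%d", i - 1L)))
    data.frame(id = e$id, name = e$name %||% e$id,
               ec = e$ec %||% NA_character_,
               family = e$family %||% NA_character_,
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(enzymes$id))
    stop(schemaError("duplicate enzyme id", pointer = "/enzymes"))

  rules <- list()
  for (i in seq_along(doc$rules)) {
    r <- doc$rules[[i]]
    ptr <- sprintf("/rules/%d", i - 1L)
    for (f in .RULE_FIELDS)
      if (is.null(r[[f]]))
        stop(schemaError(sprintf("rule missing field '%s'", f), pointer = ptr))
    id <- r$id
    if (id %in% names(rules))
      stop(schemaError(sprintf("duplicate rule id '%s'", id), pointer = ptr))
    compiled <- tryCatch(compileSmirks(r$smirks), error = function(e)
      stop(ruleCompileError(id, conditionMessage(e))))
    constraints <- lapply(seq_along(r$constraints %||% list()), function(j) {
      con <- r$constraints[[j]]
      kind <- con$kind %||% stop(schemaError("constraint without kind",
        pointer = sprintf("%s/constraints/%d", ptr, j - 1L)))
      if (kind %in% c("smarts_required", "smarts_forbidden")) {
        if (is.null(con$smarts) || !obSmartsValid(con$smarts))
          stop(ruleCompileError(id, sprintf("constraint SMARTS does not compile: %s",
                                            con$smarts %||% "<missing>")))
        list(kind = kind, smarts = con$smarts)
      } else if (kind == "property_predicate") {
        prop <- con$property %||% ""
        if (!prop %in% c("mass", "alogp", "heavy_atom_count"))
          stop(schemaError(sprintf("unknown property '%s'", prop),
                           pointer = sprintf("%s/constraints/%d", ptr, j - 1L)))
        thr <- con$threshold
        if (is.null(thr) || !is.finite(as.numeric(thr)))
          stop(schemaError("predicate threshold must be finite",
                           pointer = sprintf("%s/constraints/%d", ptr, j - 1L)))
        cmp <- con$comparator %||% "<="
        if (!cmp %in% c("<=", "<", ">=", ">", "=="))
          stop(schemaError(sprintf("unknown comparator '%s'", cmp),
                           pointer = sprintf("%s/constraints/%d", ptr, j - 1L)))
        list(kind = kind, property = prop, comparator = cmp,
             threshold = as.numeric(thr))
      } else {
        stop(schemaError(sprintf("unknown constraint kind '%s'", kind),
                         pointer = sprintf("%s/constraints/%d", ptr, j - 1L)))
      }
    })
    enz <- unlist(r$enzymes)
    missing <- setdiff(enz, enzymes$id)
    if (length(missing))
      stop(referenceError(sprintf("rule '%s' references unknown enzyme(s): %s",
                                  id, paste(missing, collapse = ", "))))
    bios <- unlist(r$biosystems)
    mods <- unlist(r$modules)
    if (!all(mods %in% .MODULE_IDS))
      stop(schemaError(sprintf("rule '%s' has unknown module tag", id),
                       pointer = ptr))
    rule <- new("BiotransformationRule",
                id = id, name = r$name, smirks = r$smirks,
                compiled = unclass(compiled), constraints = constraints,
                enzymes = as.character(enz), biosystems = as.character(bios),
                modules = as.character(mods),
                reactionType = r$reaction_type,
                priorityTier = as.integer(r$priority_tier %||% 0L),
                massDelta = as.character(r$mass_delta %||% NA_character_))
    rules[[id]] <- rule
  }

  precedence <- if (length(doc$precedence)) do.call(rbind, lapply(
    seq_along(doc$precedence), function(i) {
      p <- doc$precedence[[i]]
      ptr <- sprintf("/precedence/%d", i - 1L)
      if (is.null(p$dominant) || is.null(p$suppressed))
        stop(schemaError("precedence needs dominant and suppressed", pointer = ptr))
      if (identical(p$dominant, p$suppressed))
        stop(schemaError("dominant must differ from suppressed", pointer = ptr))
      for (rid in c(p$dominant, p$suppressed))
        if (!rid %in% names(rules))
          stop(referenceError(sprintf(
            "precedence references unknown rule '%s'", rid)))
      data.frame(dominant = p$dominant, suppressed = p$suppressed,
                 biosystem = p$biosystem %||% NA_character_,
                 stringsAsFactors = FALSE)
    })) else data.frame(dominant = character(0), suppressed = character(0),
                        biosystem = character(0), stringsAsFactors = FALSE)

  pathways <- lapply(seq_along(doc$pathways %||% list()), function(i) {
    pw <- doc$pathways[[i]]
    ptr <- sprintf("/pathways/%d", i - 1L)
    if (is.null(pw$name))
      stop(schemaError("pathway without name", pointer = ptr))
    missing <- setdiff(unlist(pw$enzymes), enzymes$id)
    if (length(missing))
      stop(referenceError(sprintf("pathway '%s' references unknown enzyme(s): %s",
                                  pw$name, paste(missing, collapse = ", "))))
    gates <- lapply(pw$class_gates %||% list(), function(gt) {
      if (is.null(gt$smarts) || !obSmartsValid(gt$smarts))
        stop(schemaError(sprintf("pathway '%s': gate SMARTS does not compile",
                                 pw$name), pointer = ptr))
      list(smarts = gt$smarts, mode = gt$mode %||% "restrict")
    })
    list(name = pw$name, biosystem = pw$biosystem %||% "human",
         enzymes = as.character(unlist(pw$enzymes)), class_gates = gates)
  })

  records <- lapply(seq_along(doc$records %||% list()), function(i) {
    rec <- doc$records[[i]]
    ptr <- sprintf("/records/%d", i - 1L)
    if (!length(rec$product_inchikeys %||% list()))
      stop(schemaError("record needs >= 1 product", pointer = ptr))
    if (!length(rec$citations %||% list()))
      stop(schemaError("record needs >= 1 citation", pointer = ptr))
    list(substrate_inchikey = rec$substrate_inchikey,
         substrate_smiles = rec$substrate_smiles,
         product_inchikeys = as.character(unlist(rec$product_inchikeys)),
         product_smiles = as.character(unlist(rec$product_smiles %||% list())),
         enzyme = rec$enzyme %||% NA_character_,
         reaction_type = rec$reaction_type %||% NA_character_,
         citations = as.character(unlist(rec$citations)))
  })

  new("Knowledgebase", rules = rules, enzymes = enzymes,
      precedence = precedence, pathways = pathways, records = records,
      source = normalizePath(path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Packaged fixture knowledgebases
#'
#' \code{defaultKnowledgebase()} loads the packaged human + human-gut rule
#' pack; \code{envKnowledgebase()} loads the environmental microbial pack.
#' Both are small fixture packs that exercise every engine behaviour; the
#' pack format accommodates much larger rule sets.
#'
#' @return A \linkS4class{Knowledgebase}.
#' @export
defaultKnowledgebase <- function() {
  kb <- getOption("metabolizr.kb.human")
  if (!is.null(kb)) return(kb)
  kb <- loadRulePack(system.file("extdata", "rulepack_human_gut.json",
                                 package = "MetabolizR", mustWork = TRUE))
  options(metabolizr.kb.human = kb)
  kb
}

#' @rdname defaultKnowledgebase
#' @export
envKnowledgebase <- function() {
  kb <- getOption("metabolizr.kb.env")
  if (!is.null(kb)) return(kb)
  kb <- loadRulePack(system.file("extdata", "rulepack_env.json",
                                 package = "MetabolizR", mustWork = TRUE))
  options(metabolizr.kb.env = kb)
  kb
}

#' Knowledgebase accessors
#' @param x a \linkS4class{Knowledgebase}.
#' @return The corresponding component.
#' @name Knowledgebase-accessors
NULL

#' @rdname Knowledgebase-accessors
#' @export
setMethod("kbRules", "Knowledgebase", function(x) x@rules)
#' @rdname Knowledgebase-accessors
#' @export
setMethod("kbEnzymes", "Knowledgebase", function(x) x@enzymes)
#' @rdname Knowledgebase-accessors
#' @export
setMethod("kbPrecedence", "Knowledgebase", function(x) x@precedence)
#' @rdname Knowledgebase-accessors
#' @export
setMethod("kbPathways", "Knowledgebase", function(x) x@pathways)
#' @rdname Knowledgebase-accessors
#' @export
setMethod("kbRecords", "Knowledgebase", function(x) x@records)

setMethod("show", "Knowledgebase", function(object) {
  cat("Knowledgebase:", length(object@rules), "rules,",
      nrow(object@enzymes), "enzymes,",
      nrow(object@precedence), "precedence relations,",
      length(object@pathways), "pathways,",
      length(object@records), "records\n")
  cat("  biosystems:",
      paste(sort(unique(unlist(lapply(object@rules, function(r) r@biosystems)))),
            collapse = ", "), "\n")
})

#' Does a rule apply to a molecule?
#'
#' TRUE iff the rule's SMIRKS reactant pattern matches at least one site
#' AND every required SMARTS constraint matches AND no forbidden SMARTS
#' matches AND every property predicate holds. Pure predicate: no state.
#'
#' @param mol a \linkS4class{Molecule} (standardized).
#' @param rule a \linkS4class{BiotransformationRule}.
#' @return logical(1).
#' @export
ruleApplies <- function(mol, rule) {
  stopifnot(is(mol, "Molecule"), is(rule, "BiotransformationRule"))
  for (con in rule@constraints) {
    ok <- switch(con$kind,
      smarts_required = isTRUE(obSmartsCount(mol@smiles, con$smarts) > 0L),
      smarts_forbidden = isTRUE(obSmartsCount(mol@smiles, con$smarts) == 0L),
      property_predicate = {
        val <- switch(con$property,
                      mass = mol@exactMass,
                      alogp = mol@alogp,
                      heavy_atom_count = heavyAtomCount(mol))
        do.call(con$comparator, list(val, con$threshold))
      })
    if (!isTRUE(ok)) return(FALSE)
  }
  hits <- matchSmarts(mol@graph, rule@compiled$reactant, limit = 1L)
  length(hits) > 0L
}

#' Validate a knowledgebase
#'
#' Reports structural issues that are legal but suspicious: rules not
#' referenced by any module, precedence cycles, and enzymes with no rules.
#' Packaged fixture packs produce an empty report.
#'
#' @param kb a \linkS4class{Knowledgebase}.
#' @return data.frame(kind, subject, message); zero rows when clean.
#' @export
validateKnowledgebase <- function(kb) {
  stopifnot(is(kb, "Knowledgebase"))
  issues <- list()
  addIssue <- function(kind, subject, message)
    issues[[length(issues) + 1L]] <<- data.frame(kind = kind, subject = subject,
                                                 message = message,
                                                 stringsAsFactors = FALSE)
  for (r in kb@rules)
    if (!length(r@modules))
      addIssue("orphan_rule", r@id, "rule not referenced by any module")
  used <- unique(unlist(lapply(kb@rules, function(r) r@enzymes)))
  for (eid in setdiff(kb@enzymes$id, used)) {
    inPathway <- any(vapply(kb@pathways, function(p) eid %in% p$enzymes, NA))
    if (!inPathway)
      addIssue("orphan_enzyme", eid, "enzyme has no associated rule")
  }
  ## precedence cycles (DFS over dominant -> suppressed edges)
  if (nrow(kb@precedence)) {
    adj <- split(kb@precedence$suppressed, kb@precedence$dominant)
    state <- new.env(parent = emptyenv())
    cyc <- character(0)
    visit <- function(v, stack) {
      st <- state[[v]]
      if (identical(st, "done")) return()
      if (identical(st, "open")) {
        cyc <<- union(cyc, v)
        return()
      }
      assign(v, "open", envir = state)
      for (w in adj[[v]] %||% character(0)) visit(w, c(stack, v))
      assign(v, "done", envir = state)
    }
    for (v in unique(kb@precedence$dominant)) visit(v, character(0))
    for (v in cyc)
      addIssue("precedence_cycle", v, "rule participates in a precedence cycle")
  }
  if (length(issues)) do.call(rbind, issues) else
    data.frame(kind = character(0), subject = character(0),
               message = character(0), stringsAsFactors = FALSE)
}

#' Serialize a knowledgebase back to rule-pack JSON
#'
#' \code{loadRulePack(saveRulePack(kb, path))} is structurally identical to
#' \code{kb} (modulo the source path).
#'
#' @param kb a \linkS4class{Knowledgebase}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
saveRulePack <- function(kb, path) {
  stopifnot(is(kb, "Knowledgebase"))
  doc <- list(
    enzymes = lapply(seq_len(nrow(kb@enzymes)), function(i) {
      e <- kb@enzymes[i, ]
      out <- list(id = e$id, name = e$name)
      if (!is.na(e$ec)) out$ec <- e$ec
      if (!is.na(e$family)) out$family <- e$family
      out
    }),
    rules = lapply(unname(kb@rules), function(r) {
      out <- list(id = r@id, name = r@name, smirks = r@smirks,
                  enzymes = as.list(r@enzymes),
                  biosystems = as.list(r@biosystems),
                  modules = as.list(r@modules),
                  reaction_type = r@reactionType,
                  priority_tier = r@priorityTier)
      if (length(r@constraints)) out$constraints <- r@constraints
      if (!is.na(r@massDelta)) out$mass_delta <- r@massDelta
      out
    }),
    precedence = lapply(seq_len(nrow(kb@precedence)), function(i) {
      p <- kb@precedence[i, ]
      out <- list(dominant = p$dominant, suppressed = p$suppressed)
      if (!is.na(p$biosystem)) out$biosystem <- p$biosystem
      out
    }),
    pathways = lapply(kb@pathways, function(pw) {
      list(name = pw$name, biosystem = pw$biosystem,
           enzymes = as.list(pw$enzymes),
           class_gates = lapply(pw$class_gates, function(gt)
             list(smarts = gt$smarts, mode = gt$mode)))
    }),
    records = kb@records
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

## parse a signed stoichiometric delta like "+C6H8O6", "-CH2", "+O-S" into
## a named integer vector of element count changes
parseMassDelta <- function(delta) {
  if (is.na(delta) || !nzchar(delta)) return(stats::setNames(integer(0), character(0)))
  m <- gregexpr("[+-][A-Za-z0-9]+", delta)
  segs <- regmatches(delta, m)[[1]]
  if (!length(segs) || sum(attr(m[[1]], "match.length")) != nchar(delta))
    stop(formulaError(sprintf("cannot parse mass delta '%s'", delta)))
  out <- integer(0)
  for (seg in segs) {
    sign <- if (substr(seg, 1, 1) == "+") 1L else -1L
    counts <- parseFormula(substr(seg, 2, nchar(seg)))
    for (el in names(counts)) {
      out[el] <- (if (el %in% names(out)) out[[el]] else 0L) + sign * counts[[el]]
    }
  }
  out[out != 0L]
}
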