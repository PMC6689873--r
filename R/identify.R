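## identify: MS-driven metabolite identification against predicted
## metabolic trees.

.PROTON_OFFSET <- 1.00727  # Da, [M+H]+ positive-mode offset

#' Neutral monoisotopic mass from a protonated molecular ion
#'
#' Converts an [M+H]+ ion m/z to the neutral monoisotopic mass by
#' subtracting 1.00727 Da. Exact inverse of adding the offset.
#'
#' @param mz ion m/z in Da (numeric vector allowed).
#' @param adduct only \code{"[M+H]+"} is supported.
#' @return neutral mass(es) in Da.
#' @examples
#' neutralMassFromIon(291.08631)  # 290.07904, epicatechin
#' @export
neutralMassFromIon <- function(mz, adduct = "[M+H]+") {
  if (!identical(adduct, "[M+H]+"))
    stop(parameterError("only the [M+H]+ adduct is supported"))
  if (any(!is.finite(mz)) || any(mz <= .PROTON_OFFSET))
    stop(parameterError(sprintf("ion m/z must exceed the %.5f Da offset",
                                .PROTON_OFFSET)))
  mz - .PROTON_OFFSET
}

## expand one round under the identification scopes
.identifyStepTree <- function(mol, scope, k, kb, ...) {
  switch(scope,
    allHuman = runAllHuman(mol, nsteps = k, kb = kb, ...),
    superbio = runSuperbio(mol, kb = kb, ...),
    envmicro = runModule(mol, "envmicro", nsteps = k, kb = kb))
}

## earliest-parent pathway from the root to `key`, as
## data.frame(step, reaction, enzymes)
.pathwayTo <- function(tree, key) {
  edges <- tree@edges
  root <- tree@root@inchikey
  chain <- list()
  cur <- key
  guard <- 0L
  while (cur != root) {
    inc <- edges[edges$child == cur, , drop = FALSE]
    if (!nrow(inc)) break
    inc <- inc[order(inc$step, inc$ruleId, inc$parent), , drop = FALSE]
    e <- inc[1, ]
    chain[[length(chain) + 1L]] <- e
    cur <- e$parent
    guard <- guard + 1L
    if (guard > nrow(edges)) break
  }
  if (!length(chain)) return(NULL)
  path <- do.call(rbind, rev(chain))
  data.frame(step = seq_len(nrow(path)), reaction = path$ruleName,
             enzymes = path$enzymes, stringsAsFactors = FALSE)
}

#' Identify metabolites matching MS-derived masses or formulas
#'
#' Expands the metabolic tree of a starting molecule step by step under
#' the chosen scope. After each step the newly produced metabolites are
#' tested against every still-unmatched target (inclusive absolute mass
#' tolerance in Da, or exact neutral Hill-formula equality); expansion
#' stops early once every target has at least one match, or when
#' \code{steps} rounds have run. All isobaric matches of a target found in
#' the same round are reported (regioisomeric conjugates share one mass).
#' The query molecule itself is never a match.
#'
#' @param mol starting \linkS4class{Molecule} or structure string.
#' @param masses numeric vector of neutral monoisotopic masses (Da).
#' @param formulas character vector of molecular formulas.
#' @param tolerance absolute mass tolerance in Da (default 0.01).
#' @param steps maximum number of biotransformation steps (default 1).
#' @param scope \code{"allHuman"}, \code{"superbio"} or \code{"envmicro"}.
#' @param kb optional knowledgebase override.
#' @return An object of class \code{"IdentificationResult"}: list with the
#'   query molecule, the scope/tolerance used, the final
#'   \linkS4class{MetabolicTree}, and per-target match lists (metabolite,
#'   pathway from the root, step count).
#' @export
identifyMetabolites <- function(mol, masses = NULL, formulas = NULL,
                                tolerance = 0.01, steps = 1L,
                                scope = c("allHuman", "superbio", "envmicro"),
                                kb = NULL) {
  scope <- match.arg(scope)
  if (is.null(masses) && is.null(formulas))
    stop(parameterError("provide masses and/or formulas"))
  if (!is.null(tolerance) && (!is.numeric(tolerance) || tolerance <= 0))
    stop(parameterError("tolerance must be > 0"))
  if (!is.numeric(steps) || steps < 1L)
    stop(parameterError("steps must be >= 1"))
  mol <- .asMolecule(mol)
  if (is.null(kb))
    kb <- if (scope == "envmicro") envKnowledgebase() else defaultKnowledgebase()

  targets <- c(
    lapply(masses %||% numeric(0), function(m)
      list(type = "mass", value = as.numeric(m))),
    lapply(formulas %||% character(0), function(f)
      list(type = "formula", value = as.character(f))))
  matches <- vector("list", length(targets))
  unmatched <- rep(TRUE, length(targets))

  seen <- mol@inchikey
  maxRounds <- if (scope == "superbio") 1L else as.integer(steps)
  tree <- NULL
  for (k in seq_len(maxRounds)) {
    tree <- .identifyStepTree(mol, scope, k, kb)
    newKeys <- setdiff(names(tree@nodes), seen)
    if (!length(newKeys) && k > 1L) break
    stillUnmatched <- which(unmatched)
    for (key in sort(newKeys)) {
      node <- tree@nodes[[key]]
      for (ti in stillUnmatched) {
        tg <- targets[[ti]]
        hit <- if (tg$type == "mass") {
          abs(node@exactMass - tg$value) <= tolerance
        } else {
          identical(node@formula, tg$value)
        }
        if (hit) {
          pw <- .pathwayTo(tree, key)
          matches[[ti]] <- c(matches[[ti]], list(list(
            metabolite = node, pathway = pw,
            steps = if (is.null(pw)) NA_integer_ else nrow(pw))))
          unmatched[ti] <- FALSE
        }
      }
    }
    seen <- union(seen, newKeys)
    if (!any(unmatched)) break
  }

  structure(list(query = mol, scope = scope, tolerance = tolerance,
                 steps = steps, tree = tree,
                 targets = lapply(seq_along(targets), function(i)
                   list(target = targets[[i]],
                        matches = matches[[i]] %||% list()))),
            class = "IdentificationResult")
}

#' @export
print.IdentificationResult <- function(x, ...) {
  cat("Metabolite identification (", x$scope, ", tolerance ",
      x$tolerance, " Da)\n", sep = "")
  cat("  query:", x$query@smiles, "\n")
  for (t in x$targets) {
    lbl <- if (t$target$type == "mass")
      sprintf("mass %.5f", t$target$value) else
      sprintf("formula %s", t$target$value)
    cat(sprintf("  %-22s %d match(es)\n", lbl, length(t$matches)))
  }
  invisible(x)
}

#' Write identification results to an SDF file
#'
#' One SDF record per matched metabolite. The pathway is stored as a
#' numbered data field listing \code{"reaction name [enzyme1; enzyme2]"}
#' lines in step order, together with the matched target value and the
#' mass deviation. Output is byte-stable for identical queries.
#'
#' @param result an \code{"IdentificationResult"}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeIdentification <- function(result, path) {
  stopifnot(inherits(result, "IdentificationResult"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(mkCondition("IOError", sprintf("cannot open '%s'", path))))
  on.exit(close(con))
  out <- character(0)
  rec <- 0L
  for (t in result$targets) {
    for (m in t$matches) {
      rec <- rec + 1L
      node <- m$metabolite
      mb <- obMolBlock(node@smiles, title = sprintf("MATCH%04d", rec))
      if (is.na(mb)) next
      fields <- c(
        "Query" = result$query@smiles,
        "QueryInChIKey" = result$query@inchikey,
        "TargetType" = t$target$type,
        "TargetValue" = as.character(t$target$value),
        "InChIKey" = node@inchikey,
        "InChI" = node@inchi,
        "MolecularFormula" = node@formula,
        "MonoisotopicMass" = sprintf("%.5f", node@exactMass),
        "MassDelta" = if (t$target$type == "mass")
          sprintf("%+.5f", node@exactMass - t$target$value) else "0",
        "StepCount" = as.character(m$steps),
        "Pathway" = paste(sprintf("%d. %s [%s]", m$pathway$step,
                                  m$pathway$reaction, m$pathway$enzymes),
                          collapse = "\n"))
      out <- c(out, mb)
      for (fn in names(fields))
        out <- c(out, sprintf("> <%s>", fn), fields[[fn]], "")
      out <- c(out, "$$$$")
    }
  }
  writeLines(out, con, sep = "\n")
  invisible(path)
}
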