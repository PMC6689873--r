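## cli_io support: annotation assembly and SDF/CSV/JSON writers.

.ANNOTATION_COLUMNS <- c(
  "MetaboliteID", "InChI", "InChIKey", "MolecularFormula",
  "MonoisotopicMass", "ReactionType", "Biosystem", "Enzymes",
  "ParentID", "ParentInChIKey", "ParentMonoisotopicMass",
  "ALogP", "ParentALogP", "Synonyms", "SMILES", "Step")

.synonymTable <- function() {
  syn <- getOption("metabolizr.synonyms")
  if (!is.null(syn)) return(syn)
  doc <- jsonlite::read_json(system.file("extdata", "synonyms.json",
                                         package = "MetabolizR",
                                         mustWork = TRUE))
  syn <- lapply(doc$synonyms, function(x) as.character(unlist(x)))
  options(metabolizr.synonyms = syn)
  syn
}

#' Offline synonym lookup for an InChIKey
#' @param inchikey a standard InChIKey.
#' @return character vector of names (possibly empty).
#' @export
lookupSynonyms <- function(inchikey) {
  syn <- .synonymTable()
  syn[[inchikey]] %||% character(0)
}

#' Annotate the metabolites of a tree
#'
#' Builds the per-metabolite annotation table: chemical identifiers
#' (deterministic metabolite ID, InChI, InChIKey), molecular formula,
#' monoisotopic mass, reaction type, biosystem, parent identifiers and
#' monoisotopic mass, metabolite and parent ALogP, and synonyms.
#' Metabolite IDs are \code{"BTM"} plus a zero-padded ordinal, assigned by
#' sorted traversal (step of first appearance, then InChIKey), so they are
#' stable across runs for identical inputs. The root is BTM0000 with empty
#' parent fields. Convergent metabolites are annotated from their earliest
#' (step, rule id, parent) edge.
#'
#' @param tree a \linkS4class{MetabolicTree}.
#' @return data.frame with one row per node (root included).
#' @export
annotateTree <- function(tree) {
  stopifnot(is(tree, "MetabolicTree"))
  edges <- tree@edges
  rootKey <- tree@root@inchikey
  keys <- setdiff(names(tree@nodes), rootKey)
  firstStep <- vapply(keys, function(k) {
    inc <- edges$step[edges$child == k]
    if (length(inc)) min(inc) else NA_integer_
  }, 0L)
  keys <- keys[order(firstStep, keys)]
  ids <- stats::setNames(sprintf("BTM%04d", seq_along(keys)), keys)
  ids[rootKey] <- "BTM0000"

  rowFor <- function(key) {
    m <- tree@nodes[[key]]
    if (key == rootKey) {
      e <- NULL
    } else {
      inc <- edges[edges$child == key, , drop = FALSE]
      inc <- inc[order(inc$step, inc$ruleId, inc$parent), , drop = FALSE]
      e <- inc[1, ]
    }
    parent <- if (is.null(e)) NULL else tree@nodes[[e$parent]]
    syn <- lookupSynonyms(m@inchikey)
    data.frame(
      MetaboliteID = unname(ids[key]),
      InChI = m@inchi,
      InChIKey = m@inchikey,
      MolecularFormula = m@formula,
      MonoisotopicMass = round(m@exactMass, 5),
      ReactionType = if (is.null(e)) "" else e$ruleName,
      Biosystem = if (is.null(e)) "" else e$biosystem,
      Enzymes = if (is.null(e)) "" else e$enzymes,
      ParentID = if (is.null(e)) "" else unname(ids[e$parent]),
      ParentInChIKey = if (is.null(e)) "" else e$parent,
      ParentMonoisotopicMass = if (is.null(parent)) NA_real_ else
        round(parent@exactMass, 5),
      ALogP = round(m@alogp, 4),
      ParentALogP = if (is.null(parent)) NA_real_ else round(parent@alogp, 4),
      Synonyms = paste(syn, collapse = "; "),
      SMILES = m@smiles,
      Step = if (is.null(e)) 0L else e$step,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(c(rootKey, keys), rowFor))
  rownames(out) <- NULL
  out[, .ANNOTATION_COLUMNS]
}

#' Write annotated metabolites to SDF, CSV or JSON
#'
#' SDF carries each annotation as a named data field; CSV holds one row
#' per metabolite with the frozen annotation column set; JSON mirrors the
#' tree structure (nodes + provenance edges). Records are ordered by
#' metabolite ID, so identical inputs produce byte-identical files.
#'
#' @param annotated annotation table from \code{\link{annotateTree}} (or a
#'   \linkS4class{MetabolicTree}, which is annotated on the fly).
#' @param format \code{"sdf"}, \code{"csv"} or \code{"json"}.
#' @param path output path.
#' @param tree the source tree; required for \code{format = "json"} when
#'   \code{annotated} is a plain table.
#' @return \code{path}, invisibly.
#' @export
writeStructures <- function(annotated, format = c("sdf", "csv", "json"),
                            path, tree = NULL) {
  format <- match.arg(format)
  if (is(annotated, "MetabolicTree")) {
    tree <- annotated
    annotated <- annotateTree(tree)
  }
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop(mkCondition("IOError", sprintf("directory '%s' does not exist", dir)))
  annotated <- annotated[order(annotated$MetaboliteID), , drop = FALSE]
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.csv(annotated, con, row.names = FALSE, fileEncoding = "UTF-8")
  } else if (format == "json") {
    if (is.null(tree))
      stop(parameterError("JSON output requires the source tree"))
    treeToJson(tree, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    out <- character(0)
    dataCols <- setdiff(.ANNOTATION_COLUMNS, "SMILES")
    for (i in seq_len(nrow(annotated))) {
      row <- annotated[i, ]
      mb <- obMolBlock(row$SMILES, title = row$MetaboliteID)
      if (is.na(mb)) next
      out <- c(out, mb)
      for (col in dataCols) {
        val <- row[[col]]
        val <- if (is.na(val)) "" else as.character(val)
        out <- c(out, sprintf("> <%s>", col), val, "")
      }
      out <- c(out, "$$$$")
    }
    writeLines(out, con, sep = "\n")
  }
  invisible(path)
}

#' The frozen annotation column set
#' @return character vector of CSV column / SDF data-field names.
#' @export
annotationColumns <- function() .ANNOTATION_COLUMNS
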