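## chem_core: parsing, validation, standardization and identifiers.

.NEUTRALIZE_EXCEPTIONS <- c(
  nitro = "[O-][N+](=O)",
  n_oxide = "[O-][N+;X4]",
  aromatic_n_oxide = "[O-][n+]"
)

#' Parse molecular structure input
#'
#' Reads one or more raw structures from text or a file. SMILES and InChI
#' inputs hold a single molecule per string; MOL holds one record; SDF may
#' hold multiple records. Records that cannot be parsed are reported as
#' indexed errors without aborting the batch.
#'
#' @param source a character string (structure text) or path to a file.
#' @param format one of \code{"auto"}, \code{"smiles"}, \code{"inchi"},
#'   \code{"mol"}, \code{"sdf"}. \code{"auto"} infers from a file extension
#'   or from the text itself.
#' @return A list with elements \code{structures} (list of raw records,
#'   each \code{list(smiles, label, index)}) and \code{errors} (list of
#'   \code{list(index, message)}).
#' @export
parseInput <- function(source, format = c("auto", "smiles", "inchi", "mol", "sdf")) {
  format <- match.arg(format)
  isFile <- length(source) == 1L && !grepl("\n", source) && file.exists(source) &&
    !dir.exists(source)
  if (format == "auto") {
    if (isFile) {
      ext <- tolower(tools::file_ext(source))
      format <- switch(ext, sdf = "sdf", mol = "mol", smi = "smiles",
                       smiles = "smiles", inchi = "inchi",
                       stop(parameterError(sprintf(
                         "cannot infer format from extension '.%s'", ext))))
    } else {
      format <- if (grepl("^InChI=", trimws(source[1]))) "inchi" else "smiles"
    }
  }

  structures <- list(); errors <- list()
  push <- function(smi, label, idx) {
    if (is.na(smi)) {
      errors[[length(errors) + 1L]] <<- list(index = idx,
                                             message = "unparseable record")
    } else {
      structures[[length(structures) + 1L]] <<-
        list(smiles = smi, label = label, index = idx)
    }
  }

  if (format %in% c("smiles", "inchi")) {
    txt <- if (isFile) readLines(source, warn = FALSE) else
      strsplit(source, "\n", fixed = TRUE)[[1]]
    txt <- txt[nzchar(trimws(txt))]
    if (!length(txt)) return(list(structures = list(), errors = list()))
    for (i in seq_along(txt)) {
      fields <- strsplit(trimws(txt[i]), "[\t ]+")[[1]]
      body <- fields[1]
      label <- if (length(fields) > 1L) paste(fields[-1], collapse = " ") else
        NA_character_
      smi <- if (format == "inchi") {
        out <- obConvert("INCHI", "CAN", body)
        if (!is.na(out)) sub("\t.*$", "", out) else out
      } else obCanonicalSmiles(body)
      push(smi, label, i)
    }
  } else if (format == "mol") {
    txt <- if (isFile) paste(readLines(source, warn = FALSE), collapse = "\n")
           else source
    out <- obConvert("MOL", "CAN", txt)
    label <- trimws(strsplit(txt, "\n")[[1]][1])
    if (!nzchar(label)) label <- NA_character_
    push(if (!is.na(out)) sub("\t.*$", "", out) else out, label, 1L)
  } else {  # sdf
    if (!isFile)
      stop(parameterError("SDF input must be a file path"))
    ## ChemmineR splits the multi-record file; OpenBabel parses each record
    sdfstr <- ChemmineR::read.SDFstr(source)
    blocks <- as(sdfstr, "list")
    for (i in seq_along(blocks)) {
      lines <- blocks[[i]]
      out <- obConvert("MOL", "CAN", paste(lines, collapse = "\n"))
      label <- trimws(lines[1])
      if (!nzchar(label)) label <- NA_character_
      push(if (!is.na(out)) sub("\t.*$", "", out) else out, label, i)
    }
  }
  list(structures = structures, errors = errors)
}

## neutralize charges towards net zero; exception patterns protect
## internally balanced groups (nitro, N-oxides)
.neutralizeGraph <- function(g, exceptions = .NEUTRALIZE_EXCEPTIONS) {
  net <- sum(g$atoms$charge)
  if (net == 0L) return(g)
  protected <- integer(0)
  for (pat in exceptions) {
    hits <- tryCatch(matchSmarts(g, pat), error = function(e) list())
    protected <- union(protected, unlist(hits))
  }
  repeat {
    net <- sum(g$atoms$charge)
    if (net == 0L) break
    hyd <- mgHydrogens(g)
    if (net < 0L) {
      site <- which(g$atoms$charge < 0L &
                    g$atoms$element %in% c("O", "S", "N") &
                    !seq_len(mgNumAtoms(g)) %in% protected)
      if (!length(site)) break
      i <- site[1]
      g$atoms$charge[i] <- g$atoms$charge[i] + 1L
      g$atoms$hcount[i] <- NA_integer_
    } else {
      site <- which(g$atoms$charge > 0L & g$atoms$element %in% c("N", "P") &
                    hyd > 0L &
                    !seq_len(mgNumAtoms(g)) %in% protected)
      if (!length(site)) break
      i <- site[1]
      g$atoms$charge[i] <- g$atoms$charge[i] - 1L
      g$atoms$hcount[i] <- NA_integer_
    }
  }
  g
}

## Internal constructor from a SMILES already known to be a single fragment
.moleculeFromCanonical <- function(can, label = NA_character_) {
  g <- parseSmilesGraph(can)
  inchi <- obInChI(can)
  ikey <- obInChIKey(can)
  if (is.na(inchi) || is.na(ikey))
    stop(invalidStructure(sprintf("cannot derive InChI for '%s'", can)))
  formula <- mgFormula(g)
  new("Molecule",
      smiles = can, inchi = inchi, inchikey = ikey,
      formula = formula,
      exactMass = unname(monoisotopicMass(formula)),
      alogp = obLogP(can),
      label = if (is.na(label)) NA_character_ else as.character(label),
      graph = unclass(g))
}

#' Standardize a raw structure into a Molecule
#'
#' Validates and standardizes a structure: rejects mixtures/salts and
#' inorganic (carbon-free) input, neutralizes functional-group charges
#' towards net zero (internally balanced groups such as nitro and N-oxides
#' are kept charge-separated), re-canonicalizes, and computes identifiers,
#' Hill formula, monoisotopic mass and logP.
#'
#' @param x a SMILES/InChI string, or a raw record from
#'   \code{\link{parseInput}}.
#' @param label optional identifier carried through to outputs.
#' @return A \linkS4class{Molecule}.
#' @examples
#' \donttest{
#' m <- standardizeMolecule("[O-]c1ccccc1")   # phenolate -> phenol
#' molFormula(m)                              # "C6H6O"
#' }
#' @export
standardizeMolecule <- function(x, label = NA_character_) {
  if (is.list(x)) {
    if (!is.null(x$label) && !is.na(x$label) && is.na(label)) label <- x$label
    x <- x$smiles
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("^InChI=", trimws(x))) {
    out <- obConvert("INCHI", "CAN", trimws(x))
    x <- if (!is.na(out)) sub("\t.*$", "", out) else NA_character_
    if (is.na(x)) stop(invalidStructure("unparseable InChI"))
  }
  can <- obCanonicalSmiles(x)
  if (is.na(can)) stop(invalidStructure(sprintf("unparseable structure '%s'", x)))
  if (grepl(".", can, fixed = TRUE)) stop(mixtureRejected())
  g <- parseSmilesGraph(can)
  if (!any(g$atoms$element == "C")) stop(inorganicRejected())
  g2 <- .neutralizeGraph(g)
  if (!identical(g2$atoms$charge, g$atoms$charge)) {
    can <- obCanonicalSmiles(writeSmilesGraph(g2))
    if (is.na(can))
      stop(invalidStructure("structure invalid after charge neutralization"))
  }
  .moleculeFromCanonical(can, label)
}

#' @describeIn standardizeMolecule shorthand constructor from SMILES.
#' @export
molecule <- function(x, label = NA_character_) standardizeMolecule(x, label)

#' Accessors for Molecule objects
#'
#' @param x a \linkS4class{Molecule}.
#' @return The corresponding slot value.
#' @name Molecule-accessors
NULL

#' @rdname Molecule-accessors
#' @export
setMethod("smiles", "Molecule", function(x) x@smiles)
#' @rdname Molecule-accessors
#' @export
setMethod("inchi", "Molecule", function(x) x@inchi)
#' @rdname Molecule-accessors
#' @export
setMethod("inchikey", "Molecule", function(x) x@inchikey)
#' @rdname Molecule-accessors
#' @export
setMethod("molFormula", "Molecule", function(x) x@formula)
#' @rdname Molecule-accessors
#' @export
setMethod("exactMass", "Molecule", function(x) x@exactMass)
#' @rdname Molecule-accessors
#' @export
setMethod("alogp", "Molecule", function(x) x@alogp)
#' @rdname Molecule-accessors
#' @export
setMethod("molLabel", "Molecule", function(x) x@label)

setMethod("show", "Molecule", function(object) {
  cat("Molecule", if (!is.na(object@label)) paste0("'", object@label, "'") else "",
      "\n")
  cat("  SMILES:  ", object@smiles, "\n", sep = "")
  cat("  InChIKey:", object@inchikey, "\n")
  cat("  Formula: ", object@formula,
      sprintf("  (%.5f Da, ALogP %.2f)", object@exactMass, object@alogp),
      "\n", sep = "")
})

#' Heavy-atom count of a molecule
#' @param x a \linkS4class{Molecule}.
#' @return integer heavy-atom (non-hydrogen) count.
#' @export
heavyAtomCount <- function(x) {
  stopifnot(is(x, "Molecule"))
  mgHeavyAtoms(x@graph)
}
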