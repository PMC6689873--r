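## Thin wrappers around ChemmineOB / OpenBabel used for canonicalization,
## InChI/InChIKey generation, logP estimation and full-SMARTS matching.
## Results are memoised per session: tree enumeration revisits the same
## structures many times.

.obCache <- new.env(parent = emptyenv())

.obMemo <- function(key, fn) {
  if (!is.null(.obCache[[key]])) return(.obCache[[key]])
  val <- fn()
  assign(key, val, envir = .obCache)
  val
}

.obStrip <- function(x) sub("[[:space:]]+$", "", x)

## Convert a single structure between OpenBabel formats. Returns NA_character_
## when OpenBabel cannot parse/produce the record (its diagnostics go to
## stderr).
obConvert <- function(from, to, text) {
  key <- paste0(from, ">", to, ">", text)
  .obMemo(key, function() {
    out <- tryCatch(
      ChemmineOB::convertFormat(from, to, paste0(text, "\n")),
      error = function(e) "")
    out <- .obStrip(out)
    if (!nzchar(out)) NA_character_ else out
  })
}

obCanonicalSmiles <- function(smiles) {
  out <- obConvert("SMI", "CAN", smiles)
  if (!is.na(out)) out <- sub("\t.*$", "", out)
  out
}

obInChI <- function(smiles) {
  out <- obConvert("SMI", "INCHI", smiles)
  if (!is.na(out) && !grepl("^InChI=", out)) out <- NA_character_
  out
}

obInChIKey <- function(smiles) {
  out <- obConvert("SMI", "INCHIKEY", smiles)
  if (!is.na(out) && !grepl("^[A-Z]{14}-[A-Z]{10}-[A-Z]$", out))
    out <- NA_character_
  out
}

obMolBlock <- function(smiles, title = "") {
  out <- obConvert("SMI", "MOL", smiles)
  if (is.na(out)) return(NA_character_)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines[1] <- title
  ## scrub the timestamped program line for byte-stable output
  if (length(lines) >= 2L) lines[2] <- " MetabolizR"
  paste(lines, collapse = "\n")
}

.obMolRef <- function(smiles) {
  key <- paste0("ref>", smiles)
  .obMemo(key, function() {
    refs <- tryCatch(
      ChemmineOB::forEachMol("SMILES", paste0(smiles, "\n"), identity),
      error = function(e) list())
    if (length(refs)) refs[[1]] else NULL
  })
}

## OpenBabel logP estimate (additive atom-contribution model)
obLogP <- function(smiles) {
  key <- paste0("logp>", smiles)
  .obMemo(key, function() {
    ref <- .obMolRef(smiles)
    if (is.null(ref)) return(NA_real_)
    p <- tryCatch(ChemmineOB::prop_OB(ref), error = function(e) NULL)
    if (is.null(p)) NA_real_ else as.numeric(p$logP)
  })
}

## number of embeddings of a full-syntax SMARTS (recursive SMARTS allowed);
## used for rule constraints and structural feature flags
obSmartsCount <- function(smiles, smarts, unique = FALSE) {
  key <- paste0("sm>", unique, ">", smarts, ">", smiles)
  .obMemo(key, function() {
    ref <- .obMolRef(smiles)
    if (is.null(ref)) return(NA_integer_)
    as.integer(ChemmineOB::smartsSearch_OB(list(ref), smarts,
                                           uniqueMatches = unique))
  })
}

## validate that a SMARTS compiles under OpenBabel (errors propagate)
obSmartsValid <- function(smarts) {
  ref <- .obMolRef("C")
  ok <- tryCatch({
    ChemmineOB::smartsSearch_OB(list(ref), smarts, uniqueMatches = TRUE)
    TRUE
  }, error = function(e) FALSE)
  ok
}
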