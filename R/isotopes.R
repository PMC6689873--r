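## Monoisotopic (most-abundant-isotope) atomic masses, CODATA/IUPAC values.
## Only elements plausibly seen in organic xenobiotics are listed; anything
## else raises a FormulaError.

.MONOISOTOPIC <- c(
  H  = 1.00782503207,
  B  = 11.0093054,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  F  = 18.99840322,
  Na = 22.9897692809,
  Mg = 23.985041700,
  Si = 27.9769265325,
  P  = 30.97376163,
  S  = 31.97207100,
  Cl = 34.96885268,
  K  = 38.96370668,
  Ca = 39.96259098,
  Fe = 55.9349375,
  Zn = 63.9291422,
  Se = 79.9165213,
  Br = 78.9183371,
  I  = 126.904473
)

#' Parse a Hill-order molecular formula
#'
#' Splits a molecular formula such as \code{"C15H14O6"} into a named integer
#' vector of element counts. Charges and isotope labels are not supported.
#'
#' @param formula character(1), e.g. \code{"C21H22O12"}.
#' @return Named integer vector of element counts.
#' @examples
#' parseFormula("C15H14O6")
#' @export
parseFormula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  s <- gsub("\\s", "", formula)
  if (!nzchar(s)) stop(formulaError("empty formula"))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)
  parts <- regmatches(s, m)[[1]]
  if (sum(attr(m[[1]], "match.length")) != nchar(s))
    stop(formulaError(sprintf("cannot parse formula '%s'", formula)))
  counts <- integer(0)
  for (p in parts) {
    el <- sub("[0-9]*$", "", p)
    n <- sub("^[A-Za-z]+", "", p)
    n <- if (nzchar(n)) as.integer(n) else 1L
    if (n <= 0L) stop(formulaError(sprintf("non-positive count for %s", el)))
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums most-abundant-isotope atomic masses over all atoms (hydrogens
#' included) of a Hill-notation formula.
#'
#' @param formula character(1) molecular formula, e.g. \code{"H2O"}.
#' @return numeric(1), mass in Da.
#' @examples
#' monoisotopicMass("H2O")         # 18.01056
#' monoisotopicMass("C15H14O6")    # 290.07904 (epicatechin)
#' @export
monoisotopicMass <- function(formula) {
  counts <- parseFormula(formula)
  unknown <- setdiff(names(counts), names(.MONOISOTOPIC))
  if (length(unknown))
    stop(formulaError(sprintf("unknown element symbol(s): %s",
                              paste(unknown, collapse = ", "))))
  sum(.MONOISOTOPIC[names(counts)] * counts)
}

## Hill order: C first, H second, all others alphabetical. If no carbon,
## everything alphabetical.
hillFormula <- function(counts) {
  counts <- counts[counts > 0L]
  els <- names(counts)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", intersect("H", els), rest)
  } else {
    ord <- sort(els)
  }
  paste0(vapply(ord, function(e) {
    if (counts[[e]] == 1L) e else paste0(e, counts[[e]])
  }, character(1)), collapse = "")
}

formulaError <- function(msg) {
  structure(class = c("FormulaError", "error", "condition"),
            list(message = msg, call = sys.call(-1)))
}
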