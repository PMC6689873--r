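## SMILES reading/writing for the internal molgraph representation.
##
## The parser accepts the canonical SMILES emitted by OpenBabel (organic
## subset, bracket atoms, ring closures incl. %nn, branches, charges,
## [nH], stereo tokens which are recorded but not interpreted) plus atom
## maps, which makes it reusable for the product side of SMIRKS rules.

.ORGANIC_SUBSET <- c("B", "C", "N", "O", "P", "S", "F", "Cl", "Br", "I")

## implicit hydrogen count from standard valence rules
mgDeriveH <- function(el, aromatic, charge, bsum) {
  vals <- .ALLOWED_VALENCE[[el]]
  if (is.null(vals)) return(0L)
  extra <- if (isTRUE(aromatic) && el %in% c("C", "N", "P")) 1L else 0L
  adj <- if (el %in% c("N", "P")) charge else
         if (el %in% c("O", "S", "Se")) charge else 0L
  vals <- vals + adj
  need <- bsum + extra
  vals <- vals[vals >= need]
  if (length(vals)) as.integer(min(vals) - need) else 0L
}

parseError <- function(msg) {
  structure(class = c("SmilesParseError", "InvalidStructure", "error",
                      "condition"),
            list(message = msg, call = NULL))
}

## Parse a SMILES (or SMIRKS product fragment) into a molgraph.
## Returns molgraph with an extra atoms$map column when maps are present.
parseSmilesGraph <- function(s, allowDots = FALSE) {
  s <- trimws(s)
  if (!nzchar(s)) stop(parseError("empty SMILES"))
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- list(); bonds <- list()
  prev <- NA_integer_
  stack <- integer(0)
  pending <- NULL   # list(order, aromatic) or NULL
  rings <- list()   # digit -> list(atom, bond)

  addAtom <- function(element, aromatic, charge, hcount, chiral, map) {
    atoms[[length(atoms) + 1L]] <<- list(
      element = element, aromatic = aromatic, charge = charge,
      hcount = hcount, chiral = chiral, map = map)
    idx <- length(atoms)
    if (!is.na(prev)) {
      b <- pending
      if (is.null(b)) {
        arom <- isTRUE(atoms[[prev]]$aromatic) && isTRUE(aromatic)
        b <- list(order = 1L, aromatic = arom)
      }
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = idx,
                                           order = b$order,
                                           aromatic = b$aromatic)
    }
    pending <<- NULL
    prev <<- idx
    idx
  }

  closeRing <- function(digit) {
    if (is.na(prev)) stop(parseError("ring closure before any atom"))
    key <- as.character(digit)
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, bond = pending)
      pending <<- NULL
    } else {
      open <- rings[[key]]
      rings[[key]] <<- NULL
      b <- pending
      if (is.null(b)) b <- open$bond
      if (is.null(b)) {
        arom <- isTRUE(atoms[[open$atom]]$aromatic) &&
                isTRUE(atoms[[prev]]$aromatic)
        b <- list(order = 1L, aromatic = arom)
      }
      bonds[[length(bonds) + 1L]] <<- list(a1 = open$atom, a2 = prev,
                                           order = b$order,
                                           aromatic = b$aromatic)
      pending <<- NULL
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") {
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (!length(stack)) stop(parseError("unbalanced parenthesis"))
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == "-") {
      pending <- list(order = 1L, aromatic = FALSE); i <- i + 1L
    } else if (ch == "=") {
      pending <- list(order = 2L, aromatic = FALSE); i <- i + 1L
    } else if (ch == "#") {
      pending <- list(order = 3L, aromatic = FALSE); i <- i + 1L
    } else if (ch == ":") {
      pending <- list(order = 1L, aromatic = TRUE); i <- i + 1L
    } else if (ch == "/" || ch == "\\") {
      pending <- list(order = 1L, aromatic = FALSE); i <- i + 1L
    } else if (ch == ".") {
      if (!allowDots) stop(parseError("multi-fragment SMILES ('.') not allowed here"))
      prev <- NA_integer_; pending <- NULL; i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) stop(parseError("bad %nn ring closure"))
      digit <- paste0(chars[i + 1L], chars[i + 2L])
      if (!grepl("^[0-9]{2}$", digit)) stop(parseError("bad %nn ring closure"))
      closeRing(digit); i <- i + 3L
    } else if (grepl("[0-9]", ch)) {
      closeRing(ch); i <- i + 1L
    } else if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop(parseError("unterminated bracket atom"))
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regexec(paste0(
        "^([0-9]+)?",                       # isotope (ignored)
        "(#[0-9]+|[A-Z][a-z]?|as|se|[bcnops]|\\*)", # element
        "(@@|@)?",                          # chirality (recorded only)
        "(H[0-9]*)?",                       # explicit H count
        "(\\+[0-9]*|-[0-9]*|\\++|-+)?",     # charge
        "(:[0-9]+)?$"), body)[[1]]
      if (m[1] == -1L) stop(parseError(sprintf("bad bracket atom [%s]", body)))
      gp <- regmatches(body, regexec(paste0(
        "^([0-9]+)?(#[0-9]+|[A-Z][a-z]?|as|se|[bcnops]|\\*)(@@|@)?(H[0-9]*)?",
        "(\\+[0-9]*|-[0-9]*|\\++|-+)?(:[0-9]+)?$"), body))[[1]]
      sym <- gp[3]
      if (grepl("^#", sym)) {
        ## atomic-number atom (SMIRKS product templates): element fixed,
        ## aromaticity left undetermined (NA, resolved by the transform)
        el <- .SMARTS_EL_FROM_NUM[sub("#", "", sym)]
        if (is.na(el)) stop(parseError(sprintf("unknown atomic number in [%s]", body)))
        element <- unname(el)
        aromatic <- NA
      } else {
        aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se", "as")
        element <- if (sym == "*") "*" else {
          e <- sym
          substr(e, 1, 1) <- toupper(substr(e, 1, 1))
          e
        }
      }
      chiral <- gp[4]
      htok <- gp[5]
      hcount <- if (nzchar(htok)) {
        if (htok == "H") 1L else as.integer(sub("^H", "", htok))
      } else 0L
      ctok <- gp[6]
      charge <- 0L
      if (nzchar(ctok)) {
        if (grepl("^\\++$", ctok)) charge <- nchar(ctok)
        else if (grepl("^-+$", ctok)) charge <- -nchar(ctok)
        else if (grepl("^\\+[0-9]+$", ctok)) charge <- as.integer(sub("\\+", "", ctok))
        else if (grepl("^-[0-9]+$", ctok)) charge <- -as.integer(sub("-", "", ctok))
      }
      mtok <- gp[7]
      map <- if (nzchar(mtok)) as.integer(sub(":", "", mtok)) else NA_integer_
      addAtom(element, aromatic, charge, hcount, chiral, map)
      i <- j + 1L
    } else {
      ## organic-subset atom
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        addAtom(two, FALSE, 0L, NA_integer_, "", NA_integer_); i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        addAtom(ch, FALSE, 0L, NA_integer_, "", NA_integer_); i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        addAtom(toupper(ch), TRUE, 0L, NA_integer_, "", NA_integer_)
        i <- i + 1L
      } else {
        stop(parseError(sprintf("unexpected character '%s' in SMILES", ch)))
      }
    }
  }
  if (length(stack)) stop(parseError("unbalanced parenthesis"))
  if (length(rings)) stop(parseError("unmatched ring closure"))
  if (!length(atoms)) stop(parseError("no atoms parsed"))

  atomdf <- data.frame(
    element = vapply(atoms, `[[`, "", "element"),
    aromatic = vapply(atoms, `[[`, NA, "aromatic"),
    charge = vapply(atoms, `[[`, 0L, "charge"),
    hcount = vapply(atoms, `[[`, NA_integer_, "hcount"),
    chiral = vapply(atoms, `[[`, "", "chiral"),
    map = vapply(atoms, `[[`, NA_integer_, "map"),
    stringsAsFactors = FALSE)
  bonddf <- if (length(bonds)) data.frame(
    a1 = vapply(bonds, `[[`, 0L, "a1"),
    a2 = vapply(bonds, `[[`, 0L, "a2"),
    order = vapply(bonds, `[[`, 0L, "order"),
    aromatic = vapply(bonds, `[[`, NA, "aromatic")) else mgEmptyBonds()
  g <- mgNew(atomdf, bonddf)

  ## fold explicit-H atoms into neighbour hcount
  hatoms <- which(g$atoms$element == "H" & g$atoms$charge == 0L)
  if (length(hatoms)) {
    for (h in hatoms) {
      nb <- c(g$bonds$a2[g$bonds$a1 == h], g$bonds$a1[g$bonds$a2 == h])
      if (length(nb) == 1L && !is.na(g$atoms$hcount[nb]))
        g$atoms$hcount[nb] <- g$atoms$hcount[nb] + 1L
      ## NA hcount re-derives correctly once the H atom is dropped
    }
    keep <- setdiff(seq_len(mgNumAtoms(g)), hatoms)
    g <- mgSubgraph(g, keep)
  }

  ## a default bond between aromatic atoms is only aromatic inside a ring
  ## (e.g. the biaryl bond in flavonoids is single)
  if (any(g$bonds$aromatic)) {
    ring <- mgRingInfo(g)
    fix <- g$bonds$aromatic & !ring$bond
    g$bonds$aromatic[fix] <- FALSE
  }
  g
}

## Write molgraph back to SMILES (stereo annotations are dropped; fragments
## joined with '.').
writeSmilesGraph <- function(g) {
  if (mgNumAtoms(g) == 0L) return("")
  memb <- mgComponents(g)
  if (max(memb) > 1L) {
    return(paste(vapply(mgSplit(g), writeSmilesGraph, character(1)),
                 collapse = "."))
  }
  n <- mgNumAtoms(g)
  adj <- mgAdjacency(g)
  hyd <- mgHydrogens(g)
  bsum <- mgBondOrderSum(g)

  atomToken <- function(i) {
    a <- g$atoms[i, ]
    el <- a$element
    sym <- if (isTRUE(a$aromatic)) tolower(el) else el
    plain <- el %in% .ORGANIC_SUBSET && a$charge == 0L
    if (plain) {
      derived <- mgDeriveH(el, a$aromatic, a$charge, bsum[i])
      if (derived == hyd[i]) return(sym)
    }
    h <- hyd[i]
    htok <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
    ctok <- if (a$charge == 0L) "" else if (a$charge == 1L) "+" else
            if (a$charge == -1L) "-" else
            if (a$charge > 0L) paste0("+", a$charge) else
            paste0("-", abs(a$charge))
    paste0("[", sym, htok, ctok, "]")
  }

  bondToken <- function(k, from, to) {
    b <- g$bonds[k, ]
    if (isTRUE(b$aromatic)) return("")
    if (b$order == 2L) return("=")
    if (b$order == 3L) return("#")
    ## single bond between two aromatic atoms must be explicit
    if (isTRUE(g$atoms$aromatic[from]) && isTRUE(g$atoms$aromatic[to]))
      return("-")
    ""
  }

  visited <- logical(n)
  ringTok <- vector("list", n)   # per-atom ring closure tokens
  seenBond <- logical(nrow(g$bonds))
  digit <- 0L
  nextDigit <- function() {
    digit <<- digit + 1L
    if (digit < 10L) as.character(digit) else sprintf("%%%02d", digit)
  }
  treeChildren <- vector("list", n)
  dfs <- function(i, fromBond) {
    visited[i] <<- TRUE
    for (j in adj[[i]]) {
      k <- mgBondBetween(g, i, j)
      if (!is.na(fromBond) && k == fromBond) next
      if (seenBond[k]) next
      seenBond[k] <<- TRUE
      if (visited[j]) {
        d <- nextDigit()
        tok <- bondToken(k, i, j)
        ringTok[[i]] <<- c(ringTok[[i]], paste0(tok, d))
        ringTok[[j]] <<- c(ringTok[[j]], paste0(tok, d))
      } else {
        treeChildren[[i]] <<- c(treeChildren[[i]], j)
        dfs(j, k)
      }
    }
  }
  dfs(1L, NA_integer_)

  emit <- function(i) {
    out <- paste0(atomToken(i), paste0(unlist(ringTok[[i]]), collapse = ""))
    kids <- treeChildren[[i]]
    if (length(kids)) {
      parts <- vapply(seq_along(kids), function(q) {
        j <- kids[q]
        btok <- bondToken(mgBondBetween(g, i, j), i, j)
        paste0(btok, emit(j))
      }, character(1))
      if (length(parts) > 1L)
        out <- paste0(out, paste0("(", parts[-length(parts)], ")",
                                  collapse = ""), parts[length(parts)])
      else out <- paste0(out, parts)
    }
    out
  }
  emit(1L)
}
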