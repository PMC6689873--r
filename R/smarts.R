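## SMARTS-subset compiler and subgraph matcher.
##
## This supports the pattern language used by the SMIRKS reactant sides of
## the packaged rules: element symbols (incl. aromatic lowercase and #n),
## A/a, H<n>, X<n>, D<n>, R/R0, charges, '*', '!' negation, '&'/implicit
## high-precedence AND, ',' OR, ';' low-precedence AND, atom maps, ring
## closures, branches, and the bond primitives - = # : ~ plus the default
## single-or-aromatic bond. Recursive SMARTS ($(...)) is deliberately not
## part of the subset: rule applicability constraints are evaluated with
## OpenBabel's full SMARTS engine instead (see obSmartsCount).

smartsError <- function(msg) {
  structure(class = c("RuleCompileError", "error", "condition"),
            list(message = msg, call = NULL))
}

.SMARTS_EL_FROM_NUM <- stats::setNames(names(.ELEMENT_NUMBER), .ELEMENT_NUMBER)

## parse one bracket-atom expression body (without the surrounding []) into
## list(alts-of-ands structure, map)
parseSmartsAtomExpr <- function(body, full) {
  map <- NA_integer_
  mm <- regmatches(body, regexec("^(.*):([0-9]+)$", body))[[1]]
  if (length(mm)) { body <- mm[2]; map <- as.integer(mm[3]) }
  if (!nzchar(body)) stop(smartsError(sprintf("empty atom expression in '%s'", full)))

  parsePrims <- function(seg) {
    prims <- list()
    i <- 1L; n <- nchar(seg)
    while (i <= n) {
      neg <- FALSE
      if (substr(seg, i, i) == "!") { neg <- TRUE; i <- i + 1L }
      if (substr(seg, i, i) == "&") { i <- i + 1L; next }
      rest <- substr(seg, i, n)
      m <- regmatches(rest, regexec(paste0(
        "^(#[0-9]+|Cl|Br|Si|Se|Na|[BCNOPSFI]|[bcnops]|\\*|",
        "A|a|H[0-9]*|X[0-9]+|D[0-9]+|R[0-9]*|",
        "\\+[0-9]*|-[0-9]*)"), rest))[[1]]
      if (!length(m) || !nzchar(m[2]))
        stop(smartsError(sprintf("unsupported SMARTS primitive at '%s' in '%s'",
                                 rest, full)))
      tok <- m[2]
      prim <- if (grepl("^#", tok)) {
        num <- sub("#", "", tok)
        el <- .SMARTS_EL_FROM_NUM[num]
        if (is.na(el)) stop(smartsError(sprintf("unknown atomic number %s", num)))
        list(kind = "element", element = unname(el), aromatic = NA)
      } else if (tok %in% c("Cl", "Br", "Si", "Se", "Na", "B", "C", "N", "O",
                            "P", "S", "F", "I")) {
        list(kind = "element", element = tok, aromatic = FALSE)
      } else if (tok %in% c("b", "c", "n", "o", "p", "s")) {
        list(kind = "element", element = toupper(tok), aromatic = TRUE)
      } else if (tok == "*") {
        list(kind = "any")
      } else if (tok == "A") {
        list(kind = "aliphatic")
      } else if (tok == "a") {
        list(kind = "aromatic")
      } else if (grepl("^H", tok)) {
        nH <- sub("H", "", tok)
        list(kind = "hcount", value = if (nzchar(nH)) as.integer(nH) else 1L)
      } else if (grepl("^X", tok)) {
        list(kind = "connections", value = as.integer(sub("X", "", tok)))
      } else if (grepl("^D", tok)) {
        list(kind = "degree", value = as.integer(sub("D", "", tok)))
      } else if (grepl("^R", tok)) {
        nR <- sub("R", "", tok)
        if (nzchar(nR) && as.integer(nR) == 0L) list(kind = "notring")
        else list(kind = "ring")
      } else if (grepl("^\\+", tok)) {
        v <- sub("\\+", "", tok)
        list(kind = "charge", value = if (nzchar(v)) as.integer(v) else 1L)
      } else {
        v <- sub("-", "", tok)
        list(kind = "charge", value = -(if (nzchar(v)) as.integer(v) else 1L))
      }
      prim$negate <- neg
      prims[[length(prims) + 1L]] <- prim
      i <- i + nchar(tok) + 0L
    }
    prims
  }

  groups <- strsplit(body, ";", fixed = TRUE)[[1]]
  expr <- lapply(groups, function(gseg) {
    alts <- strsplit(gseg, ",", fixed = TRUE)[[1]]
    lapply(alts, parsePrims)
  })
  list(expr = expr, map = map)
}

## Compile a connected SMARTS pattern into list(atoms=list(expr,map),
## bonds=data.frame(a1,a2,spec)).
compileSmartsPattern <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) stop(smartsError("empty SMARTS"))
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  atoms <- list(); bonds <- list()
  prev <- NA_integer_; stack <- integer(0)
  pending <- NULL
  rings <- list()

  addAtom <- function(expr, map) {
    atoms[[length(atoms) + 1L]] <<- list(expr = expr, map = map)
    idx <- length(atoms)
    if (!is.na(prev)) {
      spec <- if (is.null(pending)) "default" else pending
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev, a2 = idx, spec = spec)
    }
    pending <<- NULL
    prev <<- idx
  }
  closeRing <- function(key) {
    if (is.null(rings[[key]])) {
      rings[[key]] <<- list(atom = prev, spec = pending); pending <<- NULL
    } else {
      open <- rings[[key]]; rings[[key]] <<- NULL
      spec <- pending
      if (is.null(spec)) spec <- open$spec
      if (is.null(spec)) spec <- "default"
      bonds[[length(bonds) + 1L]] <<- list(a1 = open$atom, a2 = prev,
                                           spec = spec)
      pending <<- NULL
    }
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L }
    else if (ch == ")") {
      if (!length(stack)) stop(smartsError(sprintf("unbalanced parenthesis in '%s'", s)))
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]; i <- i + 1L
    }
    else if (ch == "-") { pending <- "single"; i <- i + 1L }
    else if (ch == "=") { pending <- "double"; i <- i + 1L }
    else if (ch == "#") { pending <- "triple"; i <- i + 1L }
    else if (ch == ":") { pending <- "arom"; i <- i + 1L }
    else if (ch == "~") { pending <- "any"; i <- i + 1L }
    else if (grepl("[0-9]", ch)) { closeRing(ch); i <- i + 1L }
    else if (ch == "%") {
      key <- paste0(chars[i + 1L], chars[i + 2L]); closeRing(key); i <- i + 3L
    }
    else if (ch == "[") {
      j <- i + 1L; depth <- 0L
      while (j <= n && !(chars[j] == "]" && depth == 0L)) {
        if (chars[j] == "[") depth <- depth + 1L
        if (chars[j] == "]") depth <- depth - 1L
        j <- j + 1L
      }
      if (j > n) stop(smartsError(sprintf("unterminated bracket in '%s'", s)))
      body <- paste0(chars[(i + 1L):(j - 1L)], collapse = "")
      if (grepl("$", body, fixed = TRUE))
        stop(smartsError("recursive SMARTS ($(...)) is outside the supported subset"))
      ae <- parseSmartsAtomExpr(body, s)
      addAtom(ae$expr, ae$map)
      i <- j + 1L
    }
    else {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        addAtom(list(list(list(kind = "element", element = two,
                               aromatic = FALSE, negate = FALSE))),
                NA_integer_)
        i <- i + 2L
      } else if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
        addAtom(list(list(list(kind = "element", element = ch,
                               aromatic = FALSE, negate = FALSE))),
                NA_integer_)
        i <- i + 1L
      } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
        addAtom(list(list(list(kind = "element", element = toupper(ch),
                               aromatic = TRUE, negate = FALSE))),
                NA_integer_)
        i <- i + 1L
      } else if (ch == "*") {
        addAtom(list(list(list(kind = "any", negate = FALSE))), NA_integer_)
        i <- i + 1L
      } else {
        stop(smartsError(sprintf("unexpected character '%s' in SMARTS '%s'", ch, s)))
      }
    }
  }
  if (length(stack)) stop(smartsError(sprintf("unbalanced parenthesis in '%s'", s)))
  if (length(Filter(Negate(is.null), rings)))
    stop(smartsError(sprintf("unmatched ring closure in '%s'", s)))
  if (!length(atoms)) stop(smartsError(sprintf("no atoms in SMARTS '%s'", s)))
  bonddf <- if (length(bonds)) data.frame(
    a1 = vapply(bonds, `[[`, 0L, "a1"),
    a2 = vapply(bonds, `[[`, 0L, "a2"),
    spec = vapply(bonds, `[[`, "", "spec"),
    stringsAsFactors = FALSE) else
    data.frame(a1 = integer(0), a2 = integer(0), spec = character(0))
  structure(list(atoms = atoms, bonds = bonddf, smarts = s),
            class = "smartsPattern")
}

## precomputed per-molecule matching context
mgMatchContext <- function(g) {
  hyd <- mgHydrogens(g)
  deg <- mgDegree(g)
  ring <- mgRingInfo(g)
  list(element = g$atoms$element, aromatic = g$atoms$aromatic,
       charge = g$atoms$charge, hyd = hyd, degree = deg,
       conn = deg + hyd, inring = ring$atom, ringbond = ring$bond)
}

primMatches <- function(prim, ctx, i) {
  val <- switch(prim$kind,
    element = {
      ok <- ctx$element[i] == prim$element
      if (ok && !is.na(prim$aromatic)) ok <- ctx$aromatic[i] == prim$aromatic
      ok
    },
    any = TRUE,
    aliphatic = !ctx$aromatic[i],
    aromatic = ctx$aromatic[i],
    hcount = ctx$hyd[i] == prim$value,
    connections = ctx$conn[i] == prim$value,
    degree = ctx$degree[i] == prim$value,
    ring = ctx$inring[i],
    notring = !ctx$inring[i],
    charge = ctx$charge[i] == prim$value,
    stop(smartsError(paste("unknown primitive kind", prim$kind))))
  if (isTRUE(prim$negate)) !val else val
}

atomExprMatches <- function(expr, ctx, i) {
  for (group in expr) {       # ';' AND over groups
    groupOK <- FALSE
    for (alt in group) {      # ',' OR over alternatives
      altOK <- TRUE
      for (prim in alt) {     # '&' AND over primitives
        if (!primMatches(prim, ctx, i)) { altOK <- FALSE; break }
      }
      if (altOK) { groupOK <- TRUE; break }
    }
    if (!groupOK) return(FALSE)
  }
  TRUE
}

bondSpecMatches <- function(spec, order, aromatic) {
  switch(spec,
    default = aromatic || order == 1L,
    single = !aromatic && order == 1L,
    double = !aromatic && order == 2L,
    triple = !aromatic && order == 3L,
    arom = aromatic,
    any = TRUE,
    stop(smartsError(paste("unknown bond spec", spec))))
}

## All embeddings of pattern in molecule graph. Returns list of integer
## vectors (pattern atom index -> molecule atom index). When unique=TRUE,
## embeddings mapping onto the same unordered atom set are collapsed.
matchSmarts <- function(g, pattern, ctx = NULL, unique = FALSE,
                        limit = Inf) {
  if (is.character(pattern)) pattern <- compileSmartsPattern(pattern)
  if (is.null(ctx)) ctx <- mgMatchContext(g)
  np <- length(pattern$atoms)
  nm <- mgNumAtoms(g)
  if (nm < np) return(list())
  adj <- mgAdjacency(g)

  ## pattern traversal order: BFS from atom 1 keeping connectivity
  pb <- pattern$bonds
  padj <- vector("list", np)
  if (nrow(pb)) for (k in seq_len(nrow(pb))) {
    padj[[pb$a1[k]]] <- c(padj[[pb$a1[k]]], k)
    padj[[pb$a2[k]]] <- c(padj[[pb$a2[k]]], k)
  }
  order <- 1L; parentBond <- NA_integer_
  seen <- c(TRUE, rep(FALSE, np - 1L))
  queue <- 1L
  while (length(queue)) {
    cur <- queue[1L]; queue <- queue[-1L]
    for (k in padj[[cur]]) {
      oth <- if (pb$a1[k] == cur) pb$a2[k] else pb$a1[k]
      if (!seen[oth]) {
        seen[oth] <- TRUE
        order <- c(order, oth); parentBond <- c(parentBond, k)
        queue <- c(queue, oth)
      }
    }
  }
  if (length(order) < np)
    stop(smartsError(sprintf("disconnected SMARTS pattern '%s'", pattern$smarts)))

  results <- list()
  amap <- rep(NA_integer_, np)
  used <- logical(nm)

  bondOK <- function(k, mi, mj) {
    bk <- mgBondBetween(g, mi, mj)
    if (is.na(bk)) return(FALSE)
    bondSpecMatches(pb$spec[k], g$bonds$order[bk], g$bonds$aromatic[bk])
  }

  recurse <- function(pos) {
    if (length(results) >= limit) return()
    if (pos > np) {
      results[[length(results) + 1L]] <<- amap
      return()
    }
    p <- order[pos]
    cand <- if (pos == 1L) seq_len(nm) else {
      parent <- if (pb$a1[parentBond[pos]] == p) pb$a2[parentBond[pos]] else
        pb$a1[parentBond[pos]]
      adj[[amap[parent]]]
    }
    for (mi in cand) {
      if (used[mi]) next
      if (!atomExprMatches(pattern$atoms[[p]]$expr, ctx, mi)) next
      ok <- TRUE
      for (k in padj[[p]]) {
        oth <- if (pb$a1[k] == p) pb$a2[k] else pb$a1[k]
        if (!is.na(amap[oth]) && !bondOK(k, mi, amap[oth])) { ok <- FALSE; break }
      }
      if (!ok) next
      amap[p] <<- mi; used[mi] <<- TRUE
      recurse(pos + 1L)
      amap[p] <<- NA_integer_; used[mi] <<- FALSE
    }
  }
  recurse(1L)

  if (unique && length(results) > 1L) {
    keys <- vapply(results, function(x) paste(sort(x), collapse = ","), "")
    results <- results[!duplicated(keys)]
  }
  results
}
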