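# Substructure matching for the template catalog: a SMARTS-subset pattern
# language compiled to predicate graphs, matched by backtracking search
# over the explicit-hydrogen molecular graph.
#
# Supported atom primitives: element symbols (C, N, O, S, F, Cl, H),
# #<n> atomic number, X<d> total connections, H<d> attached-hydrogen
# count, R / !R ring membership, a / A aromaticity, +/- formal charge,
# * wildcard, ! negation.  ',' is OR (between '&'/implicit AND groups),
# ';' is low-precedence AND.  Bond primitives: - = # : ~ plus the SMARTS
# default bond (single-or-aromatic).  Branches and ring-closure digits
# are supported.

.ATOMIC_NUMBER <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, S = 16L, Cl = 17L)

smarts_error <- function(pattern, msg) {
  stop(structure(class = c("hydro_smarts_error", "error", "condition"),
                 list(message = sprintf("bad SMARTS '%s': %s", pattern, msg),
                      call = NULL)))
}

# one primitive -> list(kind, value, negated)
parse_primitives <- function(txt, pattern) {
  prims <- list()
  i <- 1L; n <- nchar(txt)
  chars <- strsplit(txt, "")[[1]]
  while (i <= n) {
    neg <- FALSE
    if (chars[i] == "!") { neg <- TRUE; i <- i + 1L }
    if (i > n) smarts_error(pattern, "dangling '!'")
    ch <- chars[i]
    rest <- substring(txt, i)
    if (ch == "#") {
      m <- regmatches(rest, regexpr("^#[0-9]+", rest))
      if (!nzchar(m)) smarts_error(pattern, "bad #n primitive")
      prims[[length(prims) + 1L]] <- list(kind = "elem_num",
                                          value = as.integer(substring(m, 2)),
                                          neg = neg)
      i <- i + nchar(m)
    } else if (ch == "X") {
      m <- regmatches(rest, regexpr("^X[0-9]+", rest))
      if (!nzchar(m)) smarts_error(pattern, "bad X primitive")
      prims[[length(prims) + 1L]] <- list(kind = "degree",
                                          value = as.integer(substring(m, 2)),
                                          neg = neg)
      i <- i + nchar(m)
    } else if (ch == "H") {
      m <- regmatches(rest, regexpr("^H[0-9]*", rest))
      v <- if (m == "H") 1L else as.integer(substring(m, 2))
      prims[[length(prims) + 1L]] <- list(kind = "hcount", value = v, neg = neg)
      i <- i + nchar(m)
    } else if (ch == "R") {
      prims[[length(prims) + 1L]] <- list(kind = "ring", value = TRUE, neg = neg)
      i <- i + 1L
    } else if (ch == "a") {
      prims[[length(prims) + 1L]] <- list(kind = "aromatic", value = TRUE, neg = neg)
      i <- i + 1L
    } else if (ch == "A") {
      prims[[length(prims) + 1L]] <- list(kind = "aromatic", value = FALSE, neg = neg)
      i <- i + 1L
    } else if (ch == "*") {
      prims[[length(prims) + 1L]] <- list(kind = "any", value = TRUE, neg = neg)
      i <- i + 1L
    } else if (ch %in% c("+", "-")) {
      m <- regmatches(rest, regexpr("^[+-][0-9]*", rest))
      v <- if (nchar(m) == 1L) 1L else as.integer(substring(m, 2))
      if (ch == "-") v <- -v
      prims[[length(prims) + 1L]] <- list(kind = "charge", value = v, neg = neg)
      i <- i + nchar(m)
    } else if (grepl("^[A-Z]", ch)) {
      m <- regmatches(rest, regexpr("^Cl|^[A-Z]", rest))
      if (!m %in% names(.ATOMIC_NUMBER))
        smarts_error(pattern, sprintf("unsupported element '%s'", m))
      prims[[length(prims) + 1L]] <- list(kind = "elem_aliph", value = m, neg = neg)
      i <- i + nchar(m)
    } else if (grepl("^[a-z]", ch)) {
      sym <- toupper(ch)
      if (!sym %in% names(.ATOMIC_NUMBER))
        smarts_error(pattern, sprintf("unsupported aromatic element '%s'", ch))
      prims[[length(prims) + 1L]] <- list(kind = "elem_arom", value = sym, neg = neg)
      i <- i + 1L
    } else {
      smarts_error(pattern, sprintf("unsupported primitive at '%s'", rest))
    }
  }
  prims
}

# bracket body -> predicate spec: list of OR-alternatives, each a primitive list
parse_atom_expr <- function(body, pattern) {
  and_clauses <- strsplit(body, ";", fixed = TRUE)[[1]]
  lapply(and_clauses, function(cl) {
    ors <- strsplit(cl, ",", fixed = TRUE)[[1]]
    lapply(ors, function(term) parse_primitives(gsub("&", "", term), pattern))
  })
}

compile_smarts <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  n <- length(chars)
  atoms <- list()   # each: list of AND-clauses (each a list of OR primitive-lists)
  bonds <- list()   # list(a1, a2, kind)
  prev <- integer(0)
  pending <- NA_character_
  ring <- list()
  add_patom <- function(expr) {
    atoms[[length(atoms) + 1L]] <<- expr
    idx <- length(atoms)
    if (length(prev) > 0L) {
      bonds[[length(bonds) + 1L]] <<- list(a1 = prev[length(prev)], a2 = idx,
                                           kind = if (is.na(pending)) "default" else pending)
    }
    pending <<- NA_character_
    if (length(prev) == 0L) prev <<- idx else prev[length(prev)] <<- idx
  }
  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) smarts_error(pattern, "unclosed bracket")
      add_patom(parse_atom_expr(paste(chars[(i + 1L):(j - 1L)], collapse = ""), pattern))
      i <- j + 1L
    } else if (grepl("[A-Za-z*]", ch)) {
      tok <- ch
      if (ch == "C" && i < n && chars[i + 1L] == "l") { tok <- "Cl"; i <- i + 1L }
      add_patom(list(list(parse_primitives(tok, pattern))))
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "~")) {
      pending <- switch(ch, "-" = "single", "=" = "double", "#" = "triple",
                        ":" = "aromatic", "~" = "any")
      i <- i + 1L
    } else if (ch == "(") {
      prev <- c(prev, prev[length(prev)]); i <- i + 1L
    } else if (ch == ")") {
      prev <- prev[-length(prev)]; i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      key <- ch
      if (!is.null(ring[[key]])) {
        bonds[[length(bonds) + 1L]] <- list(a1 = ring[[key]], a2 = prev[length(prev)],
                                            kind = if (is.na(pending)) "default" else pending)
        ring[[key]] <- NULL
      } else ring[[key]] <- prev[length(prev)]
      pending <- NA_character_
      i <- i + 1L
    } else {
      smarts_error(pattern, sprintf("unexpected character '%s'", ch))
    }
  }
  if (length(atoms) == 0L) smarts_error(pattern, "no atoms")
  structure(list(atoms = atoms, bonds = bonds, pattern = pattern),
            class = "hydro_smarts")
}

prim_matches <- function(prim, ctx, a) {
  val <- switch(prim$kind,
    any       = TRUE,
    elem_num  = unname(.ATOMIC_NUMBER[ctx$symbol[a]]) == prim$value,
    elem_aliph = ctx$symbol[a] == prim$value && !ctx$aromatic[a],
    elem_arom = ctx$symbol[a] == prim$value && ctx$aromatic[a],
    degree    = ctx$degree[a] == prim$value,
    hcount    = ctx$hcount[a] == prim$value,
    ring      = ctx$in_ring[a],
    aromatic  = ctx$aromatic[a] == prim$value,
    charge    = ctx$charge[a] == prim$value,
    FALSE)
  if (prim$neg) !val else val
}

atom_expr_matches <- function(expr, ctx, a) {
  all(vapply(expr, function(clause) {
    any(vapply(clause, function(term) {
      all(vapply(term, prim_matches, logical(1), ctx, a))
    }, logical(1)))
  }, logical(1)))
}

bond_kind_matches <- function(kind, order) {
  switch(kind,
         default = order %in% c("single", "aromatic"),
         any = TRUE,
         kind == order)
}

match_context <- function(mol) {
  adj <- adjacency_list(mol)
  hcount <- vapply(seq_len(n_atoms(mol)), function(a) {
    sum(vapply(adj[[a]], function(k) {
      nb <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
      mol$atoms$symbol[nb] == "H"
    }, logical(1)))
  }, integer(1))
  list(symbol = mol$atoms$symbol, charge = mol$atoms$charge,
       aromatic = mol$atoms$aromatic, degree = atom_degree(mol),
       hcount = hcount, in_ring = ring_atoms(mol), adj = adj, mol = mol)
}

#' Match a SMARTS-subset pattern against a molecule
#'
#' @inheritParams n_atoms
#' @param pattern a pattern string (see the package vignette for the
#'   supported primitive subset), or a pre-compiled pattern.
#' @param unique_sets drop matches that map the pattern onto an atom set
#'   already returned by an earlier match.
#' @return List of integer vectors; element `i` of a vector is the molecule
#'   atom matched by pattern atom `i`.
#' @export
match_smarts <- function(mol, pattern, unique_sets = FALSE) {
  pat <- if (inherits(pattern, "hydro_smarts")) pattern else compile_smarts(pattern)
  ctx <- match_context(mol)
  np <- length(pat$atoms)
  # pattern adjacency
  padj <- vector("list", np)
  for (b in pat$bonds) {
    padj[[b$a1]] <- c(padj[[b$a1]], list(b))
    padj[[b$a2]] <- c(padj[[b$a2]], list(b))
  }
  results <- list()
  assign_vec <- integer(np)
  used <- logical(n_atoms(mol))

  try_atom <- function(pi) {
    if (pi > np) {
      results[[length(results) + 1L]] <<- assign_vec
      return(invisible(NULL))
    }
    # candidates constrained by already-assigned pattern neighbours
    anchors <- Filter(function(b) {
      other <- if (b$a1 == pi) b$a2 else b$a1
      other < pi
    }, padj[[pi]])
    cand <- if (length(anchors) == 0L) {
      which(!used)
    } else {
      b0 <- anchors[[1]]
      other <- if (b0$a1 == pi) b0$a2 else b0$a1
      ma <- assign_vec[other]
      nbs <- vapply(ctx$adj[[ma]], function(k) {
        if (ctx$mol$bonds$a1[k] == ma) ctx$mol$bonds$a2[k] else ctx$mol$bonds$a1[k]
      }, integer(1))
      nbs[!used[nbs]]
    }
    for (a in cand) {
      if (!atom_expr_matches(pat$atoms[[pi]], ctx, a)) next
      ok <- TRUE
      for (b in anchors) {
        other <- if (b$a1 == pi) b$a2 else b$a1
        k <- find_bond(ctx$mol, assign_vec[other], a)
        if (length(k) == 0L ||
            !bond_kind_matches(b$kind, ctx$mol$bonds$order[k[1]])) { ok <- FALSE; break }
      }
      if (!ok) next
      assign_vec[pi] <<- a; used[a] <<- TRUE
      try_atom(pi + 1L)
      used[a] <<- FALSE; assign_vec[pi] <<- 0L
    }
    invisible(NULL)
  }
  try_atom(1L)

  if (unique_sets && length(results) > 1L) {
    keys <- vapply(results, function(r) paste(sort(r), collapse = ","), character(1))
    results <- results[!duplicated(keys)]
  }
  results
}
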