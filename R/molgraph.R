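# Molecular data model: explicit-hydrogen graphs with formal charges and
# atom-map indices, plus a SMILES reader/writer restricted to the element
# vocabulary the enumerator and the network are trained on.

#' Element vocabulary
#'
#' Elements supported by the molecular data model, with standard IUPAC
#' atomic weights (amu, 3 decimals) and default valences used to infer
#' implicit hydrogens from SMILES.
#'
#' @format A data frame with columns `symbol`, `weight`, `valence`.
#' @export
element_table <- function() {
  data.frame(
    symbol  = c("H", "C", "N", "O", "F", "S", "Cl"),
    weight  = c(1.008, 12.011, 14.007, 15.999, 18.998, 32.060, 35.450),
    valence = c(1L, 4L, 3L, 2L, 1L, 2L, 1L),
    stringsAsFactors = FALSE
  )
}

.ELEM <- local({
  e <- list(
    H = list(weight = 1.008, valence = 1L),
    C = list(weight = 12.011, valence = 4L),
    N = list(weight = 14.007, valence = 3L),
    O = list(weight = 15.999, valence = 2L),
    F = list(weight = 18.998, valence = 1L),
    S = list(weight = 32.060, valence = 2L),
    Cl = list(weight = 35.450, valence = 1L)
  )
  e
})

.BOND_ORDERS <- c("single", "double", "triple", "aromatic")
.ORDER_VALUE <- c(single = 1, double = 2, triple = 3, aromatic = 1.5)

new_mol <- function(atoms, bonds) {
  structure(list(atoms = atoms, bonds = bonds), class = "hydro_mol")
}

empty_atoms <- function() {
  data.frame(symbol = character(), charge = integer(),
             aromatic = logical(), map = integer(),
             stringsAsFactors = FALSE)
}

empty_bonds <- function() {
  data.frame(a1 = integer(), a2 = integer(), order = character(),
             stringsAsFactors = FALSE)
}

#' @export
print.hydro_mol <- function(x, ...) {
  cat(sprintf("<molecule: %d atoms, %d bonds, charge %+d>  %s\n",
              n_atoms(x), n_bonds(x), total_charge(x),
              tryCatch(write_smiles(x), error = function(e) "<unwritable>")))
  invisible(x)
}

#' Number of atoms / bonds, total formal charge
#'
#' @param mol a molecule as returned by [parse_molecule()].
#' @return Integer scalar.
#' @export
n_atoms <- function(mol) nrow(mol$atoms)

#' @rdname n_atoms
#' @export
n_bonds <- function(mol) nrow(mol$bonds)

#' @rdname n_atoms
#' @export
total_charge <- function(mol) as.integer(sum(mol$atoms$charge))

#' Element multiset of a molecule or species list
#'
#' Counts of every element over all atoms, used for conservation checks
#' across the two sides of a reaction.
#'
#' @param x a molecule or a list of molecules.
#' @return Named integer vector (sorted by element symbol).
#' @export
element_multiset <- function(x) {
  if (inherits(x, "hydro_mol")) x <- list(x)
  syms <- unlist(lapply(x, function(m) m$atoms$symbol))
  tab <- table(syms)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

#' Molecular weight (amu)
#'
#' @inheritParams element_multiset
#' @return Numeric scalar, the sum of standard atomic weights.
#' @export
molecular_weight <- function(x) {
  if (inherits(x, "hydro_mol")) x <- list(x)
  w <- vapply(.ELEM, `[[`, numeric(1), "weight")
  sum(unlist(lapply(x, function(m) w[m$atoms$symbol])))
}

# ---- SMILES tokenizer / parser -------------------------------------------

.ORGANIC_SUBSET <- c("C", "N", "O", "S", "F", "Cl")

parse_error <- function(smiles, msg) {
  stop(structure(class = c("hydro_parse_error", "error", "condition"),
                 list(message = sprintf("cannot parse SMILES '%s': %s", smiles, msg),
                      call = NULL)))
}

#' Parse a SMILES string into an explicit-hydrogen molecular graph
#'
#' Reads one single-component SMILES over the element vocabulary
#' \{H, C, N, O, F, S, Cl\} (aromatic lowercase forms included) and returns a
#' molecular graph in which every hydrogen is a real node.  Formal charges
#' and atom-map indices (`[O-:4]` style) are retained.  Any element outside
#' the vocabulary, or a syntax error, raises a parse error naming the input.
#'
#' @param smiles a SMILES string (one molecule; use [parse_species()] for
#'   dot-separated species lists).
#' @return A molecule object: a list with data frames `atoms`
#'   (`symbol`, `charge`, `aromatic`, `map`) and `bonds`
#'   (`a1`, `a2`, `order` in single/double/triple/aromatic).
#' @examples
#' w <- parse_molecule("O")        # water: 1 O + 2 H
#' n_atoms(w)
#' @export
parse_molecule <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles))
    parse_error(if (is.character(smiles) && length(smiles) == 1L) smiles else "<non-string>",
                "input must be one non-empty string")
  if (grepl(".", smiles, fixed = TRUE))
    parse_error(smiles, "multi-component SMILES; use parse_species()")

  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- list()   # each: list(symbol, charge, aromatic, map, h = explicit H count or NA)
  bonds <- list()   # each: list(a1, a2, order)
  prev <- integer(0)            # stack; last element = current attachment point
  pending_bond <- NA_character_
  depth <- 0L                   # open branch count
  ring <- list()                # closure digit -> list(atom, order)

  add_atom <- function(symbol, aromatic, charge = 0L, map = 0L, h = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(symbol = symbol, charge = as.integer(charge),
                                         aromatic = aromatic, map = as.integer(map),
                                         h = h)
    idx <- length(atoms)
    if (length(prev) > 0L) {
      a <- prev[length(prev)]
      ord <- pending_bond
      if (is.na(ord)) {
        ord <- if (isTRUE(atoms[[a]]$aromatic) && aromatic) "aromatic" else "single"
      }
      bonds[[length(bonds) + 1L]] <<- list(a1 = a, a2 = idx, order = ord)
    }
    pending_bond <<- NA_character_
    if (length(prev) == 0L) prev <<- idx else prev[length(prev)] <<- idx
    idx
  }

  close_ring <- function(key) {
    if (!is.null(ring[[key]])) {
      open <- ring[[key]]
      a <- prev[length(prev)]
      ord <- pending_bond
      if (is.na(ord)) ord <- open$order
      if (is.na(ord)) {
        ord <- if (isTRUE(atoms[[open$atom]]$aromatic) &&
                   isTRUE(atoms[[a]]$aromatic)) "aromatic" else "single"
      }
      if (open$atom == a) parse_error(smiles, sprintf("ring closure %s to itself", key))
      bonds[[length(bonds) + 1L]] <<- list(a1 = open$atom, a2 = a, order = ord)
      ring[[key]] <<- NULL
    } else {
      ring[[key]] <- list(atom = prev[length(prev)], order = pending_bond)
      ring <<- ring
    }
    pending_bond <<- NA_character_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) parse_error(smiles, "unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Za-z][a-z]?)(@{0,2})(H[0-9]*)?(\\+{1,3}|-{1,3}|\\+[0-9]+|-[0-9]+)?(:[0-9]+)?$",
        body))[[1]]
      if (length(m) == 0L) parse_error(smiles, sprintf("bad bracket atom [%s]", body))
      sym_raw <- m[3]
      aromatic <- sym_raw %in% c("c", "n", "o", "s")
      sym <- if (aromatic) toupper(sym_raw) else sym_raw
      if (!sym %in% names(.ELEM))
        parse_error(smiles, sprintf("element '%s' outside vocabulary {H,C,N,O,F,S,Cl}", sym_raw))
      htxt <- m[5]
      h <- if (is.na(htxt) || !nzchar(htxt)) 0L
           else if (htxt == "H") 1L else as.integer(substring(htxt, 2))
      ctxt <- m[6]
      charge <- 0L
      if (!is.na(ctxt) && nzchar(ctxt)) {
        if (grepl("^[+-][0-9]+$", ctxt)) {
          charge <- as.integer(ctxt)
        } else {
          charge <- (if (substring(ctxt, 1, 1) == "+") 1L else -1L) * nchar(ctxt)
        }
      }
      mtxt <- m[7]
      map <- if (is.na(mtxt) || !nzchar(mtxt)) 0L else as.integer(substring(mtxt, 2))
      add_atom(sym, aromatic, charge, map, h = h)
      i <- j + 1L
    } else if (ch %in% c("C", "N", "O", "S", "F", "B", "I", "P")) {
      sym <- ch
      if (ch == "C" && i < n && chars[i + 1L] == "l") { sym <- "Cl"; i <- i + 1L }
      if (!sym %in% .ORGANIC_SUBSET)
        parse_error(smiles, sprintf("element '%s' outside vocabulary {H,C,N,O,F,S,Cl}", sym))
      add_atom(sym, aromatic = FALSE)
      i <- i + 1L
    } else if (ch %in% c("c", "n", "o", "s")) {
      add_atom(toupper(ch), aromatic = TRUE)
      i <- i + 1L
    } else if (ch %in% c("-", "=", "#", ":", "/", "\\")) {
      pending_bond <- switch(ch, "-" = "single", "=" = "double", "#" = "triple",
                             ":" = "aromatic", "/" = "single", "\\" = "single")
      i <- i + 1L
    } else if (ch == "(") {
      if (length(prev) == 0L) parse_error(smiles, "branch before any atom")
      depth <- depth + 1L
      prev <- c(prev, prev[length(prev)])
      i <- i + 1L
    } else if (ch == ")") {
      if (length(prev) < 2L || depth == 0L) parse_error(smiles, "unmatched ')'")
      depth <- depth - 1L
      prev <- prev[-length(prev)]
      i <- i + 1L
    } else if (grepl("[0-9]", ch)) {
      close_ring(ch)
      i <- i + 1L
    } else if (ch == "%") {
      if (i + 2L > n) parse_error(smiles, "truncated %nn ring closure")
      close_ring(paste0(chars[i + 1L], chars[i + 2L]))
      i <- i + 3L
    } else {
      parse_error(smiles, sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (length(ring) > 0L) parse_error(smiles, "unclosed ring bond")
  if (depth != 0L) parse_error(smiles, "unclosed branch '('")
  if (length(atoms) == 0L) parse_error(smiles, "no atoms")

  adf <- data.frame(
    symbol = vapply(atoms, `[[`, character(1), "symbol"),
    charge = vapply(atoms, `[[`, integer(1), "charge"),
    aromatic = vapply(atoms, `[[`, logical(1), "aromatic"),
    map = vapply(atoms, `[[`, integer(1), "map"),
    stringsAsFactors = FALSE
  )
  bdf <- if (length(bonds) > 0L) data.frame(
    a1 = vapply(bonds, `[[`, integer(1), "a1"),
    a2 = vapply(bonds, `[[`, integer(1), "a2"),
    order = vapply(bonds, `[[`, character(1), "order"),
    stringsAsFactors = FALSE
  ) else empty_bonds()

  # implicit hydrogens: organic-subset atoms get (default valence - bond sum);
  # bracket atoms carry their explicit H count.
  hspec <- vapply(atoms, function(a) a$h, integer(1))
  nh <- integer(nrow(adf))
  bsum <- numeric(nrow(adf))
  if (nrow(bdf) > 0L) {
    v <- .ORDER_VALUE[bdf$order]
    for (k in seq_len(nrow(bdf))) {
      bsum[bdf$a1[k]] <- bsum[bdf$a1[k]] + v[k]
      bsum[bdf$a2[k]] <- bsum[bdf$a2[k]] + v[k]
    }
  }
  for (a in seq_len(nrow(adf))) {
    if (is.na(hspec[a])) {
      val <- .ELEM[[adf$symbol[a]]]$valence
      nh[a] <- max(0L, as.integer(val - ceiling(bsum[a] - 1e-9)))
    } else {
      nh[a] <- hspec[a]
    }
  }
  heavy_n <- nrow(adf)
  for (a in seq_len(heavy_n)) {
    if (nh[a] > 0L) {
      for (k in seq_len(nh[a])) {
        adf <- rbind(adf, data.frame(symbol = "H", charge = 0L, aromatic = FALSE,
                                     map = 0L, stringsAsFactors = FALSE))
        bdf <- rbind(bdf, data.frame(a1 = a, a2 = nrow(adf), order = "single",
                                     stringsAsFactors = FALSE))
      }
    }
  }
  rownames(adf) <- NULL
  rownames(bdf) <- NULL
  mol <- new_mol(adf, bdf)
  err <- check_valence(mol)
  if (!isTRUE(err)) parse_error(smiles, err)
  mol
}

#' Parse a dot-separated SMILES species list
#'
#' @param smiles SMILES, possibly with `.`-separated components.
#' @return A list of molecule objects, one per component.
#' @export
parse_species <- function(smiles) {
  parts <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  lapply(parts, parse_molecule)
}

# ---- structural derivations ----------------------------------------------

adjacency_list <- function(mol) {
  adj <- vector("list", n_atoms(mol))
  if (n_bonds(mol) > 0L) {
    for (k in seq_len(n_bonds(mol))) {
      a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
      adj[[a1]] <- c(adj[[a1]], k)
      adj[[a2]] <- c(adj[[a2]], k)
    }
  }
  adj
}

#' Atom degree (heavy + hydrogen neighbours)
#'
#' @inheritParams n_atoms
#' @return Integer vector over atoms.
#' @export
atom_degree <- function(mol) {
  d <- integer(n_atoms(mol))
  if (n_bonds(mol) > 0L) {
    t1 <- table(factor(mol$bonds$a1, levels = seq_len(n_atoms(mol))))
    t2 <- table(factor(mol$bonds$a2, levels = seq_len(n_atoms(mol))))
    d <- as.integer(t1 + t2)
  }
  d
}

# bridge bonds by iterative DFS (Tarjan low-link); a bond is in a ring iff
# it is not a bridge within its connected component.
bridge_bonds <- function(mol) {
  na <- n_atoms(mol); nb <- n_bonds(mol)
  if (nb == 0L) return(logical(0))
  adj <- adjacency_list(mol)
  disc <- integer(na); low <- integer(na)
  is_bridge <- logical(nb)
  timer <- 0L
  for (root in seq_len(na)) {
    if (disc[root] != 0L) next
    # stack frames: atom, parent bond, next adj position
    stack <- list(list(a = root, pb = 0L, i = 1L))
    timer <- timer + 1L; disc[root] <- low[root] <- timer
    while (length(stack) > 0L) {
      fr <- stack[[length(stack)]]
      if (fr$i <= length(adj[[fr$a]])) {
        k <- adj[[fr$a]][fr$i]
        stack[[length(stack)]]$i <- fr$i + 1L
        if (k == fr$pb) next
        nb_atom <- if (mol$bonds$a1[k] == fr$a) mol$bonds$a2[k] else mol$bonds$a1[k]
        if (disc[nb_atom] == 0L) {
          timer <- timer + 1L; disc[nb_atom] <- low[nb_atom] <- timer
          stack[[length(stack) + 1L]] <- list(a = nb_atom, pb = k, i = 1L)
        } else {
          low[fr$a] <- min(low[fr$a], disc[nb_atom])
        }
      } else {
        stack[[length(stack)]] <- NULL
        if (length(stack) > 0L) {
          par <- stack[[length(stack)]]$a
          low[par] <- min(low[par], low[fr$a])
          if (low[fr$a] > disc[par]) is_bridge[fr$pb] <- TRUE
        }
      }
    }
  }
  is_bridge
}

#' Ring membership of bonds and atoms
#'
#' A bond is in a ring iff it lies on some cycle; an atom is in a ring iff
#' it is an endpoint of such a bond.
#'
#' @inheritParams n_atoms
#' @return Logical vector over bonds ([ring_bonds()]) or atoms ([ring_atoms()]).
#' @export
ring_bonds <- function(mol) {
  if (n_bonds(mol) == 0L) return(logical(0))
  !bridge_bonds(mol)
}

#' @rdname ring_bonds
#' @export
ring_atoms <- function(mol) {
  out <- logical(n_atoms(mol))
  rb <- ring_bonds(mol)
  if (any(rb)) {
    out[unique(c(mol$bonds$a1[rb], mol$bonds$a2[rb]))] <- TRUE
  }
  out
}

#' Hybridization tags
#'
#' Assigned from the pi system: a triple bond or two or more double bonds
#' gives `sp`; any double or aromatic bond gives `sp2`; hydrogens are `s`;
#' everything else is `sp3`.
#'
#' @inheritParams n_atoms
#' @return Character vector over atoms, values in `c("s","sp","sp2","sp3")`.
#' @export
hybridization <- function(mol) {
  na <- n_atoms(mol)
  ndouble <- integer(na); ntriple <- integer(na); narom <- integer(na)
  if (n_bonds(mol) > 0L) {
    for (k in seq_len(n_bonds(mol))) {
      a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
      switch(mol$bonds$order[k],
             double = { ndouble[a1] <- ndouble[a1] + 1L; ndouble[a2] <- ndouble[a2] + 1L },
             triple = { ntriple[a1] <- ntriple[a1] + 1L; ntriple[a2] <- ntriple[a2] + 1L },
             aromatic = { narom[a1] <- narom[a1] + 1L; narom[a2] <- narom[a2] + 1L },
             NULL)
    }
  }
  out <- rep("sp3", na)
  out[ndouble >= 1L | narom >= 1L] <- "sp2"
  out[ntriple >= 1L | ndouble >= 2L] <- "sp"
  out[mol$atoms$symbol == "H"] <- "s"
  out
}

# Allowed total bond-order sums per element and formal charge.
allowed_valences <- function(symbol, charge) {
  base <- switch(symbol,
                 H = 1L, C = 4L, N = 3L, O = 2L, F = 1L, S = c(2L, 4L, 6L),
                 Cl = 1L, integer(0))
  if (symbol %in% c("N", "O", "S", "F", "Cl", "H")) {
    # cations gain a bond (e.g. hydronium O, iminium N), anions lose one
    v <- base + charge
    v <- v[v >= 0L]
    if (charge < 0L && length(v) == 0L) v <- 0L
    v
  } else if (symbol == "C") {
    if (charge == 0L) 4L else if (abs(charge) == 1L) 3L else integer(0)
  } else base
}

#' Valence sanity check
#'
#' Verifies that every atom's total bond order is consistent with its
#' element and formal charge (aromatic bonds count 1.5, rounded up).
#'
#' @inheritParams n_atoms
#' @return `TRUE`, or a character string describing the first violation.
#' @export
check_valence <- function(mol) {
  bsum <- numeric(n_atoms(mol))
  if (n_bonds(mol) > 0L) {
    v <- .ORDER_VALUE[mol$bonds$order]
    for (k in seq_len(n_bonds(mol))) {
      bsum[mol$bonds$a1[k]] <- bsum[mol$bonds$a1[k]] + v[k]
      bsum[mol$bonds$a2[k]] <- bsum[mol$bonds$a2[k]] + v[k]
    }
  }
  for (a in seq_len(n_atoms(mol))) {
    tot <- as.integer(ceiling(bsum[a] - 1e-9))
    tot_lo <- as.integer(floor(bsum[a] + 1e-9))  # fused aromatics: 3 x 1.5
    ok <- allowed_valences(mol$atoms$symbol[a], mol$atoms$charge[a])
    if (tot_lo %in% ok) tot <- tot_lo
    if (!(tot %in% ok)) {
      return(sprintf("atom %d (%s, charge %+d) has bond-order sum %d; allowed {%s}",
                     a, mol$atoms$symbol[a], mol$atoms$charge[a], tot,
                     paste(ok, collapse = ",")))
    }
  }
  TRUE
}

# ---- graph edits ----------------------------------------------------------

mol_add_atom <- function(mol, symbol, charge = 0L, map = 0L, aromatic = FALSE) {
  mol$atoms <- rbind(mol$atoms,
                     data.frame(symbol = symbol, charge = as.integer(charge),
                                aromatic = aromatic, map = as.integer(map),
                                stringsAsFactors = FALSE))
  rownames(mol$atoms) <- NULL
  mol
}

mol_add_bond <- function(mol, a1, a2, order = "single") {
  stopifnot(a1 >= 1, a2 >= 1, a1 <= n_atoms(mol), a2 <= n_atoms(mol), a1 != a2)
  mol$bonds <- rbind(mol$bonds,
                     data.frame(a1 = as.integer(a1), a2 = as.integer(a2),
                                order = order, stringsAsFactors = FALSE))
  rownames(mol$bonds) <- NULL
  mol
}

find_bond <- function(mol, a1, a2) {
  which((mol$bonds$a1 == a1 & mol$bonds$a2 == a2) |
        (mol$bonds$a1 == a2 & mol$bonds$a2 == a1))
}

mol_remove_bond <- function(mol, a1, a2) {
  k <- find_bond(mol, a1, a2)
  if (length(k) == 0L) stop(sprintf("no bond between atoms %d and %d", a1, a2))
  mol$bonds <- mol$bonds[-k[1], , drop = FALSE]
  rownames(mol$bonds) <- NULL
  mol
}

mol_set_bond_order <- function(mol, a1, a2, order) {
  k <- find_bond(mol, a1, a2)
  if (length(k) == 0L) stop(sprintf("no bond between atoms %d and %d", a1, a2))
  mol$bonds$order[k[1]] <- order
  mol
}

mol_set_charge <- function(mol, atom, charge) {
  mol$atoms$charge[atom] <- as.integer(charge)
  mol
}

#' Combine molecules into one graph (disjoint union)
#'
#' @param mols list of molecules.
#' @return One molecule whose atoms are the concatenation of the inputs.
#' @export
mol_combine <- function(mols) {
  atoms <- empty_atoms(); bonds <- empty_bonds()
  off <- 0L
  for (m in mols) {
    atoms <- rbind(atoms, m$atoms)
    if (n_bonds(m) > 0L) {
      b <- m$bonds
      b$a1 <- b$a1 + off; b$a2 <- b$a2 + off
      bonds <- rbind(bonds, b)
    }
    off <- off + n_atoms(m)
  }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  new_mol(atoms, bonds)
}

#' Split a molecule graph into connected components
#'
#' @inheritParams n_atoms
#' @return List of molecules, ordered by the smallest original atom index
#'   in each component.
#' @export
mol_components <- function(mol) {
  na <- n_atoms(mol)
  comp <- integer(na)
  adj <- adjacency_list(mol)
  cid <- 0L
  for (s in seq_len(na)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s; comp[s] <- cid
    while (length(queue) > 0L) {
      a <- queue[1]; queue <- queue[-1]
      for (k in adj[[a]]) {
        nb_atom <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
        if (comp[nb_atom] == 0L) { comp[nb_atom] <- cid; queue <- c(queue, nb_atom) }
      }
    }
  }
  lapply(seq_len(cid), function(ci) {
    sel <- which(comp == ci)
    remap <- integer(na); remap[sel] <- seq_along(sel)
    atoms <- mol$atoms[sel, , drop = FALSE]
    keep <- which(comp[mol$bonds$a1] == ci)
    bonds <- mol$bonds[keep, , drop = FALSE]
    if (nrow(bonds) > 0L) { bonds$a1 <- remap[bonds$a1]; bonds$a2 <- remap[bonds$a2] }
    rownames(atoms) <- NULL; rownames(bonds) <- NULL
    new_mol(atoms, bonds)
  })
}

# ---- canonical ordering & SMILES writer ----------------------------------

# Morgan-style iterative refinement; ties broken deterministically by
# seeding the lowest-index tied atom and re-refining.
canonical_ranks <- function(mol) {
  na <- n_atoms(mol)
  if (na == 1L) return(1L)
  adj <- adjacency_list(mol)
  deg <- atom_degree(mol)
  elem_idx <- match(mol$atoms$symbol, names(.ELEM))
  key0 <- paste(elem_idx, mol$atoms$charge, as.integer(mol$atoms$aromatic), deg)
  rank <- as.integer(factor(rank(match(key0, sort(unique(key0))), ties.method = "min")))
  rank <- match(key0, sort(unique(key0)))

  refine <- function(rank) {
    repeat {
      keys <- character(na)
      for (a in seq_len(na)) {
        nb <- vapply(adj[[a]], function(k) {
          o <- mol$bonds$order[k]
          nbi <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
          sprintf("%s%04d", substr(o, 1, 2), rank[nbi])
        }, character(1))
        keys[a] <- paste(sprintf("%04d", rank[a]), paste(sort(nb), collapse = "|"))
      }
      newrank <- match(keys, sort(unique(keys)))
      if (identical(newrank, rank)) return(rank)
      rank <- newrank
    }
  }
  rank <- refine(rank)
  while (max(rank) < na) {
    # break the first remaining tie class at its lowest atom index
    tied <- which(duplicated(rank) | duplicated(rank, fromLast = TRUE))
    pick <- tied[order(rank[tied], tied)][1]
    key <- rank * 2L + as.integer(seq_len(na) != pick)
    rank <- match(key, sort(unique(key)))
    rank <- refine(rank)
  }
  rank
}

needs_bracket <- function(sym, aromatic, charge, h, map, with_maps) {
  if (charge != 0L) return(TRUE)
  if (with_maps && map > 0L) return(TRUE)
  if (sym == "H") return(TRUE)
  if (!sym %in% .ORGANIC_SUBSET) return(TRUE)
  FALSE
}

atom_token <- function(sym, aromatic, charge, h, map, with_maps) {
  s <- if (aromatic && sym %in% c("C", "N", "O", "S")) tolower(sym) else sym
  if (!needs_bracket(sym, aromatic, charge, h, map, with_maps)) {
    # plain organic-subset atom: implicit-H reparse must agree, which the
    # caller guarantees by only folding the valence-completing hydrogens
    return(s)
  }
  htxt <- if (h == 0L) "" else if (h == 1L) "H" else paste0("H", h)
  ctxt <- if (charge == 0L) "" else if (charge == 1L) "+" else if (charge == -1L) "-"
          else sprintf("%+d", charge)
  mtxt <- if (with_maps && map > 0L) paste0(":", map) else ""
  paste0("[", s, htxt, ctxt, mtxt, "]")
}

#' Write a molecule as SMILES
#'
#' Deterministic writer: atoms are emitted in canonical (Morgan-refined)
#' order, so two isomorphic graphs produce the same string.  With
#' `with_maps = TRUE` every atom — hydrogens included — is written as an
#' explicit bracket node carrying its atom-map index; otherwise chemically
#' implicit hydrogens are folded into heavy-atom hydrogen counts.
#'
#' @inheritParams n_atoms
#' @param with_maps write atom-map indices and keep all hydrogens explicit.
#' @return A SMILES string; `parse_molecule(write_smiles(m))` is isomorphic
#'   to `m`.
#' @export
write_smiles <- function(mol, with_maps = FALSE) {
  na <- n_atoms(mol)
  if (na == 0L) stop("empty molecule")
  rank <- canonical_ranks(mol)
  adj <- adjacency_list(mol)

  fold <- logical(na)   # hydrogens folded into neighbour H counts
  hcount <- integer(na)
  if (!with_maps) {
    for (a in seq_len(na)) {
      if (mol$atoms$symbol[a] == "H" && mol$atoms$charge[a] == 0L &&
          length(adj[[a]]) == 1L) {
        k <- adj[[a]][1]
        nb <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
        if (mol$atoms$symbol[nb] != "H" && mol$bonds$order[k] == "single") {
          fold[a] <- TRUE
          hcount[nb] <- hcount[nb] + 1L
        }
      }
    }
  }
  keep <- which(!fold)
  if (length(keep) == 0L) keep <- seq_len(na)  # H2 corner case: keep all

  # bracket decision for plain atoms: reparse must infer the same H count
  bsum <- numeric(na)
  if (n_bonds(mol) > 0L) {
    v <- .ORDER_VALUE[mol$bonds$order]
    for (k in seq_len(n_bonds(mol))) {
      if (!fold[mol$bonds$a1[k]] && !fold[mol$bonds$a2[k]]) {
        bsum[mol$bonds$a1[k]] <- bsum[mol$bonds$a1[k]] + v[k]
        bsum[mol$bonds$a2[k]] <- bsum[mol$bonds$a2[k]] + v[k]
      }
    }
  }

  token_of <- function(a) {
    sym <- mol$atoms$symbol[a]
    plain_ok <- !needs_bracket(sym, mol$atoms$aromatic[a], mol$atoms$charge[a],
                               hcount[a], mol$atoms$map[a], with_maps)
    if (plain_ok) {
      val <- .ELEM[[sym]]$valence
      inferred <- max(0L, as.integer(val - ceiling(bsum[a] - 1e-9)))
      if (inferred != hcount[a]) plain_ok <- FALSE
    }
    if (plain_ok) {
      s <- if (mol$atoms$aromatic[a] && sym %in% c("C", "N", "O", "S")) tolower(sym) else sym
      s
    } else {
      atom_token(sym, mol$atoms$aromatic[a], mol$atoms$charge[a], hcount[a],
                 mol$atoms$map[a], with_maps)
    }
  }

  visited <- logical(na)
  ring_id <- 0L
  bond_sym <- function(k, from) {
    o <- mol$bonds$order[k]
    a1 <- mol$bonds$a1[k]; a2 <- mol$bonds$a2[k]
    both_arom <- mol$atoms$aromatic[a1] && mol$atoms$aromatic[a2]
    switch(o,
           single = if (both_arom) "-" else "",
           double = "=",
           triple = "#",
           aromatic = if (both_arom) "" else ":")
  }

  sorted_nbrs <- function(a) {
    nbrs <- adj[[a]]
    if (length(nbrs) == 0L) return(integer(0))
    ord <- order(rank[vapply(nbrs, function(k)
      if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k], integer(1))])
    nbrs[ord]
  }

  # pass 1: classify bonds into spanning-tree and ring-closure (back) edges
  nb_total <- n_bonds(mol)
  tree_edge <- logical(nb_total); back_edge <- logical(nb_total)
  classify <- function(a, via) {
    visited[a] <<- TRUE
    for (k in sorted_nbrs(a)) {
      nb <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
      if (fold[nb] || fold[a] || k == via || tree_edge[k] || back_edge[k]) next
      if (visited[nb]) back_edge[k] <<- TRUE
      else { tree_edge[k] <<- TRUE; classify(nb, k) }
    }
  }

  # pass 2: emit tokens; ring digits assigned at first encounter of each
  # back edge and re-emitted at the partner atom
  out <- character(0)
  emit <- function(x) out[[length(out) + 1L]] <<- x
  ring_digit <- list()
  rec <- function(a, via) {
    if (via != 0L) emit(bond_sym(via, a))
    emit(token_of(a))
    kids <- integer(0)
    for (k in sorted_nbrs(a)) {
      nb <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
      if (fold[nb] || k == via) next
      if (back_edge[k]) {
        key <- as.character(k)
        if (is.null(ring_digit[[key]])) {
          ring_id <<- ring_id + 1L
          ring_digit[[key]] <<- if (ring_id < 10L) as.character(ring_id)
                                else sprintf("%%%02d", ring_id)
        }
        emit(bond_sym(k, a)); emit(ring_digit[[key]])
      } else if (tree_edge[k]) kids <- c(kids, k)
    }
    for (idx in seq_along(kids)) {
      k <- kids[idx]
      nb <- if (mol$bonds$a1[k] == a) mol$bonds$a2[k] else mol$bonds$a1[k]
      last <- idx == length(kids)
      if (!last) emit("(")
      rec(nb, k)
      if (!last) emit(")")
    }
  }

  comps <- split(keep, {
    # component labels among kept atoms
    na_all <- na
    comp <- integer(na_all)
    cid <- 0L
    for (s in seq_len(na_all)) {
      if (comp[s] != 0L) next
      cid <- cid + 1L
      queue <- s; comp[s] <- cid
      while (length(queue) > 0L) {
        x <- queue[1]; queue <- queue[-1]
        for (k in adj[[x]]) {
          nb2 <- if (mol$bonds$a1[k] == x) mol$bonds$a2[k] else mol$bonds$a1[k]
          if (comp[nb2] == 0L) { comp[nb2] <- cid; queue <- c(queue, nb2) }
        }
      }
    }
    comp[keep]
  })
  pieces <- character(0)
  for (cc in comps) {
    start <- cc[which.min(rank[cc])]
    classify(start, 0L)
    out <- character(0)
    rec(start, 0L)
    pieces <- c(pieces, paste(out, collapse = ""))
  }
  paste(pieces, collapse = ".")
}
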