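# Atom / bond / global featurization shared by the template engine outputs
# and the network.  The schema is versioned; serialized graphs and trained
# models embed the version and refuse mismatched inputs.

#' Feature schema version
#'
#' @return Character scalar identifying the featurization layout.
#' @export
feature_schema_version <- function() "hydro-feat-1"

.HYBRID_TAGS <- c("s", "sp", "sp2", "sp3")

#' Functional-group catalog identifiers
#'
#' Stable ordering of the 13 hydrolyzable functional groups; this order
#' defines the functional-group one-hot block of the global features.
#'
#' @return Character vector of group ids.
#' @export
fg_catalog_ids <- function() {
  c("lactone", "nitrile", "lactam", "imide", "nitrogen-sulfur cleavage",
    "enamine", "amide", "cyclic carbonate", "aliphatic fluoride",
    "carboxylic acid ester", "carbamate", "urea", "epoxide")
}

#' Feature dimensionalities under the current schema
#'
#' @return Named list with `atom`, `bond` and `global` dimensions.
#' @export
feature_dims <- function() {
  list(atom = 7L + 1L + 1L + 1L + length(.HYBRID_TAGS) + 1L,
       bond = 4L + 1L + 1L,
       global = 4L + length(fg_catalog_ids()))
}

schema_error <- function(msg) {
  stop(structure(class = c("hydro_schema_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Featurize all atoms of a molecule
#'
#' Per-atom features: element one-hot over \{H,C,N,O,F,S,Cl\}, degree,
#' atomic weight (amu), in-ring flag, hybridization one-hot
#' (s/sp/sp2/sp3) and formal charge.
#'
#' @inheritParams n_atoms
#' @return Numeric matrix, one row per atom, `feature_dims()$atom` columns.
#' @export
featurize_atoms <- function(mol) {
  syms <- mol$atoms$symbol
  bad <- setdiff(unique(syms), names(.ELEM))
  if (length(bad) > 0L)
    schema_error(sprintf("element(s) outside vocabulary: %s",
                         paste(bad, collapse = ", ")))
  na <- n_atoms(mol)
  elem <- matrix(0, na, length(.ELEM),
                 dimnames = list(NULL, paste0("elem_", names(.ELEM))))
  elem[cbind(seq_len(na), match(syms, names(.ELEM)))] <- 1
  hyb <- hybridization(mol)
  hybm <- matrix(0, na, length(.HYBRID_TAGS),
                 dimnames = list(NULL, paste0("hyb_", .HYBRID_TAGS)))
  hybm[cbind(seq_len(na), match(hyb, .HYBRID_TAGS))] <- 1
  w <- vapply(.ELEM, `[[`, numeric(1), "weight")
  out <- cbind(elem,
               degree = atom_degree(mol),
               weight = unname(w[syms]),
               in_ring = as.numeric(ring_atoms(mol)),
               hybm,
               charge = as.numeric(mol$atoms$charge))
  stopifnot(ncol(out) == feature_dims()$atom)
  out
}

#' Featurize one atom
#'
#' @inheritParams n_atoms
#' @param atom atom index in `mol`.
#' @return Named numeric vector (one row of [featurize_atoms()]).
#' @export
featurize_atom <- function(mol, atom) {
  if (atom < 1L || atom > n_atoms(mol)) schema_error("atom index out of range")
  featurize_atoms(mol)[atom, ]
}

#' Featurize all bonds of a molecule
#'
#' Per-bond features: bond-order one-hot (single/double/triple/aromatic),
#' in-ring flag, and a conjugation flag (both endpoints carry pi systems).
#'
#' @inheritParams n_atoms
#' @return Numeric matrix, one row per bond, `feature_dims()$bond` columns.
#' @export
featurize_bonds <- function(mol) {
  nb <- n_bonds(mol)
  ord <- matrix(0, nb, 4L,
                dimnames = list(NULL, paste0("order_", .BOND_ORDERS)))
  if (nb > 0L) ord[cbind(seq_len(nb), match(mol$bonds$order, .BOND_ORDERS))] <- 1
  hyb <- hybridization(mol)
  conj <- if (nb > 0L) {
    as.numeric(mol$bonds$order == "aromatic" |
               (hyb[mol$bonds$a1] %in% c("sp", "sp2") &
                hyb[mol$bonds$a2] %in% c("sp", "sp2")))
  } else numeric(0)
  out <- cbind(ord,
               in_ring = as.numeric(ring_bonds(mol)),
               conjugated = conj)
  stopifnot(ncol(out) == feature_dims()$bond)
  out
}

#' @rdname featurize_bonds
#' @param bond bond index in `mol`.
#' @export
featurize_bond <- function(mol, bond) {
  if (bond < 1L || bond > n_bonds(mol)) schema_error("bond index out of range")
  featurize_bonds(mol)[bond, ]
}

#' Featurize one side of a reaction
#'
#' Aggregates over every species on the side: atom count, bond count,
#' molecular weight (amu), total formal charge, and the one-hot encoding
#' of the hydrolyzing functional group.
#'
#' @param species a molecule or list of molecules (one reaction side).
#' @param fg_label functional-group id from [fg_catalog_ids()].
#' @return Named numeric vector of length `feature_dims()$global`.
#' @export
featurize_global <- function(species, fg_label) {
  if (inherits(species, "hydro_mol")) species <- list(species)
  ids <- fg_catalog_ids()
  if (!fg_label %in% ids)
    schema_error(sprintf("unknown functional-group label '%s'", fg_label))
  fg <- as.numeric(ids == fg_label)
  names(fg) <- paste0("fg_", gsub("[^a-z]+", "_", ids))
  out <- c(n_atoms = sum(vapply(species, n_atoms, integer(1))),
           n_bonds = sum(vapply(species, n_bonds, integer(1))),
           mol_weight = molecular_weight(species),
           total_charge = sum(vapply(species, total_charge, integer(1))),
           fg)
  stopifnot(length(out) == feature_dims()$global)
  out
}
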