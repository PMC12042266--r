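# Union reaction graphs: atom nodes mapped across both sides, bond nodes
# the union of reactant and product bond sets (keyed by unordered mapped
# atom-index pairs), one global node, and product-minus-reactant
# difference features with zero vectors standing in for the absent side.

mapping_error <- function(msg) {
  stop(structure(class = c("hydro_mapping_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

side_atom_table <- function(species) {
  maps <- unlist(lapply(species, function(m) m$atoms$map))
  sp <- rep(seq_along(species), vapply(species, n_atoms, integer(1)))
  at <- unlist(lapply(species, function(m) seq_len(n_atoms(m))))
  data.frame(map = maps, species = sp, atom = at)
}

#' Total atom bijection of a reaction
#'
#' Uses the atom-map indices carried on every atom (hydrogens included) to
#' pair each reactant atom with its product counterpart.  The result is
#' independent of species ordering on either side.
#'
#' @param rxn a `hydro_reaction` (or any object with mapped `reactants` and
#'   `products` lists).
#' @return Data frame with one row per mapped atom: `map`,
#'   `r_species`, `r_atom`, `p_species`, `p_atom`, ordered by `map`.
#' @export
map_reaction_atoms <- function(rxn) {
  rt <- side_atom_table(rxn$reactants)
  pt <- side_atom_table(rxn$products)
  if (any(rt$map <= 0L) || any(pt$map <= 0L))
    mapping_error("unmapped atom (map index 0) on a reaction side")
  if (anyDuplicated(rt$map))
    mapping_error(sprintf("duplicated reactant map index %d",
                          rt$map[duplicated(rt$map)][1]))
  if (anyDuplicated(pt$map))
    mapping_error(sprintf("duplicated product map index %d",
                          pt$map[duplicated(pt$map)][1]))
  if (!setequal(rt$map, pt$map))
    mapping_error(sprintf("atom map is not a bijection: %d reactant vs %d product atoms, first unpaired index %s",
                          nrow(rt), nrow(pt),
                          paste(union(setdiff(rt$map, pt$map),
                                      setdiff(pt$map, rt$map))[1])))
  rt <- rt[order(rt$map), ]; pt <- pt[order(pt$map), ]
  data.frame(map = rt$map,
             r_species = rt$species, r_atom = rt$atom,
             p_species = pt$species, p_atom = pt$atom)
}

side_bond_table <- function(species, atab) {
  # bonds keyed by sorted mapped atom pairs; features per bond
  rows <- list()
  for (si in seq_along(species)) {
    m <- species[[si]]
    if (n_bonds(m) == 0L) next
    bf <- featurize_bonds(m)
    for (k in seq_len(n_bonds(m))) {
      key <- sort(c(m$atoms$map[m$bonds$a1[k]], m$atoms$map[m$bonds$a2[k]]))
      rows[[length(rows) + 1L]] <- list(key = key, feat = bf[k, ])
    }
  }
  rows
}

#' Build the union reaction graph
#'
#' Atom nodes are the mapped atoms (count equal on both sides); bond nodes
#' are the union of reactant and product bond sets keyed by unordered
#' mapped-atom pairs; one global node connects to every atom and bond
#' node.  Each atom/bond node holds the product-minus-reactant feature
#' difference, with an all-zero vector standing in for the side on which a
#' bond is absent (`reactant_only` = broken, `product_only` = formed).  A
#' bond present on both sides with changed order contributes a nonzero
#' difference but stays `both`.  The global node carries the reactant-side
#' aggregate features (atom/bond counts, molecular weight, total charge —
#' the condition's charge state — and the functional-group one-hot).
#'
#' @param rxn a `hydro_reaction` with a total atom map and a `fg_id`.
#' @return A `hydro_rxn_graph`: `atom_diff` (n_atoms x d_atom),
#'   `bond_diff` (n_bonds x d_bond), `bond_flag`, `bond_atoms` (n_bonds x 2
#'   positions into the atom node order), `global` features, `maps`,
#'   `schema`, and `dG` copied from the reaction label.
#' @export
build_reaction_graph <- function(rxn) {
  atab <- map_reaction_atoms(rxn)
  nA <- nrow(atab)

  rfeat <- lapply(rxn$reactants, featurize_atoms)
  pfeat <- lapply(rxn$products, featurize_atoms)
  d_atom <- feature_dims()$atom
  atom_diff <- matrix(0, nA, d_atom)
  for (i in seq_len(nA)) {
    rf <- rfeat[[atab$r_species[i]]][atab$r_atom[i], ]
    pf <- pfeat[[atab$p_species[i]]][atab$p_atom[i], ]
    atom_diff[i, ] <- pf - rf
  }
  colnames(atom_diff) <- colnames(rfeat[[1]])

  rb <- side_bond_table(rxn$reactants, atab)
  pb <- side_bond_table(rxn$products, atab)
  rkeys <- vapply(rb, function(x) paste(x$key, collapse = "-"), character(1))
  pkeys <- vapply(pb, function(x) paste(x$key, collapse = "-"), character(1))
  all_keys <- sort(union(rkeys, pkeys))
  nB <- length(all_keys)
  d_bond <- feature_dims()$bond
  bond_diff <- matrix(0, nB, d_bond)
  colnames(bond_diff) <- names(rb[[1]]$feat) %||% colnames(featurize_bonds(water_mol()))
  flag <- character(nB)
  bond_atoms <- matrix(0L, nB, 2L)
  map_pos <- match(atab$map, atab$map)  # identity; positions by map value
  pos_of_map <- seq_len(nA); names(pos_of_map) <- as.character(atab$map)
  for (j in seq_len(nB)) {
    key <- all_keys[j]
    ri <- match(key, rkeys); pi <- match(key, pkeys)
    rf <- if (!is.na(ri)) rb[[ri]]$feat else rep(0, d_bond)
    pf <- if (!is.na(pi)) pb[[pi]]$feat else rep(0, d_bond)
    bond_diff[j, ] <- pf - rf
    flag[j] <- if (!is.na(ri) && !is.na(pi)) "both"
               else if (!is.na(ri)) "reactant_only" else "product_only"
    pair <- as.integer(strsplit(key, "-", fixed = TRUE)[[1]])
    bond_atoms[j, ] <- unname(pos_of_map[as.character(pair)])
  }

  glob <- featurize_global(rxn$reactants, rxn$fg_id)
  structure(list(atom_diff = atom_diff,
                 bond_diff = bond_diff,
                 bond_flag = flag,
                 bond_atoms = bond_atoms,
                 bond_keys = all_keys,
                 global = glob,
                 maps = atab$map,
                 fg_id = rxn$fg_id,
                 condition = rxn$condition,
                 dG = rxn$dG,
                 schema = feature_schema_version()),
            class = "hydro_rxn_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hydro_rxn_graph <- function(x, ...) {
  cat(sprintf("<reaction graph: %d atom nodes, %d bond nodes (%d both / %d broken / %d formed), schema %s>\n",
              nrow(x$atom_diff), nrow(x$bond_diff),
              sum(x$bond_flag == "both"), sum(x$bond_flag == "reactant_only"),
              sum(x$bond_flag == "product_only"), x$schema))
  invisible(x)
}

# ---- graph store ----------------------------------------------------------

graph_to_list <- function(g) {
  list(atom_diff = unclass(g$atom_diff), bond_diff = unclass(g$bond_diff),
       bond_flag = g$bond_flag, bond_atoms = g$bond_atoms,
       bond_keys = g$bond_keys, global = as.list(g$global),
       maps = g$maps, fg_id = g$fg_id, condition = g$condition,
       dG = if (is.na(g$dG)) NULL else g$dG, schema = g$schema)
}

list_to_graph <- function(x) {
  ad <- do.call(rbind, lapply(x$atom_diff, as.numeric))
  bd <- if (length(x$bond_diff) > 0L) do.call(rbind, lapply(x$bond_diff, as.numeric))
        else matrix(0, 0, feature_dims()$bond)
  ba <- if (length(x$bond_atoms) > 0L)
          matrix(as.integer(unlist(x$bond_atoms)), ncol = 2L, byrow = TRUE)
        else matrix(0L, 0, 2L)
  structure(list(atom_diff = ad, bond_diff = bd,
                 bond_flag = as.character(unlist(x$bond_flag %||% character(0))),
                 bond_atoms = ba,
                 bond_keys = as.character(unlist(x$bond_keys %||% character(0))),
                 global = unlist(x$global),
                 maps = as.integer(unlist(x$maps)),
                 fg_id = x$fg_id, condition = x$condition,
                 dG = if (is.null(x$dG) || identical(x$dG, "NA")) NA_real_
                      else as.numeric(x$dG),
                 schema = x$schema),
            class = "hydro_rxn_graph")
}

#' Precompute and serialize reaction graphs
#'
#' Builds the union reaction graph for every reaction in the dataset and
#' writes a directory store: one JSON file per graph plus a `manifest.json`
#' holding the schema version, feature dimensions and per-record status.
#' Records that fail to build are logged in the manifest with their error
#' message and skipped.
#'
#' @param reactions list of `hydro_reaction`.
#' @param dir output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
precompute_graphs <- function(reactions, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  status <- vector("list", length(reactions))
  for (i in seq_along(reactions)) {
    g <- tryCatch(build_reaction_graph(reactions[[i]]), error = function(e) e)
    if (inherits(g, "error")) {
      status[[i]] <- list(id = i, ok = FALSE, error = conditionMessage(g))
    } else {
      f <- file.path(dir, sprintf("graph-%06d.json", i))
      jsonlite::write_json(graph_to_list(g), f, digits = I(17), auto_unbox = TRUE)
      status[[i]] <- list(id = i, ok = TRUE, file = basename(f))
    }
  }
  manifest <- list(schema = feature_schema_version(),
                   dims = feature_dims(),
                   n = length(reactions),
                   records = status)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = I(17), auto_unbox = TRUE)
  invisible(manifest)
}

#' Load a serialized graph store
#'
#' @param dir store directory written by [precompute_graphs()].
#' @return List of `hydro_rxn_graph` (failed records are absent).
#' @export
load_graph_store <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  if (!file.exists(mf)) mapping_error(sprintf("no manifest.json under '%s'", dir))
  manifest <- jsonlite::read_json(mf)
  if (!identical(manifest$schema, feature_schema_version()))
    schema_error(sprintf("graph store schema '%s' does not match current '%s'",
                         manifest$schema, feature_schema_version()))
  out <- list()
  for (rec in manifest$records) {
    if (!isTRUE(rec$ok)) next
    f <- file.path(dir, rec$file)
    if (!file.exists(f))
      mapping_error(sprintf("graph store corrupt: record %d file missing", rec$id))
    out[[length(out) + 1L]] <- list_to_graph(jsonlite::read_json(f))
  }
  out
}
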