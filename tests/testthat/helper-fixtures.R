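# Shared helpers: a panel of parseable molecules spanning the catalog, and
# memoized fixture sets so expensive generation runs once per suite.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixtures <- function(n, seed, noise_sd = 0, ...) {
  key <- paste(n, seed, noise_sd, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- generate_fixtures(
      fixture_spec(n = n, seed = seed, noise_sd = noise_sd, ...))
  }
  .fixture_cache[[key]]
}

cached_graphs <- function(n, seed, noise_sd = 0) {
  key <- paste("g", n, seed, noise_sd, sep = "_")
  if (is.null(.fixture_cache[[key]])) {
    fx <- cached_fixtures(n, seed, noise_sd)
    .fixture_cache[[key]] <- lapply(fx, function(r) build_reaction_graph(r$reaction))
  }
  .fixture_cache[[key]]
}

panel_smiles <- function() {
  c(water = "O", methyl_acetate = "CC(=O)OC", hydronium = "[OH3+]",
    hydroxide = "[OH-]", benzene = "c1ccccc1", naphthalene = "c1ccc2ccccc2c1",
    acetonitrile = "CC#N", acetamide = "CC(=O)N", gbl = "O=C1CCCO1",
    pyrrolidinone = "O=C1CCCN1", ethylene_oxide = "C1CO1",
    ethylene_carbonate = "O=C1OCCO1", methyl_carbamate = "NC(=O)OC",
    dimethylurea = "CNC(=O)NC", fluoroethane = "CCF", sulfenamide = "CSNC",
    enamine = "CC=CN(C)C", cyanoester = "N#CCC(=O)OCC",
    succinimide = "O=C1CCC(=O)N1", pyridine = "c1ccncc1",
    phenyl_acetate = "CC(=O)Oc1ccccc1", charged_ester = "[O-]C(=O)C")
}

# permute the atoms of a molecule deterministically; maps travel with atoms
permute_mol <- function(mol, perm) {
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  atoms <- mol$atoms[perm, , drop = FALSE]
  bonds <- mol$bonds
  if (nrow(bonds) > 0L) { bonds$a1 <- inv[bonds$a1]; bonds$a2 <- inv[bonds$a2] }
  rownames(atoms) <- NULL; rownames(bonds) <- NULL
  structure(list(atoms = atoms, bonds = bonds), class = "hydro_mol")
}

# shuffle node order inside a reaction graph (consistent relabeling)
permute_graph <- function(g, seed) {
  set.seed(seed)
  pa <- sample(nrow(g$atom_diff))
  inv <- integer(length(pa)); inv[pa] <- seq_along(pa)
  pb <- if (nrow(g$bond_diff) > 0L) sample(nrow(g$bond_diff)) else integer(0)
  g$atom_diff <- g$atom_diff[pa, , drop = FALSE]
  g$maps <- g$maps[pa]
  if (length(pb) > 0L) {
    g$bond_diff <- g$bond_diff[pb, , drop = FALSE]
    g$bond_flag <- g$bond_flag[pb]
    g$bond_keys <- g$bond_keys[pb]
    g$bond_atoms <- matrix(inv[g$bond_atoms[pb, , drop = FALSE]], ncol = 2L)
  }
  g
}
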