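# Union reaction graphs: atom bijections, difference features, the
# both/broken/formed partition against a brute-force oracle, and the
# serialized store.

ester_reaction <- function() {
  m <- parse_molecule("CC(=O)OC")
  apply_hydrolysis_template(m, detect_functional_groups(m)[[1]])
}

# independent brute-force bond partition from raw reaction species
brute_force_partition <- function(rxn) {
  side_keys <- function(species) {
    unlist(lapply(species, function(m) {
      if (n_bonds(m) == 0L) return(character(0))
      vapply(seq_len(n_bonds(m)), function(k) {
        paste(sort(c(m$atoms$map[m$bonds$a1[k]], m$atoms$map[m$bonds$a2[k]])),
              collapse = "-")
      }, character(1))
    }))
  }
  r <- side_keys(rxn$reactants); p <- side_keys(rxn$products)
  list(both = length(intersect(r, p)),
       broken = length(setdiff(r, p)),
       formed = length(setdiff(p, r)),
       union = length(union(r, p)))
}

test_that("atom map bijection covers all atoms and survives species reordering", {
  r <- ester_reaction()
  ab <- map_reaction_atoms(r)
  expect_equal(nrow(ab), 14L)         # 11 substrate + 3 water atoms
  expect_setequal(ab$map, 1:14)

  r2 <- r; r2$products <- rev(r2$products)
  ab2 <- map_reaction_atoms(r2)
  expect_identical(ab$map, ab2$map)

  rid <- r; rid$products <- rid$reactants
  abid <- map_reaction_atoms(rid)
  expect_identical(abid$r_species, abid$p_species)
  expect_identical(abid$r_atom, abid$p_atom)

  broken_map <- r
  broken_map$products[[1]]$atoms$map[1] <- 99L
  expect_error(map_reaction_atoms(broken_map), class = "hydro_mapping_error")
  dup_map <- r
  dup_map$products[[1]]$atoms$map[2] <- dup_map$products[[1]]$atoms$map[1]
  expect_error(map_reaction_atoms(dup_map), class = "hydro_mapping_error")
})

test_that("ester graph has the hand-enumerated union structure", {
  g <- build_reaction_graph(ester_reaction())
  expect_equal(nrow(g$atom_diff), 14L)
  expect_equal(nrow(g$bond_diff), 14L)   # 10 both + 2 broken + 2 formed
  expect_equal(sum(g$bond_flag == "both"), 10L)
  expect_equal(sum(g$bond_flag == "reactant_only"), 2L)
  expect_equal(sum(g$bond_flag == "product_only"), 2L)
  expect_equal(unname(g$global["fg_carboxylic_acid_ester"]), 1)
  expect_true(all(is.finite(g$atom_diff)), all(is.finite(g$bond_diff)))
})

test_that("identity reactions give all-zero differences; reversal negates them", {
  r <- ester_reaction()
  rid <- r; rid$products <- rid$reactants
  gid <- build_reaction_graph(rid)
  expect_true(all(gid$atom_diff == 0))
  expect_true(all(gid$bond_diff == 0))
  expect_true(all(gid$bond_flag == "both"))

  g <- build_reaction_graph(r)
  rrev <- r; rrev$reactants <- r$products; rrev$products <- r$reactants
  grev <- build_reaction_graph(rrev)
  expect_equal(grev$atom_diff, -g$atom_diff, tolerance = 1e-12)
  expect_equal(grev$bond_diff, -g$bond_diff, tolerance = 1e-12)
  flips <- c(both = "both", reactant_only = "product_only",
             product_only = "reactant_only")
  expect_identical(unname(flips[g$bond_flag]), grev$bond_flag)
})

test_that("union partition matches the brute-force oracle on 200 fixtures", {
  fx <- cached_fixtures(200, seed = 31)
  for (rec in fx) {
    g <- build_reaction_graph(rec$reaction)
    bf <- brute_force_partition(rec$reaction)
    expect_equal(sum(g$bond_flag == "both"), bf$both)
    expect_equal(sum(g$bond_flag == "reactant_only"), bf$broken)
    expect_equal(sum(g$bond_flag == "product_only"), bf$formed)
    expect_equal(nrow(g$bond_diff), bf$union)
    expect_equal(nrow(g$atom_diff),
                 sum(vapply(rec$reaction$reactants, n_atoms, integer(1))))
  }
})

test_that("consistent relabeling yields an isomorphic graph with equal difference multisets", {
  r <- ester_reaction()
  g <- build_reaction_graph(r)
  # renumber the atom maps with a random bijection on both sides
  set.seed(13)
  relabel <- sample(14L)
  r2 <- r
  for (side in c("reactants", "products")) {
    r2[[side]] <- lapply(r2[[side]], function(m) {
      m$atoms$map <- relabel[m$atoms$map]; m
    })
  }
  g2 <- build_reaction_graph(r2)
  sig <- function(gg) {
    list(sort(apply(gg$atom_diff, 1, paste, collapse = ",")),
         sort(paste(apply(gg$bond_diff, 1, paste, collapse = ","), gg$bond_flag)))
  }
  expect_equal(sig(g2), sig(g))
})

test_that("graph store round trips bit-identically and deterministically", {
  fx <- cached_fixtures(30, seed = 31)
  rxns <- lapply(fx, `[[`, "reaction")
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  mf <- precompute_graphs(rxns, d1)
  expect_equal(length(mf$records), 30L)
  expect_true(all(vapply(mf$records, `[[`, logical(1), "ok")))
  back <- load_graph_store(d1)
  ref <- lapply(rxns, build_reaction_graph)
  expect_equal(length(back), 30L)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$atom_diff, unname(ref[[i]]$atom_diff))
    expect_identical(back[[i]]$bond_diff, unname(ref[[i]]$bond_diff))
    expect_identical(back[[i]]$bond_flag, ref[[i]]$bond_flag)
    expect_identical(back[[i]]$dG, ref[[i]]$dG)
  }
  # identical bytes when built twice from the same input
  precompute_graphs(rxns, d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # empty store round trip
  d3 <- withr::local_tempdir()
  precompute_graphs(list(), d3)
  expect_length(load_graph_store(d3), 0L)
  # corrupt store surfaces the offending record
  file.remove(file.path(d1, "graph-000001.json"))
  expect_error(load_graph_store(d1), class = "hydro_mapping_error")
})
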