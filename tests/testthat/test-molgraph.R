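# Molecular data model: parsing, writing, valence, ring/hybridization
# derivations and featurization.

test_that("parsing gives explicit-hydrogen graphs with correct counts and charges", {
  w <- parse_molecule("O")
  expect_equal(n_atoms(w), 3L)        # 1 O + 2 H
  expect_equal(n_bonds(w), 2L)
  expect_equal(total_charge(w), 0L)

  m <- parse_molecule("CC(=O)OC")     # methyl acetate, hand count with H
  expect_equal(n_atoms(m), 11L)
  expect_equal(n_bonds(m), 10L)
  expect_equal(total_charge(m), 0L)

  h3o <- parse_molecule("[OH3+]")
  expect_equal(total_charge(h3o), 1L)
  expect_equal(h3o$atoms$charge[h3o$atoms$symbol == "O"], 1L)

  oh <- parse_molecule("[OH-]")
  expect_equal(n_atoms(oh), 2L)
  expect_equal(total_charge(oh), -1L)
})

test_that("unparsable or out-of-vocabulary input raises a parse error naming it", {
  expect_error(parse_molecule("C(("), class = "hydro_parse_error")
  expect_error(parse_molecule("CC(=O"), class = "hydro_parse_error")
  expect_error(parse_molecule("[Br]"), regexp = "Br")
  expect_error(parse_molecule("CP(C)C"), class = "hydro_parse_error")
  expect_error(parse_molecule("C1CC"), regexp = "ring")
})

test_that("write/parse round trip preserves counts, charge and identity", {
  for (s in panel_smiles()) {
    m <- parse_molecule(s)
    w <- write_smiles(m)
    m2 <- parse_molecule(w)
    expect_equal(n_atoms(m2), n_atoms(m), info = s)
    expect_equal(n_bonds(m2), n_bonds(m), info = s)
    expect_equal(total_charge(m2), total_charge(m), info = s)
    expect_equal(element_multiset(m2), element_multiset(m), info = s)
    expect_identical(write_smiles(m2), w, info = s)   # writer is a fixed point
  }
})

test_that("canonical writer is invariant under atom relabeling", {
  set.seed(4)
  for (s in c("CC(=O)OC", "N#CCC(=O)OCC", "O=C1CCCO1", "c1ccc2ccccc2c1")) {
    m <- parse_molecule(s)
    ref <- write_smiles(m)
    for (k in 1:5) {
      pm <- permute_mol(m, sample(n_atoms(m)))
      expect_identical(write_smiles(pm), ref, info = s)
    }
  }
})

test_that("canonical SMILES agree with the OpenBabel oracle across the panel", {
  library(ChemmineOB)
  for (s in panel_smiles()) {
    m <- parse_molecule(s)
    ob_in <- trimws(convertFormat("SMI", "CAN", s))
    ob_out <- trimws(convertFormat("SMI", "CAN", write_smiles(m)))
    expect_identical(ob_out, ob_in, info = s)
  }
})

test_that("ring and hybridization derivations match hand expectations", {
  m <- parse_molecule("CC(=O)OC")
  expect_false(any(ring_atoms(m)))
  hyb <- hybridization(m)
  expect_equal(hyb[2], "sp2")         # carbonyl carbon
  expect_equal(hyb[1], "sp3")
  expect_true(all(hyb[m$atoms$symbol == "H"] == "s"))

  e <- parse_molecule("C1CO1")
  expect_equal(sum(ring_bonds(e)), 3L)
  expect_equal(sum(ring_atoms(e)), 3L)

  n <- parse_molecule("CC#N")
  expect_equal(hybridization(n)[2:3], c("sp", "sp"))
})

test_that("atom featurization matches the schema and hand-derived values", {
  m <- parse_molecule("CC(=O)OC")
  f <- featurize_atom(m, 2L)          # carbonyl carbon
  expect_equal(unname(f["elem_C"]), 1)
  expect_equal(unname(f["degree"]), 3)
  expect_equal(unname(f["weight"]), 12.011)
  expect_equal(unname(f["in_ring"]), 0)
  expect_equal(unname(f["hyb_sp2"]), 1)

  w <- parse_molecule("O")
  fh <- featurize_atom(w, 2L)         # a hydrogen
  expect_equal(unname(fh["elem_H"]), 1)
  expect_equal(unname(fh["degree"]), 1)
  expect_equal(unname(fh["weight"]), 1.008)

  expect_identical(featurize_atoms(m), featurize_atoms(m))  # deterministic
})

test_that("one-hot blocks always sum to one", {
  for (s in panel_smiles()) {
    m <- parse_molecule(s)
    fa <- featurize_atoms(m)
    expect_true(all(abs(rowSums(fa[, 1:7, drop = FALSE]) - 1) < 1e-12), info = s)
    expect_true(all(abs(rowSums(fa[, 11:14, drop = FALSE]) - 1) < 1e-12), info = s)
    if (n_bonds(m) > 0) {
      fb <- featurize_bonds(m)
      expect_true(all(abs(rowSums(fb[, 1:4, drop = FALSE]) - 1) < 1e-12), info = s)
    }
    g <- featurize_global(m, "urea")
    expect_equal(sum(g[5:17]), 1)
  }
})

test_that("global features aggregate one reaction side", {
  m <- parse_molecule("CC(=O)OC")
  g <- featurize_global(m, "carboxylic acid ester")
  expect_equal(unname(g["n_atoms"]), 11)
  expect_equal(unname(g["n_bonds"]), 10)
  expect_equal(unname(g["mol_weight"]), 74.079, tolerance = 1e-9)
  expect_equal(unname(g["fg_carboxylic_acid_ester"]), 1)

  w <- parse_molecule("O")
  gw <- featurize_global(list(m, w), "carboxylic acid ester")
  expect_equal(unname(gw["n_atoms"]), 14)
  expect_equal(unname(gw["n_bonds"]), 12)

  expect_error(featurize_global(m, "not a group"), class = "hydro_schema_error")
})

test_that("featurization of relabeled molecules is row-permuted but equal", {
  set.seed(11)
  m <- parse_molecule("N#CCC(=O)OCC")
  f <- featurize_atoms(m)
  perm <- sample(n_atoms(m))
  pm <- permute_mol(m, perm)
  fp <- featurize_atoms(pm)
  expect_equal(fp, f[perm, , drop = FALSE], ignore_attr = TRUE)
})
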