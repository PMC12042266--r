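# Template catalog, functional-group detection, and pH-aware product
# generation with conservation guarantees.

canonical_products <- function(rxn) sort(vapply(rxn$products, write_smiles, character(1)))

test_that("built-in catalog covers the thirteen groups with populated rules", {
  cat13 <- load_template_catalog()
  expect_gte(length(cat13), 13L)
  ids <- vapply(cat13, `[[`, character(1), "fg_id")
  expect_setequal(ids, fg_catalog_ids())
  expect_true("carboxylic acid ester" %in% ids)
  urea <- cat13[[which(ids == "urea")]]
  expect_equal(urea$n_products, 3L)
  carbamate <- cat13[[which(ids == "carbamate")]]
  expect_equal(carbamate$n_products, 3L)
  for (tp in cat13) {
    expect_s3_class(tp$compiled, "hydro_smarts")   # every pattern compiles
    expect_true(all(tp$scissile >= 1L))
    expect_true(tp$n_products %in% 1:3)
    expect_false(is.na(tp$prot_site))              # protonation rule for all groups
  }
  # stable order
  expect_identical(ids, vapply(load_template_catalog(), `[[`, character(1), "fg_id"))
})

test_that("catalog YAML round trip preserves the templates", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_template_catalog(load_template_catalog(), path)
  back <- load_template_catalog(path)
  expect_equal(vapply(back, `[[`, character(1), "fg_id"), fg_catalog_ids())
  expect_equal(back[[1]]$smarts, load_template_catalog()[[1]]$smarts)
  m <- parse_molecule("CC(=O)OC")
  expect_length(detect_functional_groups(m, back), 1L)
})

test_that("detection returns one match per occurrence and deduplicates symmetry", {
  expect_length(detect_functional_groups(parse_molecule("C")), 0L)
  m <- parse_molecule("CC(=O)OC")
  hits <- detect_functional_groups(m)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$fg_id, "carboxylic acid ester")

  two <- detect_functional_groups(parse_molecule("N#CCC(=O)OCC"))
  expect_setequal(vapply(two, `[[`, character(1), "fg_id"),
                  c("nitrile", "carboxylic acid ester"))

  # diester: two independent ester occurrences
  di <- detect_functional_groups(parse_molecule("COC(=O)CC(=O)OC"))
  expect_length(di, 2L)

  # urea's mirrored match collapses to one entry
  u <- detect_functional_groups(parse_molecule("CNC(=O)NC"))
  expect_length(u, 1L)
})

test_that("imide and anhydride exclusions keep group labels disjoint", {
  succ <- detect_functional_groups(parse_molecule("O=C1CCC(=O)N1"))
  expect_true(all(vapply(succ, `[[`, character(1), "fg_id") == "imide"))
  anh <- detect_functional_groups(parse_molecule("CC(=O)OC(=O)C"))
  expect_false("carboxylic acid ester" %in% vapply(anh, `[[`, character(1), "fg_id"))
})

test_that("neutral worked examples give the textbook products", {
  m <- parse_molecule("CC(=O)OC")
  r <- apply_hydrolysis_template(m, detect_functional_groups(m)[[1]])
  expect_setequal(canonical_products(r),
                  c(write_smiles(parse_molecule("CC(=O)O")),
                    write_smiles(parse_molecule("CO"))))

  a <- parse_molecule("CC(=O)N")
  ra <- apply_hydrolysis_template(a, detect_functional_groups(a)[[1]])
  expect_setequal(canonical_products(ra),
                  c(write_smiles(parse_molecule("CC(=O)O")),
                    write_smiles(parse_molecule("N"))))

  ep <- parse_molecule("C1CO1")
  re <- enumerate_hydrolysis(ep, "neutral")
  expect_equal(canonical_products(re[[1]]),
               write_smiles(parse_molecule("OCCO")))
})

test_that("nitrile cascade emits exactly two reactions through the amide", {
  rn <- enumerate_hydrolysis(parse_molecule("CC#N"), "neutral")
  expect_length(rn, 2L)
  expect_equal(rn[[1]]$fg_id, "nitrile")
  expect_equal(canonical_products(rn[[1]]), write_smiles(parse_molecule("CC(=O)N")))
  expect_setequal(canonical_products(rn[[2]]),
                  c(write_smiles(parse_molecule("CC(=O)O")),
                    write_smiles(parse_molecule("N"))))
  # every nitrile match yields 2 reactions; non-nitrile matches yield 1
  rc <- enumerate_hydrolysis(parse_molecule("N#CCC(=O)OCC"), "neutral")
  expect_length(rc, 3L)   # nitrile + cascade + ester
})

test_that("carbamate and urea decompose into three products", {
  rc <- enumerate_hydrolysis(parse_molecule("CNC(=O)OC"), "neutral")
  expect_length(rc[[1]]$products, 3L)
  prods <- canonical_products(rc[[1]])
  expect_true(write_smiles(parse_molecule("O=C=O")) %in% prods)
  ru <- enumerate_hydrolysis(parse_molecule("CNC(=O)NC"), "neutral")
  expect_length(ru[[1]]$products, 3L)
  expect_equal(sum(prods == write_smiles(parse_molecule("O=C=O"))), 1L)
})

test_that("protonation adds one H at the template site with +1 charge", {
  m <- parse_molecule("CC(=O)OC")
  match <- detect_functional_groups(m)[[1]]
  p <- protonate(m, match)
  expect_equal(total_charge(p), 1L)
  expect_equal(n_atoms(p), n_atoms(m) + 1L)
  carbonyl_o <- match$atoms[3]
  expect_equal(p$atoms$charge[carbonyl_o], 1L)

  n <- parse_molecule("CC#N")
  mn <- detect_functional_groups(n)[[1]]
  pn <- protonate(n, mn)
  expect_equal(pn$atoms$charge[mn$atoms[1]], 1L)   # nitrile nitrogen
  expect_equal(total_charge(pn), 1L)

  # charge delta is +1 for every group in the catalog
  for (s in c("O=C1CCCO1", "CCF", "CSNC", "CNC(=O)NC", "C1CO1")) {
    mm <- parse_molecule(s)
    hit <- detect_functional_groups(mm)[[1]]
    expect_equal(total_charge(protonate(mm, hit)), total_charge(mm) + 1L, info = s)
  }
})

test_that("hydroxylation adds OH at the electrophilic site with -1 charge", {
  m <- parse_molecule("CC(=O)OC")
  match <- detect_functional_groups(m)[[1]]
  h <- hydroxylate(m, match)
  expect_equal(total_charge(h), -1L)
  expect_equal(n_atoms(h), n_atoms(m) + 2L)
  # carbonyl pi bond reduced to single, alkoxide oxygen carries the charge
  cC <- match$atoms[2]; cO <- match$atoms[3]
  k <- which((h$bonds$a1 == cC & h$bonds$a2 == cO) | (h$bonds$a1 == cO & h$bonds$a2 == cC))
  expect_equal(h$bonds$order[k], "single")
  expect_equal(h$atoms$charge[cO], -1L)

  ep <- parse_molecule("C1CO1")
  he <- hydroxylate(ep, detect_functional_groups(ep)[[1]])
  expect_equal(total_charge(he), -1L)
  expect_false(any(ring_atoms(he)))   # epoxide ring opened

  fl <- parse_molecule("CCF")
  expect_error(hydroxylate(fl, detect_functional_groups(fl)[[1]]),
               class = "hydro_condition_error")
})

test_that("acidic scheme uses two waters and emits hydronium", {
  m <- parse_molecule("CC(=O)OC")
  r <- assemble_reaction(m, detect_functional_groups(m)[[1]], "acidic")
  expect_equal(r$n_water, 2L)
  waters <- sum(vapply(r$reactants, function(x)
    identical(sort(x$atoms$symbol), c("H", "H", "O")) && total_charge(x) == 0L,
    logical(1)))
  expect_equal(waters, 2L)
  expect_equal(sum(vapply(r$reactants, total_charge, integer(1))), 1L)
  hyd <- write_smiles(parse_molecule("[OH3+]"))
  expect_true(hyd %in% canonical_products(r))
  expect_equal(sum(vapply(r$products, total_charge, integer(1))), 1L)
})

test_that("basic scheme emits hydroxide with a balancing water", {
  m <- parse_molecule("CC(=O)OC")
  r <- assemble_reaction(m, detect_functional_groups(m)[[1]], "basic")
  expect_equal(r$n_water, 1L)
  expect_equal(sum(vapply(r$reactants, total_charge, integer(1))), -1L)
  oh <- write_smiles(parse_molecule("[OH-]"))
  expect_true(oh %in% canonical_products(r))
  expect_equal(sum(vapply(r$products, total_charge, integer(1))), -1L)
})

test_that("every emitted reaction conserves elements, charge and the atom map", {
  for (s in c("CC(=O)OC", "CC#N", "CNC(=O)OC", "CNC(=O)NC", "O=C1OCCO1",
              "C1CO1", "CCF", "CSNC", "CC=CN(C)C", "O=C1CCC(=O)N1")) {
    mol <- parse_molecule(s)
    for (cond in c("neutral", "acidic", "basic")) {
      rxns <- enumerate_hydrolysis(mol, cond)
      for (r in rxns) {
        expect_true(validate_reaction(r), info = paste(s, cond))
        expect_identical(element_multiset(r$reactants), element_multiset(r$products),
                         info = paste(s, cond))
      }
    }
  }
})

test_that("enumeration is deterministic and deduplicated", {
  m <- parse_molecule("N#CCC(=O)OCC")
  a <- enumerate_hydrolysis(m, "neutral")
  b <- enumerate_hydrolysis(m, "neutral")
  expect_identical(lapply(a, reaction_smiles), lapply(b, reaction_smiles))
  keys <- vapply(a, reaction_smiles, character(1), with_maps = FALSE)
  expect_false(any(duplicated(keys)))
})

test_that("reaction SMILES carries a full atom map over both sides", {
  m <- parse_molecule("CC(=O)OC")
  r <- apply_hydrolysis_template(m, detect_functional_groups(m)[[1]])
  rs <- reaction_smiles(r, with_maps = TRUE)
  lhs_maps <- as.integer(unlist(regmatches(sub(">>.*", "", rs),
                                           gregexpr("(?<=:)[0-9]+", sub(">>.*", "", rs), perl = TRUE))))
  rhs <- sub(".*>>", "", rs)
  rhs_maps <- as.integer(unlist(regmatches(rhs, gregexpr("(?<=:)[0-9]+", rhs, perl = TRUE))))
  expect_setequal(lhs_maps, rhs_maps)
  expect_equal(sort(lhs_maps), 1:14)
})
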