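# Functional-group catalog and pH-aware hydrolysis product generation.
#
# Each template carries a substructure pattern, the scissile bond (pattern
# atom indices), the attachment rule (which matched atoms receive the water
# hydroxyl and hydrogen), protonation / hydroxylation site rules for the
# acid- and base-catalyzed schemes, and an edit script.  The generic edit
# script is the four-bond scheme: delete the scissile bond and one water
# O-H, then bond the water oxygen to the electrophilic fragment and the
# water hydrogen to the leaving fragment.  Groups whose chemistry needs
# more than one cleavage (nitrile addition, carbamate/urea/cyclic-carbonate
# decarboxylation, enamine tautomer resolution) use named edit scripts.

generation_error <- function(msg, product = NULL) {
  stop(structure(class = c("hydro_generation_error", "error", "condition"),
                 list(message = msg, call = NULL, product = product)))
}

condition_error <- function(msg) {
  stop(structure(class = c("hydro_condition_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' Load the functional-group template catalog
#'
#' Returns the built-in catalog of 13 hydrolyzable functional groups, or a
#' catalog read from a YAML file with the same keys (`fg_id`, `smarts`,
#' `scissile`, `r1`, `r2`, `prot_site`, `hydrox_site`, `carbonyl_o`,
#' `n_products`, `edit`, `post_filter`).  Catalog order is stable and
#' matches the functional-group one-hot ordering.
#'
#' @param path optional YAML file overriding the built-in catalog.
#' @return List of template objects (class `hydro_template`).
#' @export
load_template_catalog <- function(path = NULL) {
  if (!is.null(path)) {
    raw <- yaml::read_yaml(path)
    return(lapply(raw, function(tp) {
      tp$compiled <- compile_smarts(tp$smarts)
      for (f in c("scissile", "prot_site", "hydrox_site", "carbonyl_o",
                  "r1", "r2", "n_products"))
        if (!is.null(tp[[f]])) tp[[f]] <- as.integer(unlist(tp[[f]]))
      structure(tp, class = "hydro_template")
    }))
  }
  .builtin_catalog()
}

#' Write a template catalog to YAML
#'
#' @param catalog list of templates from [load_template_catalog()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_template_catalog <- function(catalog, path) {
  out <- lapply(catalog, function(tp) {
    tp$compiled <- NULL
    unclass(tp)
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

tmpl <- function(fg_id, smarts, scissile, r1, r2, prot_site, hydrox_site,
                 n_products, edit = "generic", post_filter = NA_character_,
                 carbonyl_o = NA_integer_, symmetric = FALSE) {
  structure(list(fg_id = fg_id, smarts = smarts,
                 compiled = compile_smarts(smarts),
                 scissile = as.integer(scissile),
                 r1 = as.integer(r1), r2 = as.integer(r2),
                 prot_site = as.integer(prot_site),
                 hydrox_site = as.integer(hydrox_site),
                 carbonyl_o = as.integer(carbonyl_o),
                 n_products = as.integer(n_products),
                 edit = edit, post_filter = post_filter,
                 symmetric = isTRUE(symmetric)),
            class = "hydro_template")
}

.builtin_catalog <- function() {
  list(
    tmpl("lactone", "[#6,#1;!a][CX3;R](=[OX1])[OX2;R][#6;R]",
         scissile = c(2L, 4L), r1 = 2L, r2 = 4L,
         prot_site = 3L, hydrox_site = 2L, carbonyl_o = 3L,
         n_products = 1L),
    tmpl("nitrile", "[NX1]#[CX2]",
         scissile = c(1L, 2L), r1 = 2L, r2 = 1L,
         prot_site = 1L, hydrox_site = 2L, carbonyl_o = 1L,
         n_products = 1L, edit = "nitrile"),
    tmpl("lactam", "[#6,#1;!a][CX3;R](=[OX1])[NX3;R]",
         scissile = c(2L, 4L), r1 = 2L, r2 = 4L,
         prot_site = 3L, hydrox_site = 2L, carbonyl_o = 3L,
         n_products = 1L, post_filter = "not_imide"),
    tmpl("imide", "[CX3](=[OX1])[NX3][CX3]=[OX1]",
         scissile = c(1L, 3L), r1 = 1L, r2 = 3L,
         prot_site = 2L, hydrox_site = 1L, carbonyl_o = 2L,
         n_products = 2L),
    tmpl("nitrogen-sulfur cleavage", "[NX3][SX2,SX3,SX4]",
         scissile = c(1L, 2L), r1 = 2L, r2 = 1L,
         prot_site = 1L, hydrox_site = NA_integer_, carbonyl_o = NA_integer_,
         n_products = 2L),
    tmpl("enamine", "[CX3;A]=[CX3;A][NX3;!R]",
         scissile = c(2L, 3L), r1 = 2L, r2 = 3L,
         prot_site = 3L, hydrox_site = NA_integer_, carbonyl_o = NA_integer_,
         n_products = 2L, edit = "enamine", post_filter = "not_amide_n"),
    tmpl("amide", "[#6,#1;!a][CX3;!R](=[OX1])[NX3;!R]",
         scissile = c(2L, 4L), r1 = 2L, r2 = 4L,
         prot_site = 3L, hydrox_site = 2L, carbonyl_o = 3L,
         n_products = 2L, post_filter = "not_imide"),
    tmpl("cyclic carbonate", "[OX2;R][CX3;R](=[OX1])[OX2;R]",
         scissile = c(1L, 2L), r1 = 2L, r2 = 1L,
         prot_site = 3L, hydrox_site = 2L, carbonyl_o = 3L,
         n_products = 2L, edit = "carbonate"),
    tmpl("aliphatic fluoride", "[CX4][F]",
         scissile = c(1L, 2L), r1 = 1L, r2 = 2L,
         prot_site = 2L, hydrox_site = NA_integer_, carbonyl_o = NA_integer_,
         n_products = 2L),
    tmpl("carboxylic acid ester", "[#6,#1;!a][CX3;!R](=[OX1])[OX2;!R][#6]",
         scissile = c(2L, 4L), r1 = 2L, r2 = 4L,
         prot_site = 3L, hydrox_site = 2L, carbonyl_o = 3L,
         n_products = 2L, post_filter = "not_anhydride"),
    tmpl("carbamate", "[NX3][CX3](=[OX1])[OX2][#6]",
         scissile = c(1L, 2L), r1 = 2L, r2 = 1L,
         prot_site = 3L, hydrox_site = 2L, carbonyl_o = 3L,
         n_products = 3L, edit = "carbamate"),
    tmpl("urea", "[NX3][CX3](=[OX1])[NX3]",
         scissile = c(1L, 2L), r1 = 2L, r2 = 1L,
         prot_site = 3L, hydrox_site = 2L, carbonyl_o = 3L,
         n_products = 3L, edit = "urea", symmetric = TRUE),
    tmpl("epoxide", "[CX4;R]1[OX2;R][CX4;R]1",
         scissile = c(1L, 2L), r1 = 1L, r2 = 2L,
         prot_site = 2L, hydrox_site = 1L, carbonyl_o = NA_integer_,
         n_products = 1L)
  )
}

# post filters: TRUE keeps the match ---------------------------------------

carbonyl_c_neighbors <- function(mol, atom) {
  adj <- adjacency_list(mol)
  vapply(adj[[atom]], function(k) {
    nb <- if (mol$bonds$a1[k] == atom) mol$bonds$a2[k] else mol$bonds$a1[k]
    if (mol$atoms$symbol[nb] != "C") return(FALSE)
    ks <- adjacency_list(mol)[[nb]]
    any(vapply(ks, function(k2) {
      nb2 <- if (mol$bonds$a1[k2] == nb) mol$bonds$a2[k2] else mol$bonds$a1[k2]
      mol$atoms$symbol[nb2] == "O" && mol$bonds$order[k2] == "double"
    }, logical(1)))
  }, logical(1))
}

apply_post_filter <- function(name, mol, tp, m) {
  switch(name,
    not_imide = {
      # the amide/lactam nitrogen must not sit between two carbonyls
      n_atom <- m[4L]
      sum(carbonyl_c_neighbors(mol, n_atom)) < 2L
    },
    not_amide_n = {
      n_atom <- m[3L]
      !any(carbonyl_c_neighbors(mol, n_atom))
    },
    not_anhydride = {
      # ester O's exocyclic partner must not be a second carbonyl carbon
      o_atom <- m[4L]; acyl <- m[2L]
      nbrs <- carbonyl_c_neighbors(mol, o_atom)
      adj <- adjacency_list(mol)
      others <- vapply(adj[[o_atom]], function(k) {
        if (mol$bonds$a1[k] == o_atom) mol$bonds$a2[k] else mol$bonds$a1[k]
      }, integer(1))
      !any(nbrs[others != acyl])
    },
    TRUE)
}

#' Detect hydrolyzable functional groups
#'
#' Runs every catalog template's pattern over the molecule and returns one
#' match per distinct substructure occurrence, with symmetric duplicates
#' (same atom set and same scissile bond) removed.
#'
#' @inheritParams n_atoms
#' @param catalog template catalog, defaults to the built-in one.
#' @return List of matches: `fg_id`, `atoms` (molecule atom index per
#'   pattern atom), `scissile` (molecule atom index pair), `template`.
#' @export
detect_functional_groups <- function(mol, catalog = load_template_catalog()) {
  out <- list()
  for (tp in catalog) {
    ms <- match_smarts(mol, tp$compiled)
    for (m in ms) {
      if (!is.na(tp$post_filter) && !apply_post_filter(tp$post_filter, mol, tp, m))
        next
      out[[length(out) + 1L]] <- list(
        fg_id = tp$fg_id,
        atoms = m,
        scissile = sort(c(m[tp$scissile[1]], m[tp$scissile[2]])),
        template = tp)
    }
  }
  if (length(out) > 1L) {
    # symmetric templates (urea) break the same bond set from either
    # orientation, so the mirrored match is a duplicate
    keys <- vapply(out, function(x)
      paste(x$fg_id, paste(sort(x$atoms), collapse = ","),
            if (x$template$symmetric) "" else paste(x$scissile, collapse = "-")),
      character(1))
    out <- out[!duplicated(keys)]
  }
  out
}

water_mol <- function() parse_molecule("O")  # atoms: O, H, H

# edit scripts operate on the combined substrate+water graph; indices:
# sub = match atoms (combined indices), wO/wH1/wH2 = water atoms.
apply_edit_script <- function(edit, g, sub, tp, wO, wH1, wH2) {
  switch(edit,
    generic = {
      g <- mol_remove_bond(g, sub[tp$scissile[1]], sub[tp$scissile[2]])
      g <- mol_remove_bond(g, wO, wH1)
      g <- mol_add_bond(g, sub[tp$r1], wO, "single")
      g <- mol_add_bond(g, sub[tp$r2], wH1, "single")
      g
    },
    nitrile = {
      # R-C#N + H2O -> R-C(=O)-NH2 (amide; both water hydrogens move to N)
      nN <- sub[1]; nC <- sub[2]
      g <- mol_set_bond_order(g, nN, nC, "single")
      g <- mol_remove_bond(g, wO, wH1)
      g <- mol_remove_bond(g, wO, wH2)
      g <- mol_add_bond(g, nC, wO, "double")
      g <- mol_add_bond(g, nN, wH1, "single")
      g <- mol_add_bond(g, nN, wH2, "single")
      g
    },
    carbamate = {
      # R2N-C(=O)-OR' + H2O -> R2NH + CO2 + R'OH
      nN <- sub[1]; cC <- sub[2]; oE <- sub[4]
      g <- mol_remove_bond(g, nN, cC)
      g <- mol_remove_bond(g, cC, oE)
      g <- mol_remove_bond(g, wO, wH1)
      g <- mol_remove_bond(g, wO, wH2)
      g <- mol_add_bond(g, cC, wO, "double")
      g <- mol_add_bond(g, nN, wH1, "single")
      g <- mol_add_bond(g, oE, wH2, "single")
      g
    },
    urea = {
      n1 <- sub[1]; cC <- sub[2]; n2 <- sub[4]
      g <- mol_remove_bond(g, n1, cC)
      g <- mol_remove_bond(g, cC, n2)
      g <- mol_remove_bond(g, wO, wH1)
      g <- mol_remove_bond(g, wO, wH2)
      g <- mol_add_bond(g, cC, wO, "double")
      g <- mol_add_bond(g, n1, wH1, "single")
      g <- mol_add_bond(g, n2, wH2, "single")
      g
    },
    carbonate = {
      o1 <- sub[1]; cC <- sub[2]; o2 <- sub[4]
      g <- mol_remove_bond(g, o1, cC)
      g <- mol_remove_bond(g, cC, o2)
      g <- mol_remove_bond(g, wO, wH1)
      g <- mol_remove_bond(g, wO, wH2)
      g <- mol_add_bond(g, cC, wO, "double")
      g <- mol_add_bond(g, o1, wH1, "single")
      g <- mol_add_bond(g, o2, wH2, "single")
      g
    },
    enamine = {
      # C=C-NR2 + H2O -> ketone + amine (tautomer-resolved product)
      c1 <- sub[1]; c2 <- sub[2]; nN <- sub[3]
      g <- mol_set_bond_order(g, c1, c2, "single")
      g <- mol_remove_bond(g, c2, nN)
      g <- mol_remove_bond(g, wO, wH1)
      g <- mol_remove_bond(g, wO, wH2)
      g <- mol_add_bond(g, c2, wO, "double")
      g <- mol_add_bond(g, c1, wH1, "single")
      g <- mol_add_bond(g, nN, wH2, "single")
      g
    },
    generation_error(sprintf("unknown edit script '%s'", edit)))
}

#' Apply one hydrolysis template under the neutral scheme
#'
#' Combines the substrate with one water, assigns atom-map indices over the
#' pre-edit union, applies the template's bond edits, splits the result
#' into connected components and validates each one.
#'
#' @inheritParams n_atoms
#' @param match one element of [detect_functional_groups()] output.
#' @return A `hydro_reaction`: condition, reactants (substrate + water),
#'   products, `fg_id`, `n_water`, and the atom map carried on every atom.
#' @export
apply_hydrolysis_template <- function(mol, match) {
  tp <- match$template
  na <- n_atoms(mol)
  w <- water_mol()
  g <- mol_combine(list(mol, w))
  g$atoms$map <- seq_len(n_atoms(g))
  wO <- na + 1L; wH1 <- na + 2L; wH2 <- na + 3L
  g2 <- apply_edit_script(tp$edit, g, match$atoms, tp, wO, wH1, wH2)
  comps <- mol_components(g2)
  for (cm in comps) {
    err <- check_valence(cm)
    if (!isTRUE(err))
      generation_error(sprintf("product sanitization failed for '%s' (%s): %s",
                               write_smiles(mol), tp$fg_id, err),
                       product = cm)
  }
  sub <- mol
  sub$atoms$map <- seq_len(na)
  wmol <- w
  wmol$atoms$map <- na + 1:3
  rxn <- structure(list(condition = "neutral",
                        reactants = c(list(sub), list(wmol)),
                        products = comps,
                        fg_id = tp$fg_id,
                        n_water = 1L,
                        dG = NA_real_,
                        match = list(fg_id = match$fg_id, atoms = match$atoms,
                                     scissile = match$scissile)),
                   class = "hydro_reaction")
  validate_reaction(rxn)
  rxn
}

#' @export
print.hydro_reaction <- function(x, ...) {
  cat(sprintf("<%s hydrolysis of %s | %s>\n", x$condition, x$fg_id,
              reaction_smiles(x, with_maps = FALSE)))
  invisible(x)
}

#' Reaction SMILES for a reaction object
#'
#' @param rxn a `hydro_reaction`.
#' @param with_maps include atom-map indices (hydrogens stay explicit).
#' @return `reactants>>products` SMILES string.
#' @export
reaction_smiles <- function(rxn, with_maps = TRUE) {
  lhs <- vapply(rxn$reactants, write_smiles, character(1), with_maps = with_maps)
  rhs <- vapply(rxn$products, write_smiles, character(1), with_maps = with_maps)
  if (!with_maps) { lhs <- sort(lhs); rhs <- sort(rhs) }
  paste0(paste(lhs, collapse = "."), ">>", paste(rhs, collapse = "."))
}

#' Conservation checks for a reaction
#'
#' Asserts the element multiset, the total charge and the atom-map
#' bijection are identical across the two sides; used as an internal
#' consistency guard on every emitted reaction.
#'
#' @param rxn a `hydro_reaction`.
#' @return `TRUE` invisibly; raises an internal-consistency error otherwise.
#' @export
validate_reaction <- function(rxn) {
  le <- element_multiset(rxn$reactants); re <- element_multiset(rxn$products)
  if (!identical(le, re))
    generation_error(sprintf("element conservation violated: [%s] vs [%s]",
                             paste(names(le), le, collapse = " "),
                             paste(names(re), re, collapse = " ")))
  lc <- sum(vapply(rxn$reactants, total_charge, integer(1)))
  rc <- sum(vapply(rxn$products, total_charge, integer(1)))
  if (lc != rc)
    generation_error(sprintf("charge conservation violated: %+d vs %+d", lc, rc))
  lm <- sort(unlist(lapply(rxn$reactants, function(m) m$atoms$map)))
  rm_ <- sort(unlist(lapply(rxn$products, function(m) m$atoms$map)))
  if (anyDuplicated(lm) || !identical(lm, rm_))
    generation_error("atom map is not a bijection across reaction sides")
  invisible(TRUE)
}

#' Protonate a substrate at the template's electron-rich site
#'
#' Adds one hydrogen at the protonation site (e.g. the carbonyl oxygen of
#' an ester or amide, the nitrile nitrogen) and raises that site's formal
#' charge by one, modelling the acid-catalyzed (+1) reactant state.
#'
#' @inheritParams apply_hydrolysis_template
#' @return The protonated molecule (total charge +1 relative to input).
#' @export
protonate <- function(mol, match) {
  tp <- match$template
  if (is.na(tp$prot_site))
    condition_error(sprintf("template '%s' has no protonation site rule", tp$fg_id))
  site <- match$atoms[tp$prot_site]
  mol <- mol_set_charge(mol, site, mol$atoms$charge[site] + 1L)
  mol <- mol_add_atom(mol, "H")
  mol <- mol_add_bond(mol, site, n_atoms(mol), "single")
  err <- check_valence(mol)
  if (!isTRUE(err)) generation_error(sprintf("protonation broke valence: %s", err))
  mol
}

#' Hydroxylate a substrate at the template's electrophilic site
#'
#' Adds a hydroxyl at the electrophilic site (carbonyl carbon, epoxide ring
#' carbon, nitrile carbon), reducing the adjacent pi bond — or opening the
#' epoxide ring — and placing the -1 formal charge on the displaced
#' heteroatom, modelling the base-catalyzed (-1) reactant state.
#'
#' @inheritParams apply_hydrolysis_template
#' @return The hydroxylated molecule (total charge -1 relative to input).
#' @export
hydroxylate <- function(mol, match) {
  tp <- match$template
  if (is.na(tp$hydrox_site))
    condition_error(sprintf("template '%s' has no hydroxylation site rule", tp$fg_id))
  site <- match$atoms[tp$hydrox_site]
  if (tp$fg_id == "epoxide") {
    ring_o <- match$atoms[2L]
    mol <- mol_remove_bond(mol, site, ring_o)
    mol <- mol_set_charge(mol, ring_o, mol$atoms$charge[ring_o] - 1L)
  } else if (tp$fg_id == "nitrile") {
    nN <- match$atoms[1L]
    mol <- mol_set_bond_order(mol, site, nN, "double")
    mol <- mol_set_charge(mol, nN, mol$atoms$charge[nN] - 1L)
  } else {
    cO <- match$atoms[tp$carbonyl_o]
    mol <- mol_set_bond_order(mol, site, cO, "single")
    mol <- mol_set_charge(mol, cO, mol$atoms$charge[cO] - 1L)
  }
  nO <- n_atoms(mol) + 1L
  mol <- mol_add_atom(mol, "O")
  mol <- mol_add_bond(mol, site, nO, "single")
  mol <- mol_add_atom(mol, "H")
  mol <- mol_add_bond(mol, nO, n_atoms(mol), "single")
  err <- check_valence(mol)
  if (!isTRUE(err)) generation_error(sprintf("hydroxylation broke valence: %s", err))
  mol
}

#' Assemble the full reaction for a condition
#'
#' Neutral: substrate + H2O -> products.  Acidic: protonated substrate +
#' 2 H2O -> products + hydronium (the second water absorbs the proton).
#' Basic: hydroxylated substrate + H2O -> products + hydroxide.  In the
#' charged schemes the neutral products are reused verbatim: the added
#' proton plus the extra water map onto the hydronium, and the added
#' hydroxyl maps onto the product hydroxide, so element and charge
#' conservation hold by construction.
#'
#' @inheritParams apply_hydrolysis_template
#' @param condition one of `"neutral"`, `"acidic"`, `"basic"`.
#' @return A `hydro_reaction`.
#' @export
assemble_reaction <- function(mol, match, condition = c("neutral", "acidic", "basic")) {
  condition <- match.arg(condition)
  base <- apply_hydrolysis_template(mol, match)
  if (condition == "neutral") return(base)
  na <- n_atoms(mol)
  if (condition == "acidic") {
    prot <- protonate(mol, match)
    prot$atoms$map <- c(seq_len(na), na + 7L)       # added proton
    w2 <- water_mol(); w2$atoms$map <- na + 4:6     # hydronium-forming water
    hyd <- parse_molecule("[OH3+]")                 # O H H H
    hyd$atoms$map <- c(na + 4L, na + 5L, na + 6L, na + 7L)
    rxn <- base
    rxn$condition <- "acidic"
    rxn$n_water <- 2L
    rxn$reactants <- c(list(prot), base$reactants[-1], list(w2))
    rxn$products <- c(base$products, list(hyd))
  } else {
    hx <- hydroxylate(mol, match)
    hx$atoms$map <- c(seq_len(na), na + 4L, na + 5L)  # added O, H
    oh <- parse_molecule("[OH-]")
    oh$atoms$map <- c(na + 4L, na + 5L)
    rxn <- base
    rxn$condition <- "basic"
    rxn$n_water <- 1L
    rxn$reactants <- c(list(hx), base$reactants[-1])
    rxn$products <- c(base$products, list(oh))
  }
  validate_reaction(rxn)
  rxn
}

#' Enumerate all hydrolysis reactions of a molecule
#'
#' One reaction per functional-group occurrence (independently generated
#' when several groups compete), plus, for every nitrile match, the cascade
#' reaction hydrolyzing the intermediate amide into a carboxylic acid and
#' an amine (cascade depth exactly one).  Duplicate reactions (identical
#' canonical reaction strings) are removed; per-reaction generation
#' failures are collected, not fatal.
#'
#' @inheritParams assemble_reaction
#' @param catalog template catalog.
#' @return List of `hydro_reaction`; failures are attached as the
#'   `"errors"` attribute (character vector).
#' @export
enumerate_hydrolysis <- function(mol, condition = c("neutral", "acidic", "basic"),
                                 catalog = load_template_catalog()) {
  condition <- match.arg(condition)
  matches <- detect_functional_groups(mol, catalog)
  out <- list(); errs <- character(0)
  amide_tp <- Filter(function(tp) tp$fg_id == "amide", catalog)[[1]]
  for (m in matches) {
    res <- tryCatch(assemble_reaction(mol, m, condition),
                    hydro_generation_error = function(e) e,
                    hydro_condition_error = function(e) e)
    if (inherits(res, "condition")) {
      errs <- c(errs, conditionMessage(res))
      next
    }
    out[[length(out) + 1L]] <- res
    if (m$fg_id == "nitrile") {
      cascade <- tryCatch(nitrile_cascade(mol, m, condition, amide_tp),
                          hydro_generation_error = function(e) e,
                          hydro_condition_error = function(e) e)
      if (inherits(cascade, "condition")) errs <- c(errs, conditionMessage(cascade))
      else out[[length(out) + 1L]] <- cascade
    }
  }
  if (length(out) > 1L) {
    keys <- vapply(out, function(r)
      paste(r$condition, r$fg_id, reaction_smiles(r, with_maps = FALSE)),
      character(1))
    out <- out[!duplicated(keys)]
  }
  attr(out, "errors") <- errs
  out
}

# second step of the nitrile cascade: hydrolyze the intermediate amide at
# the C-N bond formed from the original nitrile.
nitrile_cascade <- function(mol, match, condition, amide_tp) {
  first <- apply_hydrolysis_template(mol, match)
  # locate the intermediate amide component via the mapped nitrile atoms
  mapN <- match$atoms[1]; mapC <- match$atoms[2]
  inter <- NULL
  for (p in first$products) {
    if (mapC %in% p$atoms$map && mapN %in% p$atoms$map) inter <- p
  }
  if (is.null(inter)) generation_error("nitrile cascade: intermediate amide not found")
  posC <- which(inter$atoms$map == mapC)
  posN <- which(inter$atoms$map == mapN)
  inter2 <- inter
  inter2$atoms$map <- rep(0L, n_atoms(inter2))  # fresh maps assigned downstream
  # match the amide template on the intermediate and keep the occurrence
  # whose scissile bond is the former nitrile C-N
  ms <- detect_functional_groups(inter2, list(amide_tp))
  if (length(ms) == 0L)
    generation_error("nitrile cascade: amide group not detected on intermediate")
  keep <- NULL
  for (m2 in ms) {
    if (setequal(m2$scissile, c(posC, posN))) keep <- m2
  }
  if (is.null(keep))
    generation_error("nitrile cascade: formed amide bond not matched")
  assemble_reaction(inter2, keep, condition)
}
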