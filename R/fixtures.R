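# Synthetic labelled-reaction generator.  Substrates are assembled from
# per-group scaffold cores with randomized substituents, run through the
# real template engine, and labelled with an additive bond-increment
# surrogate energy: sum of increments over broken bonds minus formed
# bonds, plus a per-group offset and Gaussian noise.  The surrogate is a
# synthetic stand-in for solution-phase free energies: its magnitudes
# (tens of kcal/mol, labels spanning roughly -40..40 kcal/mol) are
# literature-flavoured but not physical.

#' Fixture generation specification
#'
#' @param n number of reaction records.
#' @param seed RNG seed; generation is a pure function of the spec.
#' @param fg_mix named proportions over functional-group ids (default:
#'   uniform over the built-in catalog).
#' @param condition_mix named proportions over conditions.
#' @param noise_sd Gaussian label noise, kcal/mol.
#' @param fg_offsets named per-group energy offsets (kcal/mol); defaults
#'   spread over roughly -18..18.
#' @return A `hydro_fixture_spec`.
#' @export
fixture_spec <- function(n = 100L, seed = 1L, fg_mix = NULL,
                         condition_mix = c(neutral = 0.6, acidic = 0.2, basic = 0.2),
                         noise_sd = 0, fg_offsets = NULL) {
  ids <- fg_catalog_ids()
  if (is.null(fg_mix)) fg_mix <- stats::setNames(rep(1 / length(ids), length(ids)), ids)
  if (is.null(fg_offsets))
    fg_offsets <- stats::setNames(3 * (seq_along(ids) - (length(ids) + 1) / 2), ids)
  stopifnot(n > 0L, noise_sd >= 0,
            abs(sum(fg_mix) - 1) < 1e-6, abs(sum(condition_mix) - 1) < 1e-6,
            all(names(fg_mix) %in% ids))
  structure(list(n = as.integer(n), seed = as.integer(seed), fg_mix = fg_mix,
                 condition_mix = condition_mix, noise_sd = noise_sd,
                 fg_offsets = fg_offsets),
            class = "hydro_fixture_spec")
}

# scaffold cores; "{R}" slots take substituents from the pool
.SCAFFOLDS <- list(
  "carboxylic acid ester" = c("{R}C(=O)OC", "{R}C(=O)OCC", "{R}C(=O)OC{R}",
                              "CC(=O)O{R}"),
  "lactone" = c("O=C1CCO1", "O=C1CCCO1", "O=C1CCCCO1", "O=C1CC(C)O1",
                "O=C1CC({R})CO1"),
  "amide" = c("{R}C(=O)N", "{R}C(=O)NC", "{R}C(=O)N(C)C", "CC(=O)N{R}"),
  "lactam" = c("O=C1CCN1", "O=C1CCCN1", "O=C1CCN1C", "O=C1CC({R})CN1"),
  "imide" = c("CC(=O)NC(=O){R}", "CC(=O)N(C)C(=O){R}", "{R}C(=O)NC(=O)C"),
  "nitrile" = c("{R}C#N", "N#C{R}", "{R}CC#N"),
  "carbamate" = c("CNC(=O)OC", "{R}NC(=O)OC", "CNC(=O)O{R}", "NC(=O)OC{R}"),
  "urea" = c("CNC(=O)NC", "{R}NC(=O)NC", "NC(=O)N{R}", "CN(C)C(=O)N{R}"),
  "cyclic carbonate" = c("O=C1OCCO1", "O=C1OCC(C)O1", "O=C1OCC({R})O1"),
  "aliphatic fluoride" = c("CCF", "{R}CF", "CC({R})F", "{R}CCF"),
  "nitrogen-sulfur cleavage" = c("CSNC", "CSN(C)C", "{R}SNC", "CCSN{R}"),
  "enamine" = c("CC=CN(C)C", "C({R})=CN(C)C", "CC=CN(C)C{R}"),
  "epoxide" = c("C1CO1", "CC1CO1", "CC1OC1C", "{R}C1CO1")
)

.SUBSTITUENTS <- c("C", "CC", "CCC", "C(C)C", "CO", "CCO", "COC", "CC(C)C")

.ATOMVAL <- c(H = 1, C = 6, N = 7, O = 8, F = 9, S = 16, Cl = 17)
.ORDER_BASE <- c(single = 60, double = 110, triple = 150, aromatic = 85)

# context key of one bond endpoint: element plus sorted neighbour elements
endpoint_key <- function(mol, atom, other, adj) {
  nbs <- vapply(adj[[atom]], function(k) {
    nb <- if (mol$bonds$a1[k] == atom) mol$bonds$a2[k] else mol$bonds$a1[k]
    nb
  }, integer(1))
  nbs <- setdiff(nbs, other)
  paste0(mol$atoms$symbol[atom], "(",
         paste(sort(mol$atoms$symbol[nbs]), collapse = ""), ")")
}

endpoint_score <- function(mol, atom, other, adj) {
  nbs <- vapply(adj[[atom]], function(k) {
    if (mol$bonds$a1[k] == atom) mol$bonds$a2[k] else mol$bonds$a1[k]
  }, integer(1))
  nbs <- setdiff(nbs, other)
  3 * .ATOMVAL[[mol$atoms$symbol[atom]]] +
    0.7 * sum(.ATOMVAL[mol$atoms$symbol[nbs]])
}

#' Bond multiset of one reaction side, keyed by context
#'
#' Keys combine both endpoints' element-plus-neighbourhood context and the
#' bond order; used by the additive surrogate energy.
#'
#' @param species list of molecules (one reaction side).
#' @return Data frame `key`, `increment` with one row per bond.
#' @export
side_bond_profile <- function(species) {
  rows <- list()
  for (m in species) {
    if (n_bonds(m) == 0L) next
    adj <- adjacency_list(m)
    for (k in seq_len(n_bonds(m))) {
      a1 <- m$bonds$a1[k]; a2 <- m$bonds$a2[k]
      e1 <- endpoint_key(m, a1, a2, adj); e2 <- endpoint_key(m, a2, a1, adj)
      ord <- m$bonds$order[k]
      key <- paste(sort(c(e1, e2))[1], ord, sort(c(e1, e2))[2], sep = "|")
      inc <- .ORDER_BASE[[ord]] + endpoint_score(m, a1, a2, adj) +
             endpoint_score(m, a2, a1, adj)
      rows[[length(rows) + 1L]] <- list(key = key, increment = unname(inc))
    }
  }
  data.frame(key = vapply(rows, `[[`, character(1), "key"),
             increment = vapply(rows, `[[`, numeric(1), "increment"))
}

multiset_diff <- function(a, b) {
  # rows of a not cancelled by rows of b (multiset semantics on key)
  counts <- table(b$key)
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    k <- a$key[i]
    if (!is.na(counts[k]) && counts[k] > 0) counts[k] <- counts[k] - 1
    else keep[i] <- TRUE
  }
  a[keep, , drop = FALSE]
}

#' Additive bond-increment surrogate energy of a reaction (kcal/mol)
#'
#' Sum of increments over broken bonds minus formed bonds (bonds whose
#' context key changes count on both sides), plus the per-group offset.
#' Noise is *not* included here; [generate_fixtures()] adds it.
#'
#' @param rxn a `hydro_reaction`.
#' @param fg_offsets named offsets per functional group (kcal/mol).
#' @return Numeric scalar.
#' @export
surrogate_energy <- function(rxn, fg_offsets = fixture_spec()$fg_offsets) {
  rp <- side_bond_profile(rxn$reactants)
  pp <- side_bond_profile(rxn$products)
  broken <- multiset_diff(rp, pp)
  formed <- multiset_diff(pp, rp)
  # 0.25 scales the raw increment differences so labels span roughly
  # -40..40 kcal/mol, mirroring the neutral free-energy range
  0.25 * (sum(broken$increment) - sum(formed$increment)) +
    unname(fg_offsets[rxn$fg_id])
}

#' Generate labelled synthetic hydrolysis reactions
#'
#' Assembles substrates from the per-group scaffolds, enumerates them with
#' the real template engine under the sampled condition, labels each kept
#' reaction with the additive surrogate energy plus Gaussian noise, and
#' returns validated reaction records.  Deterministic under the spec seed.
#'
#' @param spec a [fixture_spec()].
#' @return List of records: `reaction` (labelled `hydro_reaction`),
#'   `fg_id`, `condition`, `dG`, `source = "fixture"`.
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "hydro_fixture_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)
  fg_ids <- names(spec$fg_mix)[spec$fg_mix > 0]
  fg_p <- spec$fg_mix[fg_ids]
  cond_ids <- names(spec$condition_mix)[spec$condition_mix > 0]
  cond_p <- spec$condition_mix[cond_ids]
  unsupported_basic <- c("aliphatic fluoride", "nitrogen-sulfur cleavage", "enamine")
  catalog <- load_template_catalog()
  cache <- new.env(parent = emptyenv())  # memoize enumerations per substrate
  out <- vector("list", spec$n)
  tries <- 0L
  i <- 1L
  while (i <= spec$n) {
    tries <- tries + 1L
    if (tries > 50L * spec$n)
      generation_error("unsatisfiable fixture mix: too many rejected draws")
    fg <- sample(fg_ids, 1L, prob = fg_p)
    cond <- sample(cond_ids, 1L, prob = cond_p)
    if (cond == "basic" && fg %in% unsupported_basic) next
    core <- sample(.SCAFFOLDS[[fg]], 1L)
    while (grepl("{R}", core, fixed = TRUE)) {
      core <- sub("{R}", sample(.SUBSTITUENTS, 1L), core, fixed = TRUE)
    }
    key <- paste(core, cond, fg, sep = "@")
    if (!is.null(cache[[key]])) {
      rxns <- cache[[key]]
    } else {
      mol <- tryCatch(parse_molecule(core), error = function(e) NULL)
      if (is.null(mol)) next
      rxns <- enumerate_hydrolysis(mol, cond, catalog)
      rxns <- Filter(function(r) r$fg_id == fg, rxns)
      for (ri in seq_along(rxns))
        rxns[[ri]]$base_energy <- surrogate_energy(rxns[[ri]], spec$fg_offsets)
      cache[[key]] <- rxns
    }
    if (length(rxns) == 0L) next
    rxn <- rxns[[sample.int(length(rxns), 1L)]]
    dg <- rxn$base_energy +
          if (spec$noise_sd > 0) stats::rnorm(1, 0, spec$noise_sd) else 0
    rxn$base_energy <- NULL
    rxn$dG <- dg
    out[[i]] <- list(reaction = rxn, fg_id = rxn$fg_id, condition = cond,
                     dG = dg, source = "fixture")
    i <- i + 1L
  }
  out
}
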