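# Dataset readers/writers.  Two dialects: "jsonl" (one JSON record per
# line, the package's native exchange format) and "deposit" (CSV with
# auto-detected column names, for externally deposited reaction tables).
# Every record is validated on read: all species must parse, element
# multisets and total charge must balance, and — when atom maps are
# present — the map must be a total bijection.  Invalid records are
# rejected with per-record diagnostics, never silently dropped.

io_error <- function(msg) {
  stop(structure(class = c("hydro_io_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

.DEPOSIT_COLUMNS <- list(
  reactants = c("reactants", "reactant", "reactant_smiles", "rxn_reactants"),
  products = c("products", "product", "product_smiles", "product_list"),
  condition = c("condition", "ph_condition", "medium", "scheme"),
  fg_id = c("fg_id", "fg", "functional_group", "fg_label"),
  dG = c("dg", "dg_r", "dgr", "free_energy", "delta_g", "label"),
  source = c("source", "dataset", "origin", "tag")
)

record_to_reaction <- function(rec) {
  reactants <- parse_species(rec$reactants)
  products <- unlist(lapply(rec$products, parse_species), recursive = FALSE)
  n_water <- sum(vapply(reactants, function(m) {
    identical(sort(m$atoms$symbol), c("H", "H", "O")) && total_charge(m) == 0L
  }, logical(1)))
  structure(list(condition = rec$condition, reactants = reactants,
                 products = products, fg_id = rec$fg_id,
                 n_water = as.integer(n_water),
                 dG = if (is.null(rec$dG)) NA_real_ else as.numeric(rec$dG)),
            class = "hydro_reaction")
}

validate_record <- function(rec) {
  if (!is.character(rec$reactants) || !nzchar(rec$reactants))
    return("missing reactant SMILES")
  if (length(rec$products) == 0L) return("missing product SMILES")
  if (!rec$condition %in% c("neutral", "acidic", "basic"))
    return(sprintf("unknown condition '%s'", rec$condition))
  if (!rec$fg_id %in% fg_catalog_ids())
    return(sprintf("unknown functional group '%s'", rec$fg_id))
  if (!is.null(rec$dG) && !is.finite(as.numeric(rec$dG)))
    return("non-finite dG label")
  rxn <- tryCatch(record_to_reaction(rec), error = function(e) e)
  if (inherits(rxn, "error"))
    return(sprintf("parse failure: %s", conditionMessage(rxn)))
  le <- element_multiset(rxn$reactants); re <- element_multiset(rxn$products)
  if (!identical(le, re))
    return(sprintf("element conservation violated ([%s] vs [%s])",
                   paste(names(le), le, collapse = " "),
                   paste(names(re), re, collapse = " ")))
  lc <- sum(vapply(rxn$reactants, total_charge, integer(1)))
  rc <- sum(vapply(rxn$products, total_charge, integer(1)))
  if (lc != rc) return(sprintf("charge conservation violated (%+d vs %+d)", lc, rc))
  maps <- unlist(lapply(rxn$reactants, function(m) m$atoms$map))
  if (any(maps > 0L)) {
    chk <- tryCatch({ map_reaction_atoms(rxn); TRUE },
                    error = function(e) conditionMessage(e))
    if (!isTRUE(chk)) return(chk)
  }
  rxn
}

#' Read a reaction dataset
#'
#' @param path input file.
#' @param dialect `"jsonl"` (one JSON object per line with keys
#'   `reactants`, `products`, `condition`, `fg_id`, `dG`, `source`) or
#'   `"deposit"` (CSV; column names auto-detected against a documented
#'   candidate table, overridable via `mapping`).
#' @param mapping optional named list overriding deposit column detection,
#'   e.g. `list(reactants = "lhs", dG = "energy")`.
#' @return List of accepted records (each with the rebuilt, validated
#'   `reaction`).  Attributes: `rejected` (data frame of line numbers and
#'   diagnostics), `n_total`.
#' @export
read_reaction_dataset <- function(path, dialect = c("jsonl", "deposit"),
                                  mapping = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) io_error(sprintf("file not found: %s", path))
  raw <- if (dialect == "jsonl") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    lapply(lines, function(ln) {
      tryCatch(jsonlite::fromJSON(ln, simplifyVector = TRUE),
               error = function(e) e)
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
    cols <- stats::setNames(names(.DEPOSIT_COLUMNS), names(.DEPOSIT_COLUMNS))
    lownames <- tolower(names(df))
    for (field in names(.DEPOSIT_COLUMNS)) {
      cand <- .DEPOSIT_COLUMNS[[field]]
      if (!is.null(mapping[[field]])) { cols[field] <- mapping[[field]]; next }
      hit <- which(lownames %in% cand)
      cols[field] <- if (length(hit) > 0L) names(df)[hit[1]] else NA_character_
    }
    if (is.na(cols["reactants"]) || is.na(cols["products"]))
      io_error(sprintf("deposit dialect: cannot locate reactant/product columns among {%s}",
                       paste(names(df), collapse = ", ")))
    lapply(seq_len(nrow(df)), function(i) {
      prods <- df[[cols["products"]]][i]
      list(reactants = df[[cols["reactants"]]][i],
           products = strsplit(prods, ";", fixed = TRUE)[[1]],
           condition = if (!is.na(cols["condition"])) df[[cols["condition"]]][i] else "neutral",
           fg_id = if (!is.na(cols["fg_id"])) df[[cols["fg_id"]]][i] else NA_character_,
           dG = if (!is.na(cols["dG"])) df[[cols["dG"]]][i] else NULL,
           source = if (!is.na(cols["source"])) df[[cols["source"]]][i] else "deposit")
    })
  }
  out <- list(); rej <- list()
  for (i in seq_along(raw)) {
    rec <- raw[[i]]
    if (inherits(rec, "error")) {
      rej[[length(rej) + 1L]] <- list(line = i, reason = sprintf(
        "invalid JSON: %s", conditionMessage(rec)))
      next
    }
    rec$products <- as.character(unlist(rec$products))
    v <- validate_record(rec)
    if (is.character(v)) {
      rej[[length(rej) + 1L]] <- list(line = i, reason = v)
    } else {
      out[[length(out) + 1L]] <- list(reaction = v, fg_id = rec$fg_id,
                                      condition = rec$condition,
                                      dG = v$dG,
                                      source = rec$source %||% "unknown")
    }
  }
  attr(out, "rejected") <- if (length(rej) > 0L)
    data.frame(line = vapply(rej, `[[`, numeric(1), "line"),
               reason = vapply(rej, `[[`, character(1), "reason"))
  else data.frame(line = integer(), reason = character())
  attr(out, "n_total") <- length(raw)
  out
}

record_to_row <- function(rec) {
  rxn <- rec$reaction
  list(reactants = paste(vapply(rxn$reactants, write_smiles, character(1),
                                with_maps = TRUE), collapse = "."),
       products = vapply(rxn$products, write_smiles, character(1),
                         with_maps = TRUE),
       condition = rxn$condition,
       fg_id = rxn$fg_id,
       dG = if (is.na(rxn$dG)) NULL else rxn$dG,
       source = rec$source %||% "unknown")
}

#' Write a reaction dataset
#'
#' @param records list of records as returned by [read_reaction_dataset()]
#'   or [generate_fixtures()].
#' @param path output file.
#' @param dialect `"jsonl"` or `"deposit"` (CSV).
#' @return `path`, invisibly.
#' @export
write_reaction_dataset <- function(records, path, dialect = c("jsonl", "deposit")) {
  dialect <- match.arg(dialect)
  rows <- lapply(records, record_to_row)
  if (dialect == "jsonl") {
    con <- file(path, "w")
    on.exit(close(con))
    for (r in rows) {
      writeLines(jsonlite::toJSON(r, auto_unbox = TRUE, digits = I(17)), con)
    }
  } else {
    df <- data.frame(
      reactants = vapply(rows, `[[`, character(1), "reactants"),
      products = vapply(rows, function(r) paste(r$products, collapse = ";"),
                        character(1)),
      condition = vapply(rows, `[[`, character(1), "condition"),
      fg_id = vapply(rows, `[[`, character(1), "fg_id"),
      dG = vapply(rows, function(r) r$dG %||% NA_real_, numeric(1)),
      source = vapply(rows, `[[`, character(1), "source"))
    utils::write.csv(df, path, row.names = FALSE)
  }
  invisible(path)
}
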