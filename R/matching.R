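# The search engine: ion-hypothesis enumeration, tolerance matching and
# name/formula/SMILES matching across one or more MRDBs.
#
# Matching direction for masses: each observed m/z is algebraically
# neutralized under every ion hypothesis (charge state x adduct/deduct
# multiset) and the candidate neutral mass is compared against the stored
# neutral database masses with a vectorized window test.  By the exact
# round-trip identity of ion_mz()/neutral_mass_from_observed() this is
# equivalent to ionizing every database record, but costs
# O(hypotheses + records) per query instead of O(hypotheses x records)
# string-free scans.

#' Search parameters
#'
#' Bundles everything the engine needs to turn an observed m/z into
#' candidate identifications: the mass-deviation window (ppm or Da), the
#' electrospray mode, the range of proton charge states to consider
#' (0-5; 0 means "treat the query as a neutral/theoretical mass"), and
#' the adduct/deduct species that may shift the observed mass.
#'
#' Adducts and deducts are given as formula strings (`"Na"`, `"HCOOH"`)
#' or numeric masses in Da (`"21.9819"` or a named numeric vector); up to
#' `max_adduct_count` of them (counted jointly, with repetition) are
#' combined per hypothesis.
#'
#' @param tolerance_value Positive mass deviation.
#' @param tolerance_unit `"ppm"` or `"Da"`.
#' @param mode `"positive"` or `"negative"` electrospray mode.
#' @param max_charge Maximum number of proton charges, integer 0-5.
#' @param adducts,deducts Species specifications (see above); `NULL` for none.
#' @param max_adduct_count Maximum total adduct + deduct count per
#'   hypothesis.
#' @param mass_kind `"monoisotopic"` (default) or `"average"`; average
#'   masses may only be searched with a Da tolerance (ppm against an
#'   isotope-abundance-weighted mass is ill-defined).
#' @param include_neutral Include the z = 0 hypothesis (on by default, so
#'   neutral theoretical masses can be queried directly).
#' @param table Element mass table.
#' @return A `search_params` object.
#' @examples
#' search_params(5, "ppm", mode = "positive", max_charge = 1)
#' @export
search_params <- function(tolerance_value, tolerance_unit = c("ppm", "Da"),
                          mode = c("positive", "negative"),
                          max_charge = 1L, adducts = NULL, deducts = NULL,
                          max_adduct_count = 0L,
                          mass_kind = c("monoisotopic", "average"),
                          include_neutral = TRUE,
                          table = element_masses()) {
  tolerance_unit <- match.arg(tolerance_unit)
  mode <- match.arg(mode)
  mass_kind <- match.arg(mass_kind)
  if (!is.numeric(tolerance_value) || tolerance_value <= 0) {
    ms_input_error("tolerance_value must be > 0")
  }
  max_charge <- as.integer(max_charge)
  if (is.na(max_charge) || max_charge < 0L || max_charge > 5L) {
    ms_input_error("max_charge must be an integer between 0 and 5")
  }
  max_adduct_count <- as.integer(max_adduct_count)
  if (is.na(max_adduct_count) || max_adduct_count < 0L) {
    ms_input_error("max_adduct_count must be >= 0")
  }
  if (mass_kind == "average" && tolerance_unit == "ppm") {
    ms_input_error("average-mass searches require a Da tolerance")
  }
  structure(
    list(
      tolerance_value = as.numeric(tolerance_value),
      tolerance_unit = tolerance_unit, mode = mode,
      max_charge = max_charge,
      adducts = resolve_species(adducts, table),
      deducts = resolve_species(deducts, table),
      max_adduct_count = max_adduct_count,
      mass_kind = mass_kind, include_neutral = isTRUE(include_neutral)
    ),
    class = "search_params"
  )
}

#' @export
print.search_params <- function(x, ...) {
  cat(paste(serialize_params(x), collapse = "\n"), "\n")
  invisible(x)
}

# Adduct/deduct specification -> tibble(label, mass).  Accepts a character
# vector of formulae / numeric strings, a (possibly named) numeric vector,
# or NULL.
resolve_species <- function(spec, table = element_masses()) {
  if (is.null(spec) || length(spec) == 0L) {
    return(tibble::tibble(label = character(), mass = numeric()))
  }
  if (is.numeric(spec)) {
    labels <- if (!is.null(names(spec)) && all(nzchar(names(spec)))) {
      names(spec)
    } else formatC(spec, format = "fg")
    masses <- as.numeric(spec)
  } else {
    spec <- trimws(as.character(spec))
    labels <- spec
    masses <- vapply(spec, function(s) {
      if (grepl("^[0-9]+\\.?[0-9]*$", s)) as.numeric(s)
      else monoisotopic_mass(s, table)
    }, numeric(1L), USE.NAMES = FALSE)
  }
  if (any(!is.finite(masses)) || any(masses <= 0)) {
    ms_input_error("adduct/deduct species must resolve to positive masses")
  }
  tibble::tibble(label = labels, mass = masses)
}

#' Enumerate ion hypotheses
#'
#' Expands the search parameters into the full set of ion hypotheses the
#' engine will test: the cross product of charge states (z = 0 if
#' `include_neutral`, then z = 1..`max_charge`) with every multiset of
#' the declared adduct/deduct species of total count
#' <= `max_adduct_count`.  The z = 0 state carries no adducts or deducts
#' (there is no ionization event to attach them to).  The order is
#' deterministic: z ascending, then total species count, then species
#' labels lexicographically.
#'
#' @param params A `search_params` object.
#' @return List of hypotheses; each has `charge`, `mode`,
#'   `adduct_labels`, `adduct_masses`, `deduct_labels`, `deduct_masses`
#'   and a display `label` such as `"[M+2H+Na-H]2+"`.
#' @export
enumerate_hypotheses <- function(params) {
  stopifnot(inherits(params, "search_params"))
  species <- tibble::tibble(
    label = c(params$adducts$label, params$deducts$label),
    mass = c(params$adducts$mass, params$deducts$mass),
    sign = c(rep(1, nrow(params$adducts)), rep(-1, nrow(params$deducts)))
  )
  multisets <- enumerate_multisets(nrow(species), params$max_adduct_count)

  hyps <- list()
  charges <- c(if (params$include_neutral) 0L,
               if (params$max_charge >= 1L) seq_len(params$max_charge))
  for (z in charges) {
    sets <- if (z == 0L) multisets[1L] else multisets  # first is the empty multiset
    for (counts in sets) {
      idx <- rep(seq_along(counts), counts)
      add <- idx[species$sign[idx] > 0]
      ded <- idx[species$sign[idx] < 0]
      h <- list(
        charge = z, mode = params$mode,
        adduct_labels = species$label[add], adduct_masses = species$mass[add],
        deduct_labels = species$label[ded], deduct_masses = species$mass[ded]
      )
      h$label <- hypothesis_label(h)
      hyps[[length(hyps) + 1L]] <- h
    }
  }
  hyps
}

# All count vectors over n species with sum <= max_count, ordered by
# total count then lexicographically; first element is always the empty
# multiset.
enumerate_multisets <- function(n_species, max_count) {
  if (n_species == 0L || max_count == 0L) {
    return(list(integer(0)))
  }
  grid <- expand.grid(rep(list(0:max_count), n_species))
  grid <- grid[rowSums(grid) <= max_count, , drop = FALSE]
  grid <- grid[do.call(order, c(list(rowSums(grid)), as.list(grid))), , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(unlist(grid[i, ])))
}

# "[M]", "[M+H]+", "[M-2H+Cl]2-", "[M+2H+Na-H]2+" ...
hypothesis_label <- function(h) {
  collapse_counts <- function(labels, op) {
    if (length(labels) == 0L) return("")
    tab <- table(labels)
    paste0(vapply(names(tab), function(l) {
      k <- tab[[l]]
      paste0(op, if (k > 1L) k else "", l)
    }, character(1L)), collapse = "")
  }
  z <- h$charge
  if (z == 0L) return("[M]")
  s_op <- if (h$mode == "positive") "+" else "-"
  proton <- paste0(s_op, if (z > 1L) z else "", "H")
  body <- paste0("M", proton,
                 collapse_counts(h$adduct_labels, "+"),
                 collapse_counts(h$deduct_labels, "-"))
  paste0("[", body, "]", if (z > 1L) z else "", s_op)
}

#' Tolerance window test
#'
#' Tests whether a candidate neutral mass matches a theoretical database
#' mass within the configured deviation.  With a Da tolerance the window
#' is absolute; with ppm it is `tolerance * theoretical / 1e6` — the
#' theoretical (database) mass is the ppm reference, so the window
#' depends only on the candidate compound, not on the ion hypothesis.
#'
#' @param theoretical Theoretical mass(es) in Da (vectorized).
#' @param candidate Candidate neutral mass in Da.
#' @param params A `search_params` object.
#' @return List with logical `ok`, and numeric `deviation_da`
#'   (candidate - theoretical) and `deviation_ppm`.
#' @export
within_tolerance <- function(theoretical, candidate, params) {
  stopifnot(inherits(params, "search_params"))
  dev <- candidate - theoretical
  limit <- if (params$tolerance_unit == "Da") {
    rep(params$tolerance_value, length(theoretical))
  } else {
    params$tolerance_value * theoretical / 1e6
  }
  list(ok = abs(dev) <= limit,
       deviation_da = dev,
       deviation_ppm = 1e6 * dev / theoretical)
}

match_columns <- function() {
  tibble::tibble(
    query = character(), qtype = character(), source_line = integer(),
    db_name = character(), compound_id = character(), name = character(),
    formula = character(), theoretical_mass = numeric(),
    hypothesis = character(), charge = integer(),
    candidate_neutral_mass = numeric(),
    deviation_da = numeric(), deviation_ppm = numeric(),
    cas_id = character(), pathways = list(), payload = list(),
    matched = logical()
  )
}

record_hits <- function(mrdb, idx, query_row, hypothesis_label, charge,
                        theoretical, candidate, dev_da, dev_ppm) {
  r <- mrdb$records[idx, ]
  n <- nrow(r)
  if (n == 0L) return(match_columns())
  tibble::tibble(
    query = rep(query_row$raw, n), qtype = rep(query_row$qtype, n),
    source_line = rep(query_row$source_line, n),
    db_name = rep(mrdb$db_name, n),
    compound_id = r$compound_id, name = r$name, formula = r$formula,
    theoretical_mass = theoretical,
    hypothesis = rep(hypothesis_label, n), charge = rep(charge, n),
    candidate_neutral_mass = rep(candidate, length.out = n),
    deviation_da = dev_da, deviation_ppm = dev_ppm,
    cas_id = r$cas_id, pathways = r$pathways,
    payload = rep(query_row$payload, length.out = n),
    matched = rep(TRUE, n)
  )
}

#' Match a mass query against one MRDB
#'
#' For every ion hypothesis, the observed m/z is converted back to a
#' candidate neutral mass and compared to all stored masses of the
#' requested kind within the tolerance window.  Results are sorted by
#' absolute ppm deviation, then compound name.
#'
#' @param query_row One-row query tibble (from a `query_batch`) with
#'   `qtype == "mass"`, or a bare positive number.
#' @param mrdb An `mrdb` object.
#' @param params A `search_params` object.
#' @param hypotheses Optional pre-enumerated hypothesis list (reused
#'   across queries by [search()]).
#' @return Tibble of match rows (possibly empty).
#' @export
match_mass_query <- function(query_row, mrdb, params,
                             hypotheses = enumerate_hypotheses(params)) {
  query_row <- as_query_row(query_row, "mass")
  masses <- if (params$mass_kind == "monoisotopic") {
    mrdb$records$monoisotopic_mass
  } else {
    mrdb$records$average_mw
  }
  usable <- which(!is.na(masses))
  if (nrow(mrdb$records) > 0L && length(usable) == 0L) {
    ms_capability_error(sprintf(
      "MRDB '%s' carries no %s masses", mrdb$db_name, params$mass_kind))
  }
  out <- list()
  for (h in hypotheses) {
    cand <- tryCatch(
      neutral_mass_from_observed(query_row$mass_value, h$charge, h$mode,
                                 h$adduct_masses, h$deduct_masses),
      ms_hypothesis_error = function(e) NA_real_
    )
    if (is.na(cand)) next
    theo <- masses[usable]
    w <- within_tolerance(theo, cand, params)
    sel <- which(w$ok)
    if (length(sel) == 0L) next
    out[[length(out) + 1L]] <- record_hits(
      mrdb, usable[sel], query_row, h$label, h$charge,
      theo[sel], cand, w$deviation_da[sel], w$deviation_ppm[sel]
    )
  }
  res <- if (length(out)) do.call(rbind, out) else match_columns()
  res[order(abs(res$deviation_ppm), res$name), ]
}

as_query_row <- function(query_row, expected_type) {
  if (is.numeric(query_row)) {
    query_row <- tibble::tibble(
      raw = formatC(query_row, format = "fg"), qtype = "mass",
      mass_value = query_row, payload = list(character()), source_line = 1L
    )
  } else if (is.character(query_row)) {
    query_row <- single_query(query_row)$queries
  }
  if (!identical(query_row$qtype, expected_type)) {
    ms_input_error(sprintf("query '%s' is of type %s, expected %s",
                           query_row$raw, query_row$qtype, expected_type))
  }
  query_row
}

#' Match a name query (case-insensitive substring)
#'
#' Any compound whose name contains the query as a substring is a hit,
#' so `"glucose"` finds D-glucose as well as every glucose derivative
#' and conjugate in the database.  Matching is case-insensitive.
#'
#' @inheritParams match_mass_query
#' @return Tibble of match rows sorted by compound name.
#' @export
match_name_query <- function(query_row, mrdb, params = NULL) {
  query_row <- as_query_row(query_row, "name")
  idx <- which(grepl(tolower(query_row$raw), tolower(mrdb$records$name),
                     fixed = TRUE))
  idx <- idx[order(mrdb$records$name[idx])]
  record_hits(mrdb, idx, query_row, NA_character_, NA_integer_,
              mrdb$records$monoisotopic_mass[idx], NA_real_,
              rep(NA_real_, length(idx)), rep(NA_real_, length(idx)))
}

#' Match a formula query (element-count equality)
#'
#' Two formulae match when their element-count multisets are equal, so
#' token order is irrelevant (`"O7H8C6"` matches `"C6H8O7"`).  Records
#' with blank or unparseable formulae are skipped.
#'
#' @inheritParams match_mass_query
#' @return Tibble of match rows sorted by compound name.
#' @export
match_formula_query <- function(query_row, mrdb, params = NULL,
                                table = element_masses()) {
  query_row <- as_query_row(query_row, "formula")
  want <- parse_formula(query_row$raw, table)
  want <- want[order(names(want))]
  idx <- which(vapply(mrdb$records$formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(FALSE)
    got <- tryCatch(parse_formula(f, table), condition = function(e) NULL)
    if (is.null(got)) return(FALSE)
    got <- got[order(names(got))]
    identical(unclass(got), unclass(want))
  }, logical(1L), USE.NAMES = FALSE))
  idx <- idx[order(mrdb$records$name[idx])]
  record_hits(mrdb, idx, query_row, NA_character_, NA_integer_,
              mrdb$records$monoisotopic_mass[idx], NA_real_,
              rep(NA_real_, length(idx)), rep(NA_real_, length(idx)))
}

#' Match a SMILES query (exact string)
#'
#' SMILES strings are compared as whitespace-stripped strings, without
#' chemical canonicalization: a chemically equivalent but differently
#' written SMILES does not match (a documented limitation).  An optional
#' substring mode mirrors name-match semantics.
#'
#' @inheritParams match_mass_query
#' @param substring Match as substring instead of exact equality.
#' @return Tibble of match rows sorted by compound name.
#' @export
match_smiles_query <- function(query_row, mrdb, params = NULL,
                               substring = FALSE) {
  query_row <- as_query_row(query_row, "smiles")
  want <- trimws(query_row$raw)
  stored <- trimws(mrdb$records$smiles)
  idx <- if (substring) {
    which(nzchar(stored) & grepl(want, stored, fixed = TRUE))
  } else {
    which(nzchar(stored) & stored == want)
  }
  idx <- idx[order(mrdb$records$name[idx])]
  record_hits(mrdb, idx, query_row, NA_character_, NA_integer_,
              mrdb$records$monoisotopic_mass[idx], NA_real_,
              rep(NA_real_, length(idx)), rep(NA_real_, length(idx)))
}

#' Search a query batch against one or more MRDBs
#'
#' Dispatches every query to the matcher for its type, concatenates
#' results across databases (labelled by `db_name`), de-duplicates per
#' query and database by (compound, hypothesis), and preserves query
#' order.  Queries with no hit anywhere yield one explicit unmatched row
#' (`matched = FALSE`) so that input and output always reconcile.
#'
#' @param batch A `query_batch`.
#' @param mrdbs An `mrdb` or list of `mrdb` objects.
#' @param params A `search_params` object.
#' @return Tibble of match rows with attribute `params`.
#' @export
search_batch <- function(batch, mrdbs, params) {
  stopifnot(inherits(batch, "query_batch"), inherits(params, "search_params"))
  if (inherits(mrdbs, "mrdb")) mrdbs <- list(mrdbs)
  if (length(mrdbs) == 0L) ms_input_error("at least one MRDB is required")
  if (nrow(batch$queries) == 0L) ms_empty_error("query batch is empty")
  hypotheses <- enumerate_hypotheses(params)

  all_rows <- list()
  for (qi in seq_len(nrow(batch$queries))) {
    q <- batch$queries[qi, ]
    per_query <- list()
    for (db in mrdbs) {
      res <- tryCatch(
        switch(q$qtype,
          mass    = match_mass_query(q, db, params, hypotheses),
          name    = match_name_query(q, db),
          formula = match_formula_query(q, db),
          smiles  = match_smiles_query(q, db),
          ms_input_error(sprintf("unknown query type '%s'", q$qtype))
        ),
        metabosearch_error = function(e) {
          ms_error(sprintf("[%s] %s", db$db_name, conditionMessage(e)),
                   class(e)[1L])
        }
      )
      if (nrow(res) > 0L) {
        res <- res[!duplicated(paste(res$compound_id, res$hypothesis)), ]
        per_query[[length(per_query) + 1L]] <- res
      }
    }
    if (length(per_query) == 0L) {
      miss <- match_columns()[1, ]
      miss$query <- q$raw; miss$qtype <- q$qtype
      miss$source_line <- q$source_line
      miss$payload <- q$payload
      miss$pathways <- list(parse_pathways(""))
      miss$matched <- FALSE
      all_rows[[length(all_rows) + 1L]] <- miss
      next
    }
    rows <- do.call(rbind, per_query)
    if (q$qtype == "mass") {
      rows <- rows[order(abs(rows$deviation_ppm), rows$name, rows$db_name), ]
    } else {
      rows <- rows[order(rows$name, rows$db_name), ]
    }
    all_rows[[length(all_rows) + 1L]] <- rows
  }
  out <- do.call(rbind, all_rows)
  attr(out, "params") <- params
  out
}
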