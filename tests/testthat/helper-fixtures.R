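# Shared fixtures and the independent brute-force matcher used as the
# oracle for the search engine.  The oracle is deliberately naive: plain
# loops and inline arithmetic, no calls into the engine's matching path.

fixture_db <- function(seed = 1L, n_compounds = NULL) {
  generate_fixture_mrdb(seed = seed, n_compounds = n_compounds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small hand-built MRDB from an in-memory export table
tiny_db <- function(rows, db_name = "tiny") {
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(
      name = r$name,
      formula = r$formula %||% "",
      average_mw = r$average_mw %||% "",
      smiles = r$smiles %||% "",
      cas_id = r$cas_id %||% "",
      pathways = r$pathways %||% "",
      stringsAsFactors = FALSE
    )
  }))
  suppressMessages(build_mrdb(df, db_name = db_name))
}

H_MASS <- unname(element_masses()[["H"]])

# canonical multiset encoding shared by oracle and engine keys:
# signed species labels, sorted, comma-joined
combo_key <- function(adduct_labels, deduct_labels) {
  paste(sort(c(paste0("+", adduct_labels),
               if (length(deduct_labels)) paste0("-", deduct_labels))),
        collapse = ",")
}

# Brute-force reference matcher: for every record with a usable mass and
# every (charge, adduct/deduct multiset) hypothesis, neutralize the
# observed m/z with inline algebra and apply a direct |delta| <= limit
# check.  Returns a sorted key set "compound_id|z|combo".
brute_force_keys <- function(observed, mrdb, tol, unit, mode, max_charge,
                             adducts = numeric(), deducts = numeric(),
                             max_count = 0L, include_neutral = TRUE) {
  s <- if (mode == "positive") 1 else -1
  sp_mass <- c(adducts, -deducts)
  sp_label <- c(names(adducts) %||% character(), names(deducts) %||% character())
  sp_sign <- c(rep(1L, length(adducts)), rep(-1L, length(deducts)))
  n_sp <- length(sp_mass)
  combos <- list(integer(0))
  if (n_sp > 0L && max_count > 0L) {
    grid <- expand.grid(rep(list(0:max_count), n_sp))
    grid <- grid[rowSums(grid) <= max_count, , drop = FALSE]
    combos <- lapply(seq_len(nrow(grid)), function(i) as.integer(unlist(grid[i, ])))
  }
  keys <- character()
  recs <- mrdb$records
  for (ri in seq_len(nrow(recs))) {
    theo <- recs$monoisotopic_mass[ri]
    if (is.na(theo)) next
    limit <- if (unit == "Da") tol else tol * theo / 1e6
    charges <- c(if (include_neutral) 0L,
                 if (max_charge >= 1L) seq_len(max_charge))
    for (z in charges) {
      use_combos <- if (z == 0L) list(integer(0)) else combos
      for (cmb in use_combos) {
        shift <- if (length(cmb)) sum(rep(sp_mass, cmb)) else 0
        cand <- if (z == 0L) observed else observed * z - s * z * H_MASS - shift
        if (cand <= 0) next
        if (abs(cand - theo) <= limit) {
          idx <- rep(seq_len(n_sp), if (length(cmb)) cmb else integer(n_sp))
          key <- combo_key(sp_label[idx[sp_sign[idx] > 0]],
                           sp_label[idx[sp_sign[idx] < 0]])
          keys <- c(keys, paste0(recs$compound_id[ri], "|", z, "|", key))
        }
      }
    }
  }
  sort(unique(keys))
}

# engine result -> comparable key set (same encoding)
engine_keys <- function(results, hypotheses) {
  if (nrow(results) == 0L) return(character())
  lab2key <- stats::setNames(
    vapply(hypotheses, function(h) combo_key(h$adduct_labels, h$deduct_labels),
           character(1L)),
    vapply(hypotheses, function(h) h$label, character(1L))
  )
  sort(unique(paste0(results$compound_id, "|", results$charge, "|",
                     lab2key[results$hypothesis])))
}
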