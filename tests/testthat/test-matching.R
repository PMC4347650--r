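# The search engine: hypothesis enumeration, tolerance windows, the four
# matchers, multi-database search and its ordering/nesting properties.

test_that("hypothesis enumeration covers the charge x multiset cross product", {
  p <- search_params(5, "ppm", max_charge = 1)
  h <- enumerate_hypotheses(p)
  expect_equal(length(h), 2L)
  expect_identical(vapply(h, `[[`, character(1), "label"), c("[M]", "[M+H]+"))

  p2 <- search_params(5, "ppm", max_charge = 1, adducts = "Na",
                      max_adduct_count = 2)
  h2 <- enumerate_hypotheses(p2)
  expect_equal(length(h2), 4L)  # z=0; z=1 with {}, {Na}, {Na,Na}
  expect_identical(vapply(h2, `[[`, character(1), "label"),
                   c("[M]", "[M+H]+", "[M+H+Na]+", "[M+H+2Na]+"))

  # declared adducts with max count 0 degenerate to the no-adduct case
  p3 <- search_params(5, "ppm", max_charge = 2, adducts = c("Na", "K"),
                      max_adduct_count = 0)
  expect_equal(length(enumerate_hypotheses(p3)), 3L)

  # brute-force multiset count: 2 species, <= 2 total -> 6 multisets per z
  p4 <- search_params(5, "ppm", max_charge = 1, adducts = "Na",
                      deducts = "H2O", max_adduct_count = 2)
  h4 <- enumerate_hypotheses(p4)
  grid <- expand.grid(0:2, 0:2)
  expect_equal(length(h4), 1L + sum(rowSums(grid) <= 2))
  expect_equal(anyDuplicated(vapply(h4, `[[`, character(1), "label")), 0L)
})

test_that("negative mode and multi-charge labels read conventionally", {
  p <- search_params(5, "ppm", mode = "negative", max_charge = 2,
                     adducts = "Cl", max_adduct_count = 1)
  labs <- vapply(enumerate_hypotheses(p), `[[`, character(1), "label")
  expect_true("[M-H]-" %in% labs)
  expect_true("[M-2H]2-" %in% labs)
  expect_true("[M-H+Cl]-" %in% labs)
})

test_that("tolerance windows behave in Da and ppm", {
  pDa <- search_params(0.001, "Da")
  w <- within_tolerance(192.0270, 192.0275, pDa)
  expect_true(w$ok)
  expect_equal(w$deviation_da, 0.0005, tolerance = 1e-9)

  pppm <- search_params(5, "ppm")
  w2 <- within_tolerance(192.0270, 192.0290, pppm)
  expect_false(w2$ok)  # limit is ~0.00096 Da
  w3 <- within_tolerance(192.0270, 192.0270, pppm)
  expect_true(w3$ok)
  expect_equal(w3$deviation_da, 0)
  expect_equal(w3$deviation_ppm, 0)
})

test_that("an isobaric pair yields exactly two hits for a neutral mass query", {
  db <- fixture_db()
  p <- search_params(0.001, "Da", max_charge = 0)
  res <- match_mass_query(192.027, db, p)
  expect_equal(sort(res$name), c("citrate", "isocitrate"))
  expect_true(all(res$hypothesis == "[M]"))
  expect_true(all(abs(res$deviation_da) <= 0.001))
})

test_that("the lock-mass query hits leucine-enkephalin via [M+H]+", {
  db <- fixture_db()
  p <- search_params(5, "ppm", mode = "positive", max_charge = 1)
  res <- match_mass_query(556.2771, db, p)
  expect_true("leucine-enkephalin" %in% res$name)
  hit <- res[res$name == "leucine-enkephalin", ]
  expect_identical(hit$hypothesis, "[M+H]+")
  expect_equal(hit$charge, 1L)
})

test_that("a far-off mass and an unknown name return empty results", {
  db <- fixture_db()
  p <- search_params(0.001, "Da", max_charge = 1)
  expect_equal(nrow(match_mass_query(999.9, db, p)), 0L)
  expect_equal(nrow(match_name_query("zzz-not-a-compound", db)), 0L)
})

test_that("name matching is case-insensitive substring matching", {
  db <- fixture_db()
  res <- match_name_query("glucose", db)
  expect_equal(sort(res$name),
               c("D-glucose", "NDP-Glucoses", "alpha-methyl-glucose"))
  res_upper <- match_name_query("GLUCOSE", db)
  expect_identical(res_upper$name, res$name)
  # sorted by name
  expect_identical(res$name, res$name[order(res$name)])
})

test_that("formula matching ignores token order and misses absent formulae", {
  db <- fixture_db()
  r1 <- match_formula_query("C6H8O7", db)
  expect_equal(sort(r1$name), c("citrate", "isocitrate"))
  r2 <- match_formula_query("O7H8C6", db)
  expect_identical(r2$name, r1$name)
  expect_equal(nrow(match_formula_query("C999", db)), 0L)
})

test_that("SMILES matching is exact string matching, whitespace-tolerant", {
  db <- fixture_db()
  citrate_smiles <- db$records$smiles[db$records$name == "citrate"]
  r <- match_smiles_query(citrate_smiles, db)
  expect_identical(r$name, "citrate")
  r2 <- match_smiles_query(paste0(citrate_smiles, "  "), db)
  expect_identical(r2$name, "citrate")
  # chemically equivalent but differently written -> no hit
  r3 <- match_smiles_query("C(C(=O)O)C(O)(CC(=O)O)C(=O)O", db)
  expect_equal(nrow(r3), 0L)
})

test_that("searching nested databases yields nested hit sets", {
  full <- fixture_db(seed = 4, n_compounds = 70)
  sub <- subset_mrdb(full, full$records$name[seq(1, 40)], db_name = "organism")
  p <- search_params(0.01, "Da", max_charge = 2, adducts = "Na",
                     max_adduct_count = 1)
  set.seed(13)
  masses <- c(192.027, 181.07, runif(5, 70, 600))
  for (m in masses) {
    hits_full <- match_mass_query(m, full, p)
    hits_sub <- match_mass_query(m, sub, p)
    expect_true(all(paste(hits_sub$compound_id, hits_sub$hypothesis) %in%
                      paste(hits_full$compound_id, hits_full$hypothesis)))
  }
})

test_that("hits grow monotonically with tolerance and hypothesis space", {
  db <- fixture_db(seed = 5, n_compounds = 60)
  key <- function(r) paste(r$compound_id, r$hypothesis)
  for (m in c(147.053, 192.027, 300.1)) {
    # tolerance monotonicity
    h1 <- match_mass_query(m, db, search_params(0.001, "Da", max_charge = 1))
    h2 <- match_mass_query(m, db, search_params(0.01, "Da", max_charge = 1))
    expect_true(all(key(h1) %in% key(h2)))
    # charge monotonicity
    h3 <- match_mass_query(m, db, search_params(0.01, "Da", max_charge = 3))
    expect_true(all(key(h2) %in% key(h3)))
    # adduct-count monotonicity
    p_a1 <- search_params(0.01, "Da", max_charge = 1, adducts = "Na",
                          max_adduct_count = 1)
    p_a2 <- search_params(0.01, "Da", max_charge = 1, adducts = "Na",
                          max_adduct_count = 2)
    h4 <- match_mass_query(m, db, p_a1)
    h5 <- match_mass_query(m, db, p_a2)
    expect_true(all(key(h4) %in% key(h5)))
  }
})

test_that("every emitted match passes its own tolerance recheck", {
  db <- fixture_db(seed = 6, n_compounds = 80)
  p <- search_params(20, "ppm", max_charge = 3, adducts = "Na", deducts = "H",
                     max_adduct_count = 2)
  set.seed(21)
  hit_any <- FALSE
  for (m in c(192.0271, runif(10, 70, 700))) {
    res <- match_mass_query(m, db, p)
    if (nrow(res) == 0L) next
    hit_any <- TRUE
    w <- within_tolerance(res$theoretical_mass, res$candidate_neutral_mass, p)
    expect_true(all(w$ok))
    expect_equal(res$deviation_ppm,
                 1e6 * res$deviation_da / res$theoretical_mass,
                 tolerance = 1e-9)
  }
  expect_true(hit_any)
})

test_that("the engine agrees exactly with the brute-force oracle", {
  db <- fixture_db(seed = 8, n_compounds = 60)
  tbl <- element_masses()
  set.seed(31)
  for (i in 1:200) {
    tol_unit <- sample(c("ppm", "Da"), 1)
    tol <- if (tol_unit == "ppm") runif(1, 1, 100) else runif(1, 1e-4, 0.05)
    mode <- sample(c("positive", "negative"), 1)
    zmax <- sample(0:3, 1)
    n_add <- sample(0:2, 1)
    adducts <- stats::setNames(tbl[c("Na", "K")][seq_len(n_add)],
                               c("Na", "K")[seq_len(n_add)])
    deducts <- if (sample(c(TRUE, FALSE), 1)) c(H2O = 18.0105646) else NULL
    maxc <- sample(0:2, 1)
    obs <- runif(1, 50, 650)

    p <- search_params(tol, tol_unit, mode = mode, max_charge = zmax,
                       adducts = if (n_add) adducts else NULL,
                       deducts = deducts, max_adduct_count = maxc)
    hyp <- enumerate_hypotheses(p)
    eng <- engine_keys(match_mass_query(obs, db, p, hyp), hyp)
    ora <- brute_force_keys(obs, db, tol, tol_unit, mode, zmax,
                            adducts = if (n_add) adducts else numeric(),
                            deducts = if (is.null(deducts)) numeric() else deducts,
                            max_count = maxc)
    expect_identical(eng, ora)
  }
})

test_that("multi-database search labels, orders and reconciles queries", {
  full <- fixture_db()
  sub <- subset_mrdb(full, c("citrate", "D-glucose"), db_name = "organism")
  p <- search_params(0.001, "Da", max_charge = 0)
  f <- withr::local_tempfile()
  writeLines(c("192.0270", "zzz-none", "glucose"), f)
  batch <- parse_query_text_file(f)
  res <- search_batch(batch, list(full, sub), p)

  expect_setequal(unique(res$db_name[!is.na(res$db_name)]),
                  c("fixture-medium", "organism"))
  # organism hits are a subset of the full-database hits
  in_sub <- res[!is.na(res$db_name) & res$db_name == "organism", ]
  in_full <- res[!is.na(res$db_name) & res$db_name == "fixture-medium", ]
  expect_true(all(in_sub$compound_id %in% in_full$compound_id))
  # unmatched query keeps an explicit row
  miss <- res[!res$matched, ]
  expect_equal(miss$query, "zzz-none")
  # query order preserved
  expect_true(!is.unsorted(res$source_line))
})

test_that("average-mass searches use the stored average MW, Da only", {
  db <- fixture_db()
  expect_error(search_params(5, "ppm", mass_kind = "average"),
               class = "ms_input_error")
  avg <- db$records$average_mw[db$records$name == "D-glucose"]
  p <- search_params(0.05, "Da", max_charge = 0, mass_kind = "average")
  res <- match_mass_query(avg, db, p)
  expect_true("D-glucose" %in% res$name)
})

test_that("a database without the requested mass kind raises a capability error", {
  db <- tiny_db(list(list(name = "nameless", formula = "")))
  p <- search_params(0.001, "Da", max_charge = 0)
  expect_error(match_mass_query(100, db, p), class = "ms_capability_error")
})

test_that("empty batches are rejected", {
  db <- fixture_db()
  p <- search_params(0.001, "Da")
  b <- single_query("glucose")
  b$queries <- b$queries[0, ]
  expect_error(search_batch(b, db, p), class = "ms_empty_error")
})
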