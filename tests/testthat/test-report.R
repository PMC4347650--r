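# Report artifacts: row accounting, payload pass-through, parameter echo,
# hyperlinks.

search_fixture_results <- function(queries = c("192.0270", "glucose",
                                               "zzz-none"),
                                   tol = 0.001) {
  db <- fixture_db()
  p <- search_params(tol, "Da", max_charge = 0)
  f <- withr::local_tempfile(.local_envir = parent.frame())
  writeLines(queries, f)
  batch <- parse_query_text_file(f)
  list(db = db, params = p, results = search_batch(batch, db, p))
}

body_rows <- function(lines) {
  lines <- lines[!startsWith(lines, "#")]
  lines[-1]  # drop column header
}

test_that("compounds table has one row per match and explicit no-match rows", {
  s <- search_fixture_results()
  lines <- render_compounds_table(s$results, s$params)
  rows <- body_rows(lines)
  expect_equal(length(rows), nrow(s$results))
  miss <- rows[grepl("zzz-none", rows)]
  expect_length(miss, 1L)
  expect_match(miss, "no match")
})

test_that("payload columns are carried through byte-identically", {
  db <- fixture_db()
  p <- search_params(0.001, "Da", max_charge = 0)
  f <- withr::local_tempfile()
  writeLines("192.0270\t5.32\t1032.7", f)
  res <- search_batch(parse_query_text_file(f), db, p)
  rows <- body_rows(render_compounds_table(res, p))
  for (r in rows) {
    fields <- strsplit(r, "\t", fixed = TRUE)[[1]]
    expect_identical(fields[12:13], c("5.32", "1032.7"))
  }
  header <- strsplit(grep("^query\t", render_compounds_table(res, p),
                          value = TRUE), "\t")[[1]]
  expect_identical(utils::tail(header, 2), c("payload_1", "payload_2"))
})

test_that("pathways table expands each row once per pathway membership", {
  s <- search_fixture_results()
  comp_rows <- body_rows(render_compounds_table(s$results, s$params))
  path_rows <- body_rows(render_pathways_table(s$results, s$params))
  expected <- sum(vapply(s$results$pathways, function(p) {
    max(1L, if (is.null(p)) 0L else nrow(p))
  }, integer(1L)))
  expect_equal(length(path_rows), expected)
  expect_gte(length(path_rows), length(comp_rows))

  # one hit with multiple pathways appears once per pathway
  citrate <- path_rows[grepl("\tcitrate\t", path_rows)]
  expect_equal(length(citrate),
               nrow(s$results$pathways[[which(s$results$name == "citrate")[1]]]))
})

test_that("row accounting holds across randomized fixtures", {
  set.seed(17)
  for (i in 1:5) {
    db <- fixture_db(seed = i + 100, n_compounds = 45)
    p <- search_params(0.02, "Da", max_charge = 1)
    masses <- formatC(runif(4, 70, 400), format = "f", digits = 4)
    f <- withr::local_tempfile()
    writeLines(masses, f)
    res <- search_batch(parse_query_text_file(f), db, p)
    comp <- body_rows(render_compounds_table(res, p))
    path <- body_rows(render_pathways_table(res, p))
    expect_equal(length(path), sum(vapply(res$pathways, function(q) {
      max(1L, if (is.null(q)) 0L else nrow(q))
    }, integer(1L))))
    expect_equal(length(comp), nrow(res))
  }
})

test_that("the parameter echo is identical across all three artifacts", {
  s <- search_fixture_results()
  prov <- list(input = "queries.txt (text)", databases = s$db$db_name)
  comp <- render_compounds_table(s$results, s$params, prov)
  path <- render_pathways_table(s$results, s$params, prov)
  html <- render_html(s$results, s$params, prov)
  echo <- serialize_params(s$params, prov)
  expect_identical(comp[seq_along(echo)], echo)
  expect_identical(path[seq_along(echo)], echo)
  for (line in echo) {
    expect_true(grepl(line, html, fixed = TRUE))
  }
  expect_match(html, "compounds.tsv", fixed = TRUE)
  expect_match(html, "pathways.tsv", fixed = TRUE)
})

test_that("the compounds table is loss-free for the match fields", {
  s <- search_fixture_results(queries = "192.0270")
  lines <- render_compounds_table(s$results, s$params)
  tab <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                           check.names = FALSE, colClasses = "character")
  expect_identical(tab$query, s$results$query)
  expect_identical(tab$compound_id, s$results$compound_id)
  expect_identical(tab$name, s$results$name)
  expect_identical(tab$hypothesis, s$results$hypothesis)
  expect_equal(as.numeric(tab$theoretical_mass), s$results$theoretical_mass,
               tolerance = 1e-4)
  expect_equal(as.numeric(tab$deviation_da), s$results$deviation_da,
               tolerance = 1e-4)
})

test_that("HTML links carry pathway ids via the database template", {
  s <- search_fixture_results(queries = "192.0270")
  templates <- stats::setNames(s$db$link_template, s$db$db_name)
  html <- render_html(s$results, s$params, link_templates = templates)
  pw <- unique(do.call(rbind, s$results$pathways))
  for (id in pw$id) {
    expect_match(html, paste0("object=", id), fixed = TRUE)
  }
  n_anchors <- lengths(regmatches(html, gregexpr("<a href", html, fixed = TRUE)))
  # one anchor per compound id plus one per pathway membership plus 2 TSV links
  expect_equal(n_anchors,
               2L + nrow(s$results) + sum(vapply(s$results$pathways, nrow,
                                                 integer(1L))))
})

test_that("missing link templates fall back to plain text with a warning", {
  s <- search_fixture_results(queries = "192.0270")
  expect_message(html <- render_html(s$results, s$params),
                 "no link template")
  expect_false(grepl("object=TCA", html, fixed = TRUE))
})

test_that("empty results still produce a valid page and parseable tables", {
  db <- fixture_db()
  p <- search_params(0.0001, "Da", max_charge = 0)
  res <- search_batch(single_query("999.9"), db, p)
  expect_false(any(res$matched))
  html <- render_html(res[0, ], p)
  expect_match(html, "no matches")
  lines <- render_compounds_table(res, p)
  expect_equal(length(body_rows(lines)), 1L)  # the no-match row
})

test_that("write_report writes three reconcilable artifacts", {
  s <- search_fixture_results()
  out <- withr::local_tempdir()
  paths <- write_report(s$results, s$params, out,
                        link_templates = stats::setNames(s$db$link_template,
                                                         s$db$db_name))
  expect_true(all(file.exists(paths)))
  comp <- readLines(paths[["compounds"]])
  path <- readLines(paths[["pathways"]])
  echo_len <- length(serialize_params(s$params))
  expect_identical(comp[seq_len(echo_len)], path[seq_len(echo_len)])
})
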