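# Report generation: the three output artifacts of a search run.
#
#   compounds.tsv — one row per match (no pathway information),
#   pathways.tsv  — each match repeated once per pathway membership,
#   report.html   — self-contained page with the parameter echo, links
#                   to the two TSV files, and pathway/compound hyperlinks.
#
# The full parameter set is echoed, identically serialized, at the top
# of all three artifacts so a reader can always verify which settings
# produced a result file.

#' Serialize search parameters for the output echo
#'
#' @param params A `search_params` object.
#' @param provenance Optional named list of extra lines to echo
#'   (input file, databases searched, ...).
#' @return Character vector of `"# key: value"` lines.
#' @export
serialize_params <- function(params, provenance = NULL) {
  stopifnot(inherits(params, "search_params"))
  sp <- function(df) {
    if (nrow(df) == 0L) "(none)"
    else paste(sprintf("%s (%.6f Da)", df$label, df$mass), collapse = ", ")
  }
  lines <- c(
    "# metabosearch search parameters",
    sprintf("# tolerance: %s %s", format(params$tolerance_value),
            params$tolerance_unit),
    sprintf("# electrospray mode: %s", params$mode),
    sprintf("# max proton charges: %d", params$max_charge),
    sprintf("# include neutral (z=0): %s",
            if (params$include_neutral) "yes" else "no"),
    sprintf("# adducts: %s", sp(params$adducts)),
    sprintf("# deducts: %s", sp(params$deducts)),
    sprintf("# max adduct/deduct count: %d", params$max_adduct_count),
    sprintf("# mass kind: %s", params$mass_kind)
  )
  for (key in names(provenance)) {
    lines <- c(lines, sprintf("# %s: %s", key, provenance[[key]]))
  }
  lines
}

fmt_fixed <- function(x, digits) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

COMPOUND_HEADER <- c("query", "qtype", "db_name", "compound_id", "name",
                     "formula", "theoretical_mass", "hypothesis",
                     "deviation_da", "deviation_ppm", "cas_id")

compound_cells <- function(results, precision_da, precision_ppm) {
  n <- nrow(results)
  chr <- function(x) ifelse(is.na(x), "", as.character(x))
  cells <- cbind(
    chr(results$query), chr(results$qtype), chr(results$db_name),
    chr(results$compound_id),
    ifelse(results$matched, chr(results$name), "no match"),
    chr(results$formula),
    fmt_fixed(results$theoretical_mass, 4L),
    chr(results$hypothesis),
    fmt_fixed(results$deviation_da, precision_da),
    fmt_fixed(results$deviation_ppm, precision_ppm),
    chr(results$cas_id)
  )
  if (n == 0L) cells <- matrix(character(), nrow = 0L, ncol = 11L)
  cells
}

payload_matrix <- function(results) {
  width <- if (nrow(results) == 0L) 0L else max(lengths(results$payload), 0L)
  if (width == 0L) {
    return(matrix(character(), nrow = nrow(results), ncol = 0L))
  }
  mat <- vapply(results$payload, function(p) {
    c(p, rep("", width - length(p)))
  }, character(width))
  mat <- if (width == 1L) matrix(mat, ncol = 1L) else t(mat)
  colnames(mat) <- paste0("payload_", seq_len(width))
  mat
}

#' Render the compounds table
#'
#' One row per match, without pathway information; queries with zero
#' hits appear as a single explicit `no match` row so the output always
#' accounts for every input query.  Extra input columns (intensities,
#' statistics) are appended verbatim as `payload_*` columns.  Deviations
#' are printed to 4 (Da) and 2 (ppm) decimals by default.
#'
#' @param results Result tibble from [search_batch()].
#' @param params A `search_params` object (for the echo block).
#' @param provenance Optional named list echoed with the parameters.
#' @param precision_da,precision_ppm Decimal places for the deviations.
#' @return Character vector of output lines (echo, header, rows).
#' @export
render_compounds_table <- function(results, params, provenance = NULL,
                                   precision_da = 4L, precision_ppm = 2L) {
  cells <- compound_cells(results, precision_da, precision_ppm)
  pay <- payload_matrix(results)
  header <- c(COMPOUND_HEADER, colnames(pay))
  full <- cbind(cells, pay)
  rows <- if (nrow(full) == 0L) character() else {
    apply(full, 1L, paste, collapse = "\t")
  }
  c(serialize_params(params, provenance),
    paste(header, collapse = "\t"),
    rows)
}

#' Render the pathway-expanded table
#'
#' Repeats each compound row once per metabolic pathway it belongs to
#' (with `pathway_id` and `pathway_name` columns), which makes the file
#' sortable by pathway; compounds in no curated pathway emit one row
#' with blank pathway fields.  Row count is therefore
#' `sum(max(1, pathways per row))` over the compounds table.
#'
#' @inheritParams render_compounds_table
#' @return Character vector of output lines.
#' @export
render_pathways_table <- function(results, params, provenance = NULL,
                                  precision_da = 4L, precision_ppm = 2L) {
  cells <- compound_cells(results, precision_da, precision_ppm)
  pay <- payload_matrix(results)
  rows <- character()
  for (i in seq_len(nrow(results))) {
    pw <- results$pathways[[i]]
    base_cells <- c(cells[i, ], if (ncol(pay) > 0L) pay[i, ])
    if (is.null(pw) || nrow(pw) == 0L) {
      rows <- c(rows, paste(c(base_cells[seq_len(11L)], "", "",
                              base_cells[-seq_len(11L)]), collapse = "\t"))
    } else {
      for (j in seq_len(nrow(pw))) {
        rows <- c(rows, paste(c(base_cells[seq_len(11L)], pw$id[j], pw$name[j],
                                base_cells[-seq_len(11L)]), collapse = "\t"))
      }
    }
  }
  header <- c(COMPOUND_HEADER, "pathway_id", "pathway_name", colnames(pay))
  c(serialize_params(params, provenance),
    paste(header, collapse = "\t"),
    rows)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

link_or_text <- function(id, text, template) {
  if (is.null(template) || is.na(template) || !nzchar(template) ||
      is.na(id) || !nzchar(id)) {
    return(html_escape(text))
  }
  href <- gsub("{id}", utils::URLencode(id, reserved = TRUE), template,
               fixed = TRUE)
  sprintf('<a href="%s">%s</a>', html_escape(href), html_escape(text))
}

#' Render the HTML report
#'
#' A self-contained page: the parameter echo at the top, links to the
#' two downloadable TSV files, and the result table in which every
#' pathway (and compound) is hyperlinked via its database's URL
#' template (`{id}` placeholder).  Databases without a template render
#' plain text and a warning is logged.
#'
#' @inheritParams render_compounds_table
#' @param link_templates Named character vector, `db_name` -> URL
#'   template with an `{id}` placeholder.
#' @param tsv_names Names of the two TSV files the page links to.
#' @return Single character string holding the HTML document.
#' @export
render_html <- function(results, params, provenance = NULL,
                        link_templates = character(),
                        tsv_names = c("compounds.tsv", "pathways.tsv"),
                        precision_da = 4L, precision_ppm = 2L) {
  echo <- serialize_params(params, provenance)
  cells <- compound_cells(results, precision_da, precision_ppm)

  header_cells <- paste0("<th>", html_escape(c(COMPOUND_HEADER, "pathways")),
                         "</th>", collapse = "")
  body_rows <- character()
  warned <- character()
  for (i in seq_len(nrow(results))) {
    db <- results$db_name[i]
    template <- if (!is.na(db) && db %in% names(link_templates)) {
      link_templates[[db]]
    } else ""
    if (!nzchar(template) && !is.na(db) && !(db %in% warned)) {
      message(sprintf("no link template for database '%s'; rendering plain text", db))
      warned <- c(warned, db)
    }
    row_cells <- vapply(cells[i, ], html_escape, character(1L),
                        USE.NAMES = FALSE)
    # hyperlink the compound id
    row_cells[4L] <- link_or_text(results$compound_id[i], results$compound_id[i],
                                  template)
    pw <- results$pathways[[i]]
    pw_html <- if (is.null(pw) || nrow(pw) == 0L) "" else {
      paste(vapply(seq_len(nrow(pw)), function(j) {
        link_or_text(pw$id[j], pw$name[j], template)
      }, character(1L)), collapse = "; ")
    }
    body_rows <- c(body_rows, paste0(
      "<tr>", paste0("<td>", c(row_cells, pw_html), "</td>", collapse = ""),
      "</tr>"
    ))
  }
  table_html <- if (length(body_rows) == 0L) {
    "<p><em>no matches</em></p>"
  } else {
    paste0("<table border=\"1\">\n<tr>", header_cells, "</tr>\n",
           paste(body_rows, collapse = "\n"), "\n</table>")
  }
  paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>metabosearch report</title>\n</head>\n<body>\n",
    "<h1>metabosearch report</h1>\n",
    "<pre>\n", paste(html_escape(echo), collapse = "\n"), "\n</pre>\n",
    "<p>Downloads: <a href=\"", tsv_names[1L], "\">compounds file</a> | ",
    "<a href=\"", tsv_names[2L], "\">pathways file</a></p>\n",
    table_html,
    "\n</body>\n</html>\n"
  )
}

#' Write the three report artifacts
#'
#' @param results Result tibble from [search_batch()].
#' @param params A `search_params` object.
#' @param out_dir Output directory (created if missing).
#' @param provenance Optional named list echoed with the parameters.
#' @param link_templates Named character vector of URL templates per
#'   database (defaults to none).
#' @param precision_da,precision_ppm Decimal places for deviations.
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_report <- function(results, params, out_dir = ".", provenance = NULL,
                         link_templates = character(),
                         precision_da = 4L, precision_ppm = 2L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    compounds = file.path(out_dir, "compounds.tsv"),
    pathways = file.path(out_dir, "pathways.tsv"),
    html = file.path(out_dir, "report.html")
  )
  write_lines_lf <- function(lines, path) {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  write_lines_lf(render_compounds_table(results, params, provenance,
                                        precision_da, precision_ppm),
                 paths[["compounds"]])
  write_lines_lf(render_pathways_table(results, params, provenance,
                                       precision_da, precision_ppm),
                 paths[["pathways"]])
  write_lines_lf(render_html(results, params, provenance, link_templates,
                             basename(paths[1:2]),
                             precision_da, precision_ppm),
                 paths[["html"]])
  invisible(paths)
}
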