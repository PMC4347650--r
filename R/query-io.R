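# Query input: single typed queries, generic tab-delimited query lists
# (queries in column 1, any extra columns carried through untouched) and
# MarkerLynx-style peak tables with "RT_m/z" row labels.

QUERY_TYPES <- c("name", "formula", "smiles", "mass")

# characters legal in a SMILES string (organic subset + ring/branch/charge
# punctuation); used only as a classification heuristic, not validation
.SMILES_CHARSET <- "^[A-Za-z0-9@+\\-\\[\\]()=#$%/\\\\.:*]+$"
.SMILES_SPECIAL <- "[=#()\\[\\]@]|(?<![A-Za-z])[cnospb](?![A-Za-z])"

#' Classify a query string
#'
#' Decides whether a raw query is a mass, a molecular formula, a SMILES
#' string or a compound name, so each can be matched against the
#' corresponding database field.  The priority is deterministic:
#'
#' 1. parses as a positive decimal number -> `mass`;
#' 2. matches the formula grammar with all-known elements, and either
#'    contains a digit or names more than one element -> `formula`;
#' 3. contains only SMILES-alphabet characters and at least one
#'    structural character (`= # ( ) [ ] @`) or a lone lowercase
#'    aromatic atom -> `smiles`;
#' 4. otherwise -> `name`.
#'
#' Decimal masses must use `.` as the separator; comma decimals are not
#' treated as masses (locale ambiguity) and fall through to `name`.
#'
#' @param text Non-empty query string.
#' @param table Element mass table for formula validation.
#' @return One of `"mass"`, `"formula"`, `"smiles"`, `"name"`.
#' @examples
#' classify_query("192.0270")   # mass
#' classify_query("C6H8O7")     # formula
#' classify_query("glucose")    # name
#' @export
classify_query <- function(text, table = element_masses()) {
  if (length(text) != 1L || is.na(text)) ms_input_error("query must be a single string")
  text <- trimws(text)
  if (!nzchar(text)) ms_input_error("query string is empty")
  if (grepl("^[0-9]+\\.?[0-9]*$", text) &&
      suppressWarnings(!is.na(as.numeric(text))) &&
      as.numeric(text) > 0) {
    return("mass")
  }
  if (is_formula(text, table)) {
    counts <- parse_formula(text, table)
    if (grepl("[0-9]", text) || length(counts) > 1L) return("formula")
  }
  if (grepl(.SMILES_CHARSET, text, perl = TRUE) &&
      grepl(.SMILES_SPECIAL, text, perl = TRUE)) {
    return("smiles")
  }
  "name"
}

new_query_batch <- function(queries, origin, skipped) {
  structure(list(queries = queries, origin = origin, skipped = skipped),
            class = "query_batch")
}

#' @export
print.query_batch <- function(x, ...) {
  cat(sprintf("<query batch> %d queries from %s (%d line(s) skipped)\n",
              nrow(x$queries), x$origin, nrow(x$skipped)))
  invisible(x)
}

empty_skipped <- function() {
  tibble::tibble(line = integer(), reason = character())
}

#' Build a batch from a single typed query
#'
#' @param text The query string.
#' @param force_type Override automatic classification (`"auto"` keeps it).
#' @param table Element mass table.
#' @return A `query_batch` with one query.
#' @export
single_query <- function(text, force_type = "auto", table = element_masses()) {
  force_type <- match.arg(force_type, c("auto", QUERY_TYPES))
  q <- make_query(text, 1L, character(), force_type, table)
  if (is.null(q)) ms_input_error("query string is empty")
  new_query_batch(q, "single", empty_skipped())
}

make_query <- function(text, line, payload, force_type, table) {
  text <- trimws(text)
  if (!nzchar(text)) return(NULL)
  qtype <- if (force_type != "auto") force_type else classify_query(text, table)
  mass <- if (qtype == "mass") {
    v <- suppressWarnings(as.numeric(text))
    if (is.na(v) || v <= 0) {
      ms_input_error(sprintf("line %d: '%s' forced to mass but not a positive number",
                             line, text))
    }
    v
  } else NA_real_
  tibble::tibble(raw = text, qtype = qtype, mass_value = mass,
                 payload = list(payload), source_line = line)
}

#' Parse a generic query text file
#'
#' Reads a tab-delimited text file with query values of any type (masses,
#' names, formulae, SMILES, mixed) in the first column.  Extra columns —
#' intensities, statistics, anything the acquisition software wrote — are
#' never inspected, only carried through to the outputs.  Empty lines and
#' lines with an empty first field are skipped and logged with reasons
#' rather than silently dropped; `strict = TRUE` turns any skip into an
#' error.
#'
#' @param file Path to the query file.
#' @param force_type Force every query to one type instead of classifying
#'   (`"auto"`, `"name"`, `"formula"`, `"smiles"`, `"mass"`).
#' @param strict Error on any skipped line.
#' @param table Element mass table.
#' @return A `query_batch` (origin `"text_file"`).
#' @export
parse_query_text_file <- function(file, force_type = "auto", strict = FALSE,
                                  table = element_masses()) {
  force_type <- match.arg(force_type, c("auto", QUERY_TYPES))
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  queries <- list()
  skipped <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(fields) == 0L || !nzchar(trimws(lines[i]))) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(line = i, reason = "empty line")
      next
    }
    if (!nzchar(trimws(fields[1L]))) {
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(line = i, reason = "empty first field")
      next
    }
    q <- make_query(fields[1L], i, fields[-1L], force_type, table)
    queries[[length(queries) + 1L]] <- q
  }
  finish_batch(queries, skipped, "text_file", strict)
}

finish_batch <- function(queries, skipped, origin, strict) {
  skipped <- if (length(skipped)) do.call(rbind, skipped) else empty_skipped()
  if (strict && nrow(skipped) > 0L) {
    ms_input_error(sprintf(
      "strict mode: %d line(s) would be skipped (first: line %d, %s)",
      nrow(skipped), skipped$line[1L], skipped$reason[1L]
    ))
  }
  if (length(queries) == 0L) {
    ms_empty_error("no usable queries in input")
  }
  for (s in seq_len(nrow(skipped))) {
    message(sprintf("skipped line %d: %s", skipped$line[s], skipped$reason[s]))
  }
  new_query_batch(do.call(rbind, queries), origin, skipped)
}

#' Parse a MarkerLynx-style peak table
#'
#' Reads the tab-delimited marker table exported by MS marker-analysis
#' software without modification.  The first column is either a marker
#' label of the form `RT_mz` (retention time and m/z joined by an
#' underscore, e.g. `"5.32_192.0270"`) or a bare mass; every query is a
#' mass query.  The retention-time token and all remaining columns
#' (per-sample intensities) are carried through in the payload.  A header
#' row is auto-detected when the first cell is non-numeric and contains
#' no underscore.
#'
#' @inheritParams parse_query_text_file
#' @return A `query_batch` (origin `"markerlynx"`).
#' @export
parse_markerlynx_file <- function(file, strict = FALSE,
                                  table = element_masses()) {
  lines <- readLines(file, encoding = "UTF-8", warn = FALSE)
  queries <- list()
  skipped <- list()
  is_num <- function(x) grepl("^[0-9]+\\.?[0-9]*$", x)
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(line = i, reason = "empty line")
      next
    }
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    first <- trimws(fields[1L])
    if (i == 1L && !is_num(first) && !grepl("_", first, fixed = TRUE)) {
      skipped[[length(skipped) + 1L]] <- tibble::tibble(line = i, reason = "header row")
      next
    }
    if (grepl("_", first, fixed = TRUE)) {
      parts <- strsplit(first, "_", fixed = TRUE)[[1L]]
      if (length(parts) == 2L && is_num(parts[1L]) && is_num(parts[2L])) {
        q <- tibble::tibble(
          raw = first, qtype = "mass",
          mass_value = as.numeric(parts[2L]),
          payload = list(c(parts[1L], fields[-1L])),
          source_line = i
        )
        queries[[length(queries) + 1L]] <- q
        next
      }
      skipped[[length(skipped) + 1L]] <-
        tibble::tibble(line = i, reason = "unparseable marker label")
      next
    }
    if (is_num(first)) {
      q <- tibble::tibble(
        raw = first, qtype = "mass", mass_value = as.numeric(first),
        payload = list(fields[-1L]), source_line = i
      )
      queries[[length(queries) + 1L]] <- q
      next
    }
    skipped[[length(skipped) + 1L]] <-
      tibble::tibble(line = i, reason = "no parsable mass")
  }
  finish_batch(queries, skipped, "markerlynx", strict)
}
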