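# Metabolic Reference Databases (MRDBs).
#
# An MRDB is the genome-restricted search space for all queries: a named
# catalog of the compounds an organism's reconstructed metabolism can
# produce, with names, formulae, masses, SMILES strings, CAS numbers and
# pathway memberships.  MRDBs live in a plain tab-delimited flat-file
# dialect so they can be built once and searched many times.
#
# Flat-file dialect (normative for this package):
#   - UTF-8, LF, tab-delimited, one header line;
#   - leading "# mrdb <key>: <value>" comment lines carry db_name,
#     link_template, created and source_tag;
#   - columns: compound_id, name, formula, average_mw, monoisotopic_mass,
#     smiles, cas_id, pathways;
#   - pathways serialized as pipe-separated "id:name" pairs;
#   - blank field = absent; masses printed to 6 decimals.

MRDB_COLUMNS <- c("compound_id", "name", "formula", "average_mw",
                  "monoisotopic_mass", "smiles", "cas_id", "pathways")

new_mrdb <- function(db_name, records, link_template = "",
                     created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                     source_tag = "") {
  stopifnot(is.character(db_name), nzchar(db_name))
  if (anyDuplicated(records$compound_id)) {
    dup <- records$compound_id[duplicated(records$compound_id)][1L]
    ms_schema_error(sprintf("duplicate compound_id in MRDB: '%s'", dup))
  }
  structure(
    list(db_name = db_name, records = records,
         link_template = link_template, created = created,
         source_tag = source_tag),
    class = "mrdb"
  )
}

#' @export
print.mrdb <- function(x, ...) {
  n_mass <- sum(!is.na(x$records$monoisotopic_mass))
  cat(sprintf("<MRDB> %s: %d compounds (%d with monoisotopic mass)\n",
              x$db_name, nrow(x$records), n_mass))
  invisible(x)
}

#' Number of compounds in an MRDB
#' @param x An `mrdb` object.
#' @export
length.mrdb <- function(x) nrow(x$records)

empty_records <- function() {
  tibble::tibble(
    compound_id = character(), name = character(), formula = character(),
    average_mw = numeric(), monoisotopic_mass = numeric(),
    smiles = character(), cas_id = character(), pathways = list()
  )
}

# "id:name|id:name" <-> data.frame(id, name).  Split on the FIRST colon
# only, so pathway names may themselves contain colons.
parse_pathways <- function(text) {
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(id = character(), name = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(text, "|", fixed = TRUE)[[1L]]
  id <- sub(":.*$", "", parts)
  nm <- sub("^[^:]*:?", "", parts)
  data.frame(id = id, name = nm, stringsAsFactors = FALSE)
}

format_pathways <- function(df) {
  if (is.null(df) || nrow(df) == 0L) return("")
  paste(paste0(df$id, ":", df$name), collapse = "|")
}

#' Build an MRDB from a compound/pathway export
#'
#' Turns a generic tab-delimited compound export (one compound per row,
#' with its pathway memberships) into a searchable MRDB.  For every row
#' with a parseable molecular formula, the neutral monoisotopic mass is
#' computed from the bundled element table and stored alongside the
#' carried-through average molecular weight.  Rows whose formula does not
#' parse are retained without a computed mass and reported in the build
#' log (attribute `build_log`), so record count always equals input row
#' count.
#'
#' Required input columns: `name`, `formula`, `average_mw`, `smiles`,
#' `pathways` (pipe-delimited `id:name` pairs).  Optional: `cas_id`,
#' `compound_id` (generated from the name when absent).
#'
#' @param compound_table Path to a tab-delimited export, or a data frame
#'   with the columns above.
#' @param db_name Organism / encyclopedia label for the database.
#' @param link_template URL pattern with a `{id}` placeholder used to
#'   hyperlink compounds and pathways in HTML reports.
#' @param table Element mass table.
#' @param source_tag Free-text provenance string.
#' @return An `mrdb` object.
#' @export
build_mrdb <- function(compound_table, db_name, link_template = "",
                       table = element_masses(), source_tag = "") {
  if (is.character(compound_table)) {
    src <- compound_table
    compound_table <- utils::read.delim(
      compound_table, colClasses = "character", check.names = FALSE,
      na.strings = NULL, quote = "", comment.char = ""
    )
    if (!nzchar(source_tag)) source_tag <- basename(src)
  }
  required <- c("name", "formula", "average_mw", "smiles", "pathways")
  missing <- setdiff(required, names(compound_table))
  if (length(missing) > 0L) {
    ms_schema_error(sprintf("compound table is missing column(s): %s",
                            paste(missing, collapse = ", ")))
  }
  if (nrow(compound_table) == 0L) {
    ms_empty_error("compound table has no rows")
  }

  n <- nrow(compound_table)
  name <- as.character(compound_table$name)
  if (any(!nzchar(trimws(name)))) {
    ms_schema_error("compound table contains rows with an empty name")
  }
  formula <- trimws(as.character(compound_table$formula))
  cas <- if ("cas_id" %in% names(compound_table)) {
    as.character(compound_table$cas_id)
  } else rep("", n)
  ids <- if ("compound_id" %in% names(compound_table)) {
    as.character(compound_table$compound_id)
  } else make.unique(toupper(gsub("[^A-Za-z0-9]+", "-", name)), sep = "-")

  mono <- rep(NA_real_, n)
  log <- character()
  for (i in seq_len(n)) {
    if (!nzchar(formula[i])) next
    res <- tryCatch(monoisotopic_mass(formula[i], table), condition = identity)
    if (inherits(res, "condition")) {
      log <- c(log, sprintf("row %d (%s): formula '%s' not parseable: %s",
                            i, name[i], formula[i], conditionMessage(res)))
    } else {
      mono[i] <- res
    }
  }
  if (length(log) > 0L) {
    message(sprintf("build_mrdb: %d formula(e) could not be parsed; see build_log",
                    length(log)))
  }

  records <- tibble::tibble(
    compound_id = ids,
    name = name,
    formula = formula,
    average_mw = suppressWarnings(as.numeric(compound_table$average_mw)),
    monoisotopic_mass = mono,
    smiles = as.character(compound_table$smiles),
    cas_id = cas,
    pathways = lapply(as.character(compound_table$pathways), parse_pathways)
  )
  db <- new_mrdb(db_name, records, link_template, source_tag = source_tag)
  attr(db, "build_log") <- log
  db
}

fmt_mass <- function(x, digits = 6L) {
  ifelse(is.na(x), "", formatC(x, format = "f", digits = digits))
}

#' Write an MRDB to its flat-file form
#'
#' @param mrdb An `mrdb` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_mrdb()] — the round trip reproduces the database
#'   field-for-field (masses to the printed 6-decimal precision).
#' @export
write_mrdb <- function(mrdb, path) {
  stopifnot(inherits(mrdb, "mrdb"))
  r <- mrdb$records
  header <- c(
    sprintf("# mrdb db_name: %s", mrdb$db_name),
    sprintf("# mrdb link_template: %s", mrdb$link_template),
    sprintf("# mrdb created: %s", mrdb$created),
    sprintf("# mrdb source_tag: %s", mrdb$source_tag),
    paste(MRDB_COLUMNS, collapse = "\t")
  )
  rows <- paste(
    r$compound_id, r$name, r$formula,
    fmt_mass(r$average_mw), fmt_mass(r$monoisotopic_mass),
    r$smiles, r$cas_id,
    vapply(r$pathways, format_pathways, character(1L)),
    sep = "\t"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read an MRDB flat file
#'
#' @param path Path to a file written by [write_mrdb()] (or conforming
#'   to the same dialect).
#' @return An `mrdb` object.
#' @export
read_mrdb <- function(path) {
  if (!file.exists(path)) {
    ms_input_error(sprintf("MRDB file not found: '%s'", path))
  }
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta <- list(db_name = basename(path), link_template = "",
               created = "", source_tag = "")
  i <- 1L
  while (i <= length(lines) && startsWith(lines[i], "# mrdb ")) {
    kv <- sub("^# mrdb ", "", lines[i])
    key <- sub(":.*$", "", kv)
    val <- sub("^[^:]*: ?", "", kv)
    if (key %in% names(meta)) meta[[key]] <- val
    i <- i + 1L
  }
  if (i > length(lines)) {
    ms_dialect_error("MRDB file has no header line")
  }
  header <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, MRDB_COLUMNS)) {
    ms_dialect_error(sprintf(
      "unexpected MRDB header at line %d (want: %s)",
      i, paste(MRDB_COLUMNS, collapse = ", ")
    ))
  }
  body <- lines[-seq_len(i)]
  body_lineno <- seq_along(body) + i
  keep <- nzchar(body)
  body <- body[keep]
  body_lineno <- body_lineno[keep]
  if (length(body) == 0L) {
    return(new_mrdb(meta$db_name, empty_records(), meta$link_template,
                    meta$created, meta$source_tag))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; pad, but flag genuinely short rows
  nf <- lengths(fields)
  ncol <- length(MRDB_COLUMNS)
  raw_tabs <- lengths(gregexpr("\t", body, fixed = TRUE))
  bad <- which(raw_tabs != ncol - 1L)
  if (length(bad) > 0L) {
    ms_dialect_error(sprintf(
      "MRDB line %d has %d columns, expected %d",
      body_lineno[bad[1L]], raw_tabs[bad[1L]] + 1L, ncol
    ))
  }
  fields <- lapply(fields, function(f) c(f, rep("", ncol - length(f))))
  mat <- do.call(rbind, fields)
  num <- function(x) suppressWarnings(as.numeric(ifelse(nzchar(x), x, NA)))
  records <- tibble::tibble(
    compound_id = mat[, 1L],
    name = mat[, 2L],
    formula = mat[, 3L],
    average_mw = num(mat[, 4L]),
    monoisotopic_mass = num(mat[, 5L]),
    smiles = mat[, 6L],
    cas_id = mat[, 7L],
    pathways = lapply(mat[, 8L], parse_pathways)
  )
  new_mrdb(meta$db_name, records, meta$link_template,
           meta$created, meta$source_tag)
}

#' Restrict an MRDB to a subset of compounds
#'
#' Genome restriction as set restriction: an organism-specific database
#' is a subset of a larger encyclopedia, and hits against it are always a
#' subset of the superset's hits.
#'
#' @param mrdb An `mrdb` object.
#' @param names Character vector of compound names or compound ids to keep.
#' @param db_name Label for the restricted database.
#' @return An `mrdb` containing only the matching records.
#' @export
subset_mrdb <- function(mrdb, names, db_name = paste0(mrdb$db_name, "-subset")) {
  stopifnot(inherits(mrdb, "mrdb"))
  keep <- mrdb$records$name %in% names | mrdb$records$compound_id %in% names
  new_mrdb(db_name, mrdb$records[keep, ], mrdb$link_template,
           mrdb$created, mrdb$source_tag)
}

#' Metabolite distribution by molecular mass
#'
#' Bins the usable monoisotopic masses of an MRDB into left-closed,
#' right-open mass ranges, the summary conventionally printed for
#' metabolic encyclopedias (most metabolomics targets fall below
#' 1,000 Da).  The default bins are 50-99, 100-199, ..., 900-999 and
#' >1000; a mass exactly on an integer edge falls in the bin that starts
#' there.
#'
#' @param mrdb An `mrdb` object.
#' @param bin_edges Strictly increasing numeric vector of lower bin edges;
#'   the last bin is open-ended.
#' @return Named integer vector of counts, with attributes
#'   `below_first` (records with a mass below the first edge) and
#'   `no_mass` (records without a usable mass).  Counts plus
#'   `below_first` sum to the number of mass-bearing records.
#' @export
mass_distribution <- function(mrdb, bin_edges = c(50, seq(100, 1000, by = 100))) {
  stopifnot(inherits(mrdb, "mrdb"))
  if (any(diff(bin_edges) <= 0)) {
    ms_input_error("bin edges must be strictly increasing")
  }
  masses <- mrdb$records$monoisotopic_mass
  no_mass <- sum(is.na(masses))
  masses <- masses[!is.na(masses)]
  k <- length(bin_edges)
  idx <- findInterval(masses, bin_edges)  # 0 = below first edge
  counts <- tabulate(idx, nbins = k)
  labels <- c(
    paste0(bin_edges[-k], "-", bin_edges[-1L] - 1L),
    paste0(">", bin_edges[k])
  )
  # label convention: the final closed bins read "100-199" etc.; the
  # last edge opens the ">=" bin, labelled with ">" as customarily printed
  structure(stats::setNames(as.integer(counts), labels),
            below_first = sum(idx == 0L), no_mass = no_mass)
}
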