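# Molecular-formula parsing and monoisotopic / charged mass arithmetic.
# This is the numeric core: the database builder, the query classifier
# and the matching engine all reduce to these four functions.

#' Parse a molecular formula string
#'
#' Parses a flat element-count formula such as `"C6H12O6"` into a named
#' integer vector of element counts.  The grammar is a sequence of
#' (element symbol, optional count >= 1) tokens: standard capitalization
#' (one upper-case letter optionally followed by one lower-case letter),
#' no parentheses, hydrates or isotope labels — the flat style used by
#' pathway-database compound exports.  Repeated element tokens are summed,
#' so `"CHHO"` and `"CH2O"` denote the same formula.
#'
#' @param text Formula string; surrounding whitespace is ignored.
#' @param table Element mass table (validates that every symbol is known).
#' @return Named integer vector of element counts with class
#'   `"molecular_formula"`.  Element order follows first appearance.
#' @examples
#' parse_formula("C6H8O7")
#' parse_formula("CHHO")  # same as CH2O
#' @export
parse_formula <- function(text, table = element_masses()) {
  if (length(text) != 1L || is.na(text)) {
    ms_parse_error("formula must be a single string")
  }
  text <- trimws(text)
  if (!nzchar(text)) {
    ms_parse_error("formula string is empty")
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1L]]
  tokens <- regmatches(text, list(m))[[1L]]
  if (length(tokens) == 0L || paste(tokens, collapse = "") != text) {
    ms_parse_error(sprintf("malformed formula: '%s'", text))
  }
  symbols <- sub("[0-9]*$", "", tokens)
  digits <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(nzchar(digits), suppressWarnings(as.integer(digits)), 1L)
  if (anyNA(counts)) {
    ms_parse_error(sprintf("malformed count in formula: '%s'", text))
  }
  if (any(counts < 1L)) {
    bad <- tokens[counts < 1L][1L]
    ms_parse_error(sprintf("zero count not allowed in formula: '%s'", bad))
  }
  unknown <- setdiff(symbols, names(table))
  if (length(unknown) > 0L) {
    ms_element_error(sprintf(
      "unknown element symbol(s) in formula '%s': %s",
      text, paste(unique(unknown), collapse = ", ")
    ))
  }
  out <- vapply(split(counts, factor(symbols, levels = unique(symbols))), sum, 0L)
  structure(out, class = "molecular_formula")
}

#' Test whether a string is a valid molecular formula
#'
#' @param text Candidate string.
#' @param table Element mass table.
#' @return `TRUE` if [parse_formula()] would succeed.
#' @export
is_formula <- function(text, table = element_masses()) {
  !inherits(tryCatch(parse_formula(text, table), condition = identity),
            "condition")
}

#' Format a parsed formula back to a string
#'
#' @param formula Named integer vector (as from [parse_formula()]).
#' @return Formula string in Hill-like order of first appearance.
#' @export
format_formula <- function(formula) {
  if (length(formula) == 0L) return("")
  paste0(names(formula), ifelse(formula > 1L, formula, ""), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Neutral monoisotopic mass of a formula
#'
#' Sums element monoisotopic masses weighted by element counts.  The
#' empty formula has mass 0.
#'
#' @param formula A formula string or a named count vector as returned by
#'   [parse_formula()].
#' @param table Element mass table.
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass("C6H8O7")  # isocitrate / citrate, 192.027 Da
#' monoisotopic_mass("H2O")
#' @export
monoisotopic_mass <- function(formula, table = element_masses()) {
  if (is.character(formula)) formula <- parse_formula(formula, table)
  if (length(formula) == 0L) return(0)
  missing <- setdiff(names(formula), names(table))
  if (length(missing) > 0L) {
    ms_element_error(sprintf(
      "element(s) missing from mass table: %s",
      paste(missing, collapse = ", ")
    ))
  }
  sum(unname(table[names(formula)]) * as.numeric(formula))
}

#' Observed m/z for an ion hypothesis
#'
#' Computes the mass-to-charge ratio of an ion formed from a neutral
#' molecule of mass `neutral_mass` by attaching (positive mode) or
#' removing (negative mode) `charge` hydrogen atoms, plus any adduct
#' species gained and deduct species (fragments) lost during electrospray
#' ionization:
#'
#'   m/z = (M + s * z * m_H + sum(adducts) - sum(deducts)) / max(z, 1)
#'
#' where `s` is +1 in positive mode and -1 in negative mode and `m_H` is
#' the hydrogen-atom monoisotopic mass.  The electron mass is neglected
#' (hydrogen-atom convention): this reproduces the conventional printed
#' reference m/z values for lock-mass compounds such as
#' leucine-enkephalin (556.2771 in positive mode).
#'
#' Charge 0 is a valid state meaning "the neutral mass as given"; no
#' ionization event exists at z = 0, so adducts and deducts are
#' disallowed there.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Integer 0-5, the number of proton charges.
#' @param mode `"positive"` or `"negative"`.
#' @param adduct_masses,deduct_masses Numeric vectors of species masses
#'   (Da) gained / lost; empty by default.
#' @param table Element mass table (supplies the hydrogen mass).
#' @return m/z in Da.
#' @examples
#' M <- monoisotopic_mass("C28H37N5O7")  # leucine-enkephalin
#' ion_mz(M, 1, "positive")              # 556.2771
#' @export
ion_mz <- function(neutral_mass, charge, mode = c("positive", "negative"),
                   adduct_masses = numeric(), deduct_masses = numeric(),
                   table = element_masses()) {
  mode <- match.arg(mode)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 0L || charge > 5L) {
    ms_hypothesis_error("charge must be an integer between 0 and 5")
  }
  if (charge == 0L) {
    if (length(adduct_masses) > 0L || length(deduct_masses) > 0L) {
      ms_hypothesis_error("adducts/deducts are not allowed at charge 0")
    }
    return(neutral_mass)
  }
  s <- if (mode == "positive") 1 else -1
  mz <- (neutral_mass + s * charge * hydrogen_mass(table) +
           sum(adduct_masses) - sum(deduct_masses)) / charge
  if (mz <= 0) {
    ms_hypothesis_error("ion hypothesis yields a non-positive m/z")
  }
  mz
}

#' Candidate neutral mass from an observed m/z
#'
#' Exact algebraic inverse of [ion_mz()]: given an observed m/z and an
#' ion hypothesis (charge, mode, adducts, deducts), returns the neutral
#' mass M such that `ion_mz(M, ...)` equals the observation.  The
#' matching engine neutralizes every observed mass under each hypothesis
#' and compares the result to the stored neutral database masses.
#'
#' @inheritParams ion_mz
#' @param observed_mz Observed mass-to-charge ratio in Da.
#' @return Candidate neutral mass in Da.
#' @export
neutral_mass_from_observed <- function(observed_mz, charge,
                                       mode = c("positive", "negative"),
                                       adduct_masses = numeric(),
                                       deduct_masses = numeric(),
                                       table = element_masses()) {
  mode <- match.arg(mode)
  charge <- as.integer(charge)
  if (is.na(charge) || charge < 0L || charge > 5L) {
    ms_hypothesis_error("charge must be an integer between 0 and 5")
  }
  if (charge == 0L) {
    if (length(adduct_masses) > 0L || length(deduct_masses) > 0L) {
      ms_hypothesis_error("adducts/deducts are not allowed at charge 0")
    }
    return(observed_mz)
  }
  s <- if (mode == "positive") 1 else -1
  m <- observed_mz * charge - s * charge * hydrogen_mass(table) -
    sum(adduct_masses) + sum(deduct_masses)
  if (m <= 0) {
    ms_hypothesis_error("hypothesis implies a non-positive neutral mass")
  }
  m
}
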