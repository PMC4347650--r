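# Bundled monoisotopic element masses.
#
# Values are the masses of the most abundant naturally occurring isotope
# of each element, in unified atomic mass units (Da), from the CODATA /
# AME-derived compilations used throughout accurate-mass spectrometry.
# The table is a versioned constant: it is never fetched at run time, so
# every mass this package computes is reproducible from the source alone.

.ELEMENT_MASSES <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  P  = 30.97376163,
  S  = 31.97207100,
  Na = 22.9897692809,
  K  = 38.96370668,
  Cl = 34.96885268,
  F  = 18.99840322,
  Br = 78.9183371,
  I  = 126.904473,
  Si = 27.9769265325,
  B  = 11.0093054,
  Se = 79.9165213,
  Li = 7.01600455,
  Mg = 23.9850417,
  Al = 26.98153863,
  Ca = 39.96259098,
  Cr = 51.9405075,
  Mn = 54.9380451,
  Fe = 55.9349375,
  Co = 58.9331950,
  Ni = 57.9353429,
  Cu = 62.9295975,
  Zn = 63.9291422,
  As = 74.9215965,
  Mo = 97.9054082,
  Sn = 119.9021947,
  W  = 183.9509312
)

.ELEMENT_TABLE_VERSION <- "metabosearch-elements-1.0 (CODATA/AME monoisotopic)"

#' Monoisotopic element mass table
#'
#' Returns the bundled table of monoisotopic element masses used for all
#' formula-to-mass calculations.  The table is a named numeric vector
#' (element symbol -> mass in Da) with a `version_tag` attribute recording
#' its provenance.  High-resolution mass spectrometers measure the
#' monoisotopic mass of an ion, i.e. the mass built from the most abundant
#' isotope of every constituent element, so this is the quantity all
#' database masses and ion hypotheses are expressed in.
#'
#' @return Named numeric vector of masses in Da, with attribute
#'   `version_tag`.
#' @examples
#' tbl <- element_masses()
#' tbl[["C"]]  # exactly 12 by definition of the unified mass unit
#' @export
element_masses <- function() {
  structure(.ELEMENT_MASSES, version_tag = .ELEMENT_TABLE_VERSION)
}

# Hydrogen-atom mass, the charge-carrier mass used for (de)protonation.
hydrogen_mass <- function(table = element_masses()) unname(table[["H"]])
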