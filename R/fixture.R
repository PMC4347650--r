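# Deterministic synthetic MRDB fixtures.
#
# The generator emulates a genome-restricted compound catalog the way a
# chemically defined bacterial growth medium exercises a real one: it
# always contains the 20 proteinogenic amino acids, glucose, citrate and
# the compounds of a defined-medium detection panel, with their true
# molecular formulae, plus isobaric pairs (citrate/isocitrate as C6H8O7,
# leucine/isoleucine as C6H13NO2) that make hit-multiplicity behaviour
# observable.  Beyond the core, random decoy compounds with plausible
# CHNOS formulae can be appended.  Everything is deterministic for a
# fixed seed.

.CORE_COMPOUNDS <- local({
  # name, formula, smiles, cas_id, fixed pathway ids (";"-separated)
  m <- matrix(c(
    "glycine",            "C2H5NO2",    "NCC(=O)O",                        "56-40-6",  "AA-BIOSYN;AA-DEG",
    "alanine",            "C3H7NO2",    "CC(N)C(=O)O",                     "56-41-7",  "AA-BIOSYN",
    "serine",             "C3H7NO3",    "OCC(N)C(=O)O",                    "56-45-1",  "AA-BIOSYN",
    "proline",            "C5H9NO2",    "OC(=O)C1CCCN1",                   "147-85-3", "AA-BIOSYN",
    "valine",             "C5H11NO2",   "CC(C)C(N)C(=O)O",                 "72-18-4",  "AA-BIOSYN;AA-DEG",
    "threonine",          "C4H9NO3",    "CC(O)C(N)C(=O)O",                 "72-19-5",  "AA-BIOSYN",
    "cysteine",           "C3H7NO2S",   "SCC(N)C(=O)O",                    "52-90-4",  "AA-BIOSYN",
    "leucine",            "C6H13NO2",   "CC(C)CC(N)C(=O)O",                "61-90-5",  "AA-BIOSYN;AA-DEG",
    "isoleucine",         "C6H13NO2",   "CCC(C)C(N)C(=O)O",                "73-32-5",  "AA-BIOSYN",
    "asparagine",         "C4H8N2O3",   "NC(=O)CC(N)C(=O)O",               "70-47-3",  "AA-BIOSYN",
    "aspartate",          "C4H7NO4",    "OC(=O)CC(N)C(=O)O",               "56-84-8",  "AA-BIOSYN;TCA",
    "glutamine",          "C5H10N2O3",  "NC(=O)CCC(N)C(=O)O",              "56-85-9",  "AA-BIOSYN",
    "lysine",             "C6H14N2O2",  "NCCCCC(N)C(=O)O",                 "56-87-1",  "AA-BIOSYN;AA-DEG",
    "glutamate",          "C5H9NO4",    "OC(=O)CCC(N)C(=O)O",              "56-86-0",  "AA-BIOSYN;TCA",
    "methionine",         "C5H11NO2S",  "CSCCC(N)C(=O)O",                  "63-68-3",  "AA-BIOSYN",
    "histidine",          "C6H9N3O2",   "OC(=O)C(N)Cc1cnc[nH]1",           "71-00-1",  "AA-BIOSYN",
    "phenylalanine",      "C9H11NO2",   "NC(Cc1ccccc1)C(=O)O",             "63-91-2",  "AA-BIOSYN",
    "arginine",           "C6H14N4O2",  "NC(=N)NCCCC(N)C(=O)O",            "74-79-3",  "AA-BIOSYN",
    "tyrosine",           "C9H11NO3",   "NC(Cc1ccc(O)cc1)C(=O)O",          "60-18-4",  "AA-BIOSYN;AA-DEG",
    "tryptophan",         "C11H12N2O2", "NC(Cc1c[nH]c2ccccc12)C(=O)O",     "73-22-3",  "AA-BIOSYN",
    "D-glucose",          "C6H12O6",    "OCC1OC(O)C(O)C(O)C1O",            "50-99-7",  "GLYCOLYSIS;PENTOSE",
    "citrate",            "C6H8O7",     "OC(=O)CC(O)(CC(=O)O)C(=O)O",      "77-92-9",  "TCA;GLYOXYLATE",
    "isocitrate",         "C6H8O7",     "OC(C(O)C(=O)O)(CC(=O)O)C(=O)O",   "320-77-4", "TCA;GLYOXYLATE",
    "pyridoxamine",       "C8H12N2O2",  "Cc1ncc(CO)c(CN)c1O",              "85-87-0",  "PYRIDOXAL-P",
    "pyridoxal",          "C8H9NO3",    "Cc1ncc(CO)c(C=O)c1O",             "66-72-8",  "PYRIDOXAL-P",
    "thymidine",          "C10H14N2O5", "CC1=CN(C2CC(O)C(CO)O2)C(=O)NC1=O", "50-89-5", "PYRIMIDINE",
    "dihydrouracil",      "C4H6N2O2",   "O=C1CCNC(=O)N1",                  "504-07-4", "PYRIMIDINE",
    "guanosine",          "C10H13N5O5", "Nc1nc2n(cnc2c(=O)[nH]1)C1OC(CO)C(O)C1O", "118-00-3", "PURINE",
    "MOPS",               "C7H15NO4S",  "OS(=O)(=O)CCCN1CCOCC1",           "1132-61-2", "",
    "alpha-methyl-glucose", "C7H14O6",  "COC1OC(CO)C(O)C(O)C1O",           "97-30-3",  "GLYCOLYSIS",
    "NDP-Glucoses",       "",           "",                                "",         "GLYCOLYSIS",
    "leucine-enkephalin", "C28H37N5O7", "",                                "58822-25-6", ""
  ), ncol = 5L, byrow = TRUE)
  data.frame(name = m[, 1L], formula = m[, 2L], smiles = m[, 3L],
             cas_id = m[, 4L], pw = m[, 5L], stringsAsFactors = FALSE)
})

.PATHWAY_POOL <- c(
  "GLYCOLYSIS"  = "glycolysis I",
  "TCA"         = "TCA cycle I (prokaryotic)",
  "GLYOXYLATE"  = "glyoxylate cycle",
  "PENTOSE"     = "pentose phosphate pathway",
  "AA-BIOSYN"   = "amino acid biosynthesis",
  "AA-DEG"      = "amino acid degradation",
  "PYRIDOXAL-P" = "pyridoxal 5'-phosphate salvage",
  "PYRIMIDINE"  = "pyrimidine nucleoside salvage",
  "PURINE"      = "purine nucleoside salvage",
  "GLUCONEO"    = "gluconeogenesis I"
)

# Names of the defined-medium detection panel: 17 compounds queried by
# monoisotopic mass in the verification experiment.
medium_panel_names <- function() {
  c("tyrosine", "pyridoxamine", "lysine", "thymidine", "pyridoxal",
    "glycine", "dihydrouracil", "arginine", "threonine", "alanine",
    "serine", "asparagine", "histidine", "tryptophan", "aspartate",
    "glutamate", "guanosine")
}

#' Generate a deterministic fixture MRDB
#'
#' Builds a small, fully synthetic MRDB for testing and demonstration.
#' The core always contains the 20 proteinogenic amino acids, D-glucose,
#' citrate/isocitrate (an isobaric C6H8O7 pair), the 17-compound
#' defined-medium detection panel, a glucose-name family for substring
#' searches, MOPS and leucine-enkephalin — all with true formulae and
#' curated pathway assignments (1-3 each).  `isobar_groups` forces named
#' compounds to share the formula (hence mass) of the group's first
#' member.  Additional decoy compounds with random CHNOS formulae are
#' appended up to `n_compounds`.  Output is byte-identical across calls
#' with the same arguments and seed.
#'
#' @param seed Integer seed driving decoy generation and random pathway
#'   assignment.
#' @param n_compounds Total number of compounds; defaults to the core
#'   set only.  Must be >= 1 (fewer than the core truncates it).
#' @param isobar_groups List of character vectors of compound names; each
#'   group is forced onto one shared formula.
#' @param db_name Database label.
#' @param table Element mass table.
#' @return An `mrdb` object.
#' @export
generate_fixture_mrdb <- function(seed = 1L, n_compounds = NULL,
                                  isobar_groups = list(c("citrate", "isocitrate"),
                                                       c("leucine", "isoleucine")),
                                  db_name = "fixture-medium",
                                  table = element_masses()) {
  if (!is.null(n_compounds) && n_compounds < 1L) {
    ms_input_error("n_compounds must be >= 1")
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  core <- .CORE_COMPOUNDS
  for (grp in isobar_groups) {
    idx <- match(grp, core$name)
    idx <- idx[!is.na(idx)]
    if (length(idx) >= 2L) core$formula[idx] <- core$formula[idx[1L]]
  }

  n_total <- if (is.null(n_compounds)) nrow(core) else as.integer(n_compounds)
  pool_ids <- names(.PATHWAY_POOL)

  rows <- core
  if (n_total > nrow(core)) {
    n_decoy <- n_total - nrow(core)
    decoy <- data.frame(
      name = sprintf("decoy-%03d", seq_len(n_decoy)),
      formula = vapply(seq_len(n_decoy), function(i) {
        nC <- sample(2:20, 1L); nH <- sample(4:32, 1L)
        nN <- sample(0:4, 1L);  nO <- sample(1:8, 1L)
        paste0("C", nC, "H", nH,
               if (nN > 0L) paste0("N", nN) else "",
               "O", nO)
      }, character(1L)),
      smiles = "", cas_id = "",
      pw = vapply(seq_len(n_decoy), function(i) {
        k <- sample(0:3, 1L)
        paste(sample(pool_ids, k), collapse = ";")
      }, character(1L)),
      stringsAsFactors = FALSE
    )
    rows <- rbind(core, decoy)
  } else if (n_total < nrow(core)) {
    rows <- core[seq_len(n_total), ]
  }

  # fill pathway-less core entries (except deliberate blanks) from the pool
  pathways <- lapply(rows$pw, function(p) {
    ids <- if (nzchar(p)) strsplit(p, ";", fixed = TRUE)[[1L]] else character()
    data.frame(id = ids, name = unname(.PATHWAY_POOL[ids]),
               stringsAsFactors = FALSE)
  })

  export <- data.frame(
    name = rows$name,
    formula = rows$formula,
    average_mw = vapply(rows$formula, function(f) {
      if (!nzchar(f)) return("")
      # carried-through "average MW": monoisotopic + a small isotopic offset
      formatC(monoisotopic_mass(f, table) * 1.0008, format = "f", digits = 2L)
    }, character(1L)),
    smiles = rows$smiles,
    cas_id = rows$cas_id,
    pathways = vapply(pathways, format_pathways, character(1L)),
    stringsAsFactors = FALSE
  )
  db <- suppressMessages(
    build_mrdb(export, db_name = db_name,
               link_template = "https://biocyc.example.org/pathway?object={id}",
               table = table, source_tag = sprintf("fixture(seed=%d)", seed))
  )
  # fixed stamp so the same seed yields a byte-identical file
  db$created <- "1970-01-01T00:00:00"
  db
}
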