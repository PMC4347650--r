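Package: metabosearch
Title: Genome-Restricted Metabolite Identification from Mass
    Spectrometry Peak Lists
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies metabolites from accurate-mass peak lists by
    matching names, molecular formulae, SMILES strings and monoisotopic
    masses against genome-restricted metabolic reference databases
    (MRDBs), enumerating electrospray charge-state and adduct/deduct ion
    hypotheses within a ppm or Da mass tolerance, and mapping every hit
    to its metabolic pathways.  Provides a flat-file MRDB builder and
    reader, parsers for plain query lists and MarkerLynx-style peak
    tables, TSV and HTML report writers, a deterministic fixture
    generator for testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
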