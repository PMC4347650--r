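# metabosearch

Genome-restricted metabolite identification from mass-spectrometry peak
lists, in R.

## The problem

High-resolution LC-MS metabolomics yields hundreds to thousands of
accurate masses per run, and most of them never match anything in the
empirically curated compound databases. Searching universal chemical
databases instead floods the analyst with non-biological candidates. The
approach implemented here restricts candidate identifications to the
compounds an organism's genome-encoded metabolism can actually produce:
queries are matched against **Metabolic Reference Databases (MRDBs)** —
flat-file compound catalogs derived from genome-scale metabolic
reconstructions — and every hit is mapped back to its metabolic
pathways, so a mass becomes a biological hypothesis rather than just a
chemical one.

`metabosearch` is for microbiologists and metabolomics analysts who have
a peak list (or a single mass, name, formula or SMILES string) and a
reconstructed metabolism to interpret it against.

## The method

Queries are classified by type (mass, molecular formula, SMILES, name)
and dispatched to the corresponding matcher:

* **Mass queries.** An observed m/z is explained by an *ion hypothesis*:
  a proton charge state *z* ∈ 0–5, the electrospray mode *s* = ±1, and a
  multiset of adduct/deduct species (Na, K, Cl, formate, lost fragments,
  …). Under the hydrogen-atom protonation convention (electron mass
  neglected),

  ```
  m/z = (M + s·z·m_H + Σ adducts − Σ deducts) / z        (z ≥ 1)
  ```

  The engine enumerates the full cross product of charge states and
  adduct/deduct multisets (bounded by a user-set maximum count), inverts
  this relation to get a candidate neutral mass *M* per hypothesis, and
  reports every database compound whose monoisotopic mass lies within
  the tolerance window (ppm, referenced to the theoretical mass, or Da).
  With this convention the [M+H]+ ion of the leucine-enkephalin lock
  mass (C28H37N5O7) computes to m/z 556.2771.

* **Name queries** match case-insensitive substrings ("glucose" finds
  D-glucose and every glucose conjugate), **formula queries** match
  element-count multisets (token order irrelevant), and **SMILES
  queries** match as strings (no chemical canonicalization).

Monoisotopic masses are computed from molecular formulae with a bundled,
versioned element mass table — nothing is fetched at run time.

## Worked example

```r
library(metabosearch)

# A deterministic synthetic MRDB modelled on a chemically defined
# bacterial growth medium (20 amino acids, glucose, citrate/isocitrate,
# a vitamin panel, leucine-enkephalin), with pathway assignments:
db <- generate_fixture_mrdb(seed = 1)

# Positive mode, singly charged, 5 ppm, optional Na adduct:
params <- search_params(5, "ppm", mode = "positive", max_charge = 1,
                        adducts = "Na", max_adduct_count = 1)
match_mass_query(556.2771, db, params)[
  , c("name", "formula", "hypothesis", "deviation_ppm")]
#> # A tibble: 1 × 4
#>   name               formula    hypothesis deviation_ppm
#>   <chr>              <chr>      <chr>              <dbl>
#> 1 leucine-enkephalin C28H37N5O7 [M+H]+           -0.0425
```

The observed m/z 556.2771 is explained as the protonated molecule of
leucine-enkephalin, 0.04 ppm from its theoretical mass. A neutral-mass
query at Da tolerance shows isobar behaviour — two compounds share the
formula C6H8O7, so both are (correctly) reported:

```r
match_mass_query(192.0270, db, search_params(0.001, "Da", max_charge = 0))[
  , c("name", "formula", "hypothesis", "deviation_da")]
#> # A tibble: 2 × 4
#>   name       formula hypothesis deviation_da
#>   <chr>      <chr>   <chr>             <dbl>
#> 1 citrate    C6H8O7  [M]         -0.00000259
#> 2 isocitrate C6H8O7  [M]         -0.00000259
```

Batch searches read a query text file (queries in column 1, payload
columns carried through) or a MarkerLynx-style peak table
(`"RT_mz"` labels), and `write_report()` emits the three output
artifacts: `compounds.tsv` (one row per match), `pathways.tsv` (each
match repeated per pathway membership, sortable by pathway) and
`report.html` (parameter echo, TSV download links, pathway hyperlinks).

### Command line

```sh
Rscript inst/cli/metabosearch.R fixture --out medium.tsv --seed 1
Rscript inst/cli/metabosearch.R search --db medium.tsv \
    --input peaks.txt --input-format markerlynx \
    --tolerance 5 --unit ppm --mode positive --max-charge 1 \
    --adduct Na --max-adducts 1 --out-dir results/
Rscript inst/cli/metabosearch.R summarize --db medium.tsv
```

Subcommands: `build` (compound export → MRDB), `fixture`, `search`,
`summarize` (metabolite distribution by molecular mass). Exit codes:
0 success, 1 usage error, 2 data error.

## Limitations

* SMILES matching is lexical; chemically equivalent but differently
  written SMILES do not match.
* No isotope-envelope scoring, retention-time matching, MS/MS fragment
  matching, or intensity statistics — the tool identifies, it does not
  quantify.
* Average-mass searches use the carried-through average MW column with a
  Da tolerance only.

See the methods vignette (`vignettes/metabolite-identification.Rmd`) for
the full model description, parameter guidance and design rationale.
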