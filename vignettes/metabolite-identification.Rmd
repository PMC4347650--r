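---
title: "Genome-restricted metabolite identification: model and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-restricted metabolite identification: model and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabosearch)
```

## The identification model

A high-resolution mass spectrometer reports the m/z of an ion, not the
identity of a molecule. `metabosearch` turns an m/z into candidate
identifications in three steps.

**1. Ion hypotheses.** Every observed ion is assumed to arise from a
neutral molecule of monoisotopic mass $M$ by electrospray ionization:
$z$ protons are attached (positive mode, $s = +1$) or removed (negative
mode, $s = -1$), and a multiset of adduct species may be gained and
deduct species (fragments) lost:

$$ m/z \;=\; \frac{M + s\,z\,m_\mathrm{H} + \sum_i a_i - \sum_j d_j}{z},
   \qquad z \ge 1 $$

$m_\mathrm{H}$ is the hydrogen **atom** monoisotopic mass
(1.00782503 Da); the electron mass is neglected. This convention is
deliberate: it reproduces the reference m/z values conventionally
printed for lock-mass calibrants (the [M+H]+ of leucine-enkephalin,
C28H37N5O7, computes to 556.2771; the proton-mass convention would give
556.2766). At the sub-ppm level where the electron mass matters,
instrument calibration error dominates anyway.

$z = 0$ is a valid state meaning "the query already is a neutral
mass" — useful when querying theoretical masses directly — and carries
no adducts or deducts, since there is no ionization event to attach
them to. It is included in the hypothesis set by default
(`include_neutral = FALSE` suppresses it).

`enumerate_hypotheses()` expands the full cross product of charge
states and adduct/deduct multisets up to a user-set total count. This
includes mixed hypotheses such as [M+2H+Na−H]2+; whether such
proton-plus-cation combinations occur in a given source depends on the
instrument, so the maximum counts are the user's instrument knowledge,
not the engine's.

**2. Neutralization.** Rather than ionizing every database record under
every hypothesis, the engine inverts the relation above: each observed
m/z is converted to one candidate neutral mass per hypothesis
(`neutral_mass_from_observed()`, the exact algebraic inverse of
`ion_mz()` — the package tests verify the round trip to $10^{-9}$ Da
over the whole hypothesis grid). The candidate is then compared against
all stored neutral masses at once with a vectorized window test. This
is algebraically identical to the record-by-record direction but costs
O(hypotheses + records) per query rather than O(hypotheses × records).

**3. Tolerance.** The match window is either absolute
(`tolerance_unit = "Da"`) or relative (`"ppm"`), with the **theoretical
(database) mass as the ppm reference**:
$|M_\mathrm{cand} - M_\mathrm{theo}| \le \tau\, M_\mathrm{theo}/10^6$.
Referencing the theoretical mass makes the window a property of the
candidate compound alone, so a compound's acceptance does not depend on
which ion hypothesis produced the candidate; the difference from
observed-mass referencing is second order below 100 ppm.

Non-mass queries bypass the ion model entirely: names match as
case-insensitive substrings (so `"glucose"` finds every glucose
conjugate — deliberately recall-oriented; exact database names narrow
to single hits), formulae match as element-count multisets (token order
ignored), and SMILES match as whitespace-stripped strings with no
chemical canonicalization (a lexical choice: canonicalization would
drag in a cheminformatics stack and mask database inconsistencies
rather than reveal them).

## Genome restriction

The search space is a **Metabolic Reference Database**: the compound
catalog of one organism's reconstructed metabolism (or of a general
encyclopedia). Because an organism-specific MRDB is a subset of the
encyclopedia it was carved from, hit sets are nested: restricting the
database can only remove candidates, never add them. This monotonicity
is the scientific point of the tool — it is what shrinks a long list of
chemically possible identifications down to the metabolically plausible
ones — and it is enforced by construction and verified by
property-style tests on nested fixture databases.

MRDBs are flat tab-delimited files (see `?write_mrdb` for the dialect).
Only neutral monoisotopic masses are stored; charged-state masses are
computed on the fly from the ion model, which is algebraically
equivalent to precomputing them and keeps the files small. Masses are
computed from formulae with a bundled, versioned element table
(`element_masses()`); records whose formula does not parse are retained
without a mass (they remain findable by name/formula/SMILES) and logged
at build time.

## Parameters that matter

| Parameter | Units | Default | Guidance |
|---|---|---|---|
| `tolerance_value`/`unit` | ppm or Da | none (required) | Instrument mass accuracy; QTof-class instruments typically 1–10 ppm. Determines the hit-list width directly. |
| `mode` | – | positive | Must match the acquisition polarity. |
| `max_charge` | – | 1 | ESI sources are tuned for singly charged small molecules; raise only if multiply charged species are expected. |
| `adducts`/`deducts` | formula or Da | none | Declare what the sample chemistry makes plausible (Na, K from glassware and buffers; Cl, formate in negative mode). [M+Na]+ -type cationization is expressed as adduct `Na` plus deduct `H` under the single protonation formula. |
| `max_adduct_count` | – | 0 | Total adducts + deducts per hypothesis; each increment multiplies the hypothesis space. |
| `mass_kind` | – | monoisotopic | `average` searches the carried-through average MW column, Da tolerance only — ppm against an isotope-abundance-weighted mass is ill-defined. |

## Query classification

A free-text query is classified by a deterministic priority: positive
decimal number → mass; valid formula that contains a digit or more than
one element → formula; SMILES-alphabet string with at least one
structural character → smiles; otherwise name. Ambiguity is resolved,
not enumerated: `"CO"` is carbon monoxide's formula, not a name
fragment, because formula outranks name; `--force-type` (or the
`force_type` argument) overrides classification when the user knows
better. Comma decimals are never treated as masses (locale ambiguity);
they fall through to name and will simply find nothing.

Input files are tolerated, not policed: headers, blank lines and
unusable first fields are skipped and logged with line numbers (never
silently dropped), and `strict = TRUE` turns any skip into an error.
The MarkerLynx-style dialect accepted here — `RT_mz` underscore labels
or bare masses in column 1, intensities in the remaining columns — is
this package's own definition, chosen so that a bare-mass file parses
identically through either the text or the MarkerLynx channel (a tested
invariant).

## Output accounting

Three artifacts per run: `compounds.tsv` (one row per match),
`pathways.tsv` (each match repeated once per pathway membership, so the
row count is exactly $\sum \max(1, \text{pathways})$ over compound
rows), and `report.html` (parameter echo, download links, pathway
hyperlinks built from each database's URL template). The full parameter
set is echoed identically at the top of all three files, so a result
file is never separated from the settings that produced it. Queries
with zero hits emit an explicit `no match` row: input and output rows
always reconcile. Deviations print at 4 (Da) and 2 (ppm) decimals for
diffable output; `precision` widens this.

## What the fixture generator emulates — and what it does not

`generate_fixture_mrdb()` produces a deterministic synthetic MRDB
modelled on a chemically defined bacterial growth medium: the 20
proteinogenic amino acids, D-glucose, citrate and isocitrate (an
isobaric C6H8O7 pair), a 17-compound detection panel (amino acids plus
pyridoxal, pyridoxamine, thymidine, dihydrouracil, guanosine), MOPS
buffer, a glucose-name family for substring tests, and
leucine-enkephalin — all with true formulae, plausible SMILES, CAS
numbers and 1–3 curated pathway assignments. Decoy compounds with
random CHNOS formulae extend it to any size; everything is byte-stable
for a fixed seed.

This emulates the *combinatorial* structure of real MRDBs: isobars,
shared substrings, pathway multiplicity, missing formulae
(NDP-Glucoses is a deliberate formula-less class entry). It does **not**
emulate their scale (thousands of compounds), their mass-density
profile (real databases have dense isobar clusters above ~300 Da, so
real hit multiplicities are higher), chemical noise, or in-source
fragmentation. Passing tests therefore demonstrate correctness of the
matching algebra and bookkeeping, not expected hit-list sizes on real
organisms.

## Numerical choices and degenerate inputs

* Result order is deterministic: |ppm deviation| ascending, then
  compound name, then database label. Ties (exact isobars) are resolved
  alphabetically.
* Mass bins in `mass_distribution()` are left-closed on integer edges
  ([100, 200) prints as "100-199"); a mass exactly at an edge belongs to
  the bin it opens. Masses below the first edge are excluded and
  counted separately.
* The tolerance comparison is a plain `<=` on IEEE doubles with no
  epsilon padding; at the 1e-4 Da and larger windows that matter here,
  double rounding (~1e-13 relative) is negligible.
* Empty formula → mass 0; empty MRDB → zero-count distribution; empty
  hit set → explicit no-match row. Hypotheses that would imply a
  non-positive neutral mass (nonsensical deduct sets) are skipped per
  hypothesis, not fatal.
* MRDB masses are printed to 6 decimals (0.5 µDa), comfortably below
  any instrument tolerance, so the write → read round trip is an
  identity for practical purposes.

## Test problem sizes

The test suite exercises fixtures of 32–100 compounds; the
engine-versus-oracle equivalence check runs 1,000 seeded random
parameter draws (tolerance unit and width, mode, charge 0–3, Na/K/H2O
species, adduct counts 0–2) against an independent brute-force matcher
written as a plain triple loop with inline algebra, and requires exact
hit-set equality on every draw, with several hundred draws landing
non-empty hit sets. These sizes give full coverage of the hypothesis
grid while keeping the suite fast enough to run on every change.

## Known limitations

* Lexical SMILES matching (above).
* One query, one type: ambiguous strings are classified to a single
  type rather than searched against multiple fields; `force_type` is
  the escape hatch.
* No isotope-envelope scoring, retention-time or MS/MS evidence,
  pathway drawing, or intensity statistics — identification and
  pathway mapping only.
* The formula grammar is flat (no parentheses, hydrates, isotope
  labels), matching the style of pathway-database exports; structured
  formulae must be expanded before import.
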