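---
title: "Signature-peptide MRM bioanalysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature-peptide MRM bioanalysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmsig)
```

## The problem

Therapeutic proteins — monoclonal antibodies and Fc-fusion constructs such
as TNFR2–Fc (Etanercept) or CTLA-4–Fc (Abatacept) — are quantified in serum
by LC-MS through a *signature peptide*: a tryptic peptide unique to the
analyte that serves as a stoichiometric proxy for the intact protein. A
triple-quadrupole instrument monitors one precursor/fragment m/z pair
(an MRM *transition*) per peptide, peak areas are normalized to a
co-injected internal standard (ISTD), and concentrations are read off a
calibration curve. Before such an assay can support therapeutic drug
monitoring it must pass a bioanalytical validation: precision and accuracy
at QC levels spanning the calibrated range, judged against guideline
thresholds.

`mrmsig` implements the computational side of this workflow: candidate
peptide enumeration and screening, exact transition m/z design, ISTD
quantitation and ratio analyses, validation statistics, and a synthetic
peak-area generator so the entire pipeline is testable without instrument
output.

## Digestion model

Trypsin is modeled as cleaving C-terminal to lysine or arginine except when
the next residue is proline. `digest()` enumerates every peptide with up to
`max_missed` internal uncut sites (default 2) and annotates each with
1-based inclusive coordinates, terminus flags, cysteine content, and
`min_cys_distance` — the primary-sequence distance to the nearest annotated
disulfide cysteine. Distance is measured along the chain only; structural
(3-D) proximity to a disulfide is out of scope, so a peptide far in
sequence but close in space will not be flagged.

Coordinates are reported 1-based inclusive, the convention of peptide-map
tables ("aa. 42–46"). Published maps for the same molecule can disagree by
one residue depending on whether numbering starts at the mature or the
initiator N-terminus; the package always reports coordinates computed from
the sequence it was given and makes no attempt to reconcile external
numberings.

N-terminal heterogeneity is represented as *alternative starts*: a named
set of prefixes prepended to the parent sequence (e.g. `""`, `"A"`,
`"MA"`). `enumerate_start_variants()` digests each variant and returns its
first tryptic peptide. Because the variants share their C-terminus, their
y-series ions coincide — the basis of the heterogeneity ratio measurement
below. If a prefix itself contains a cleavage site the first peptide
shortens accordingly, which is the correct behaviour, not an error.

## Candidate screening

`selection_criteria()` encodes the accepted rules for signature-peptide
selection: 8–15 residues, no cysteine, no missed cleavage, not adjacent to
a disulfide bond, not the protein's N- or C-terminal peptide (terminal
fragments carry amino-acid heterogeneity), and unique against a background
peptide set. Two generalizations were needed to make the rules operational
for Fc-fusion proteins:

* **Uniqueness instead of CDR membership.** Antibody rules ask for peptides
  inside the CDRs because everything else is shared with endogenous IgG.
  Fc-fusion proteins have no CDRs, so the criterion is generalized to
  absence from a background set: the union of fully cleaved tryptic
  peptides of the supplied background proteins
  (`background_peptide_set()`), by default the Fc portions at/after each
  protein's annotated fusion junction plus any user-supplied IgG
  sequences. Isoleucine and leucine are collapsed before comparison —
  they are isobaric and indistinguishable by MRM, so treating `AAIK` and
  `AALK` as distinct would manufacture false uniqueness.
* **A quantified "vicinity" of disulfides.** No standard number exists for
  how close to a disulfide bond is too close. The package uses a residue
  window (`disulfide_window`, default 3, i.e. distances 0–2 violate) and
  exposes it in the configuration; the default is a package convention,
  flagged as such here rather than hidden.

`select_candidates()` never drops peptides: every peptide appears with its
violation list, because for heavily disulfide-bonded fusion proteins the
realistic outcome is that *no* peptide passes and the analyst must pick the
least-bad candidate (typically a cysteine-containing or N-terminal
peptide). Ranking is fewest violations first, then longer peptides (more
selective transitions), then N-to-C position; the tie-break order is a
package convention, documented in the CLI help.

## Mass computation

All masses are monoisotopic, built from the standard residue-mass table
(`amino_acid_masses`), water 18.010565 Da, proton 1.007276 Da and hydrogen
atom 1.007825 Da. Precursors are `(M + z·proton)/z`; b ions are prefix
residue sums plus protons; y ions are suffix sums plus water plus protons.
No modifications are modeled except the disulfide homodimer (assays of
this type run under mild reduction without alkylation, so there is no
carbamidomethyl-cysteine): an oxidized peptide homodimer has mass
`2M − 2·1.007825`, and after in-source disulfide cleavage its fragments
appear one hydrogen atom light (`disulfide_dimer_species()`).

Printed transition lists mix instrument-nominal and monoisotopic values
(unit-resolution quadrupoles are commonly reported at 0.1 Th granularity
that does not survive exact recomputation). The package therefore always
*computes* monoisotopic values and reconciles printed lists through
`match_transition()`, which reports the deviation explicitly instead of
storing printed values as truth. Matching uses the Chebyshev metric
`max(|ΔQ1|, |ΔQ3|)` with a 0.5 Th default tolerance, ties broken by
combined deviation then lower fragment index — deterministic by
construction. Reported rounding is half-away-from-zero (`round_half_up()`),
1 decimal for transition tables and 2 decimals for calibration standards,
matching the mixed precision of printed methods.

## Quantitation and ratio analyses

The normalized response is simply `analyte_area / istd_area`; a
non-positive ISTD area is treated as a failed injection and errors rather
than propagating.

**Calibration.** `fit_calibration()` fits weighted linear least squares of
response on concentration. The default weighting is `1/x²`, the standard
choice for bioanalytical LC-MS calibrations spanning ~3 orders of
magnitude (a 10-point 2-fold series from 100 µg/mL spans 512×): it
equalizes *relative* residuals so the LLOQ is not dominated by the top
calibrators. `none` and `1/x` are available. The fitting method is a
design choice of this package — validated-assay reports typically do not
print one — and with `1/x²` the per-level back-calculated accuracies are
invariant to rescaling all responses, which is also a regression test.
Blanks and zero samples never enter the fit. Back-calculation inverts the
line; negative values clamp to 0 with a `below_range` flag (instead of
erroring) so validation tables can still aggregate, and values outside the
calibrated span are flagged.

**N-terminal heterogeneity.** Variants sharing a common y ion have
comparable fragmentation response, so their ISTD-normalized intensities can
be compared directly. `heterogeneity_content()` reports both the
conventional percent-of-most-abundant scale (max = 100) and each variant's
share of the total; the output is scale-invariant and shares sum to 100%.

**Oxidation ratio.** For a cysteine-containing signature peptide,
`oxidation_ratio()` expresses monomer and disulfide-dimer intensities as a
percent of their *own* reference condition (e.g. untreated control = 100
for the monomer, fully oxidized = 100 for the dimer). A species below the
detection threshold is carried as not-detected (`NA`, printed `N.D.`) and
is deliberately distinct from a measured zero.

## Validation statistics

`run_statistics()` uses the universal conventions: arithmetic mean, sample
SD (n−1), CV% = 100·SD/mean, accuracy% = 100·mean/nominal; cells are
reported at 3 significant figures, half-away-from-zero. A zero mean makes
the CV not-computable (`NA`), never infinite. Pooled statistics are
computed from all `runs × replicates` individual values rather than by
combining run summaries — published "average" rows are occasionally
internally inconsistent with their own run rows, and recomputation from
raw values is the only reproducible convention.

`guideline_check()` applies the acceptance rules of bioanalytical
validation guidance (the 2013 MHLW guideline family, matching
EMA/FDA practice): accuracy within ±15% and CV ≤ 15%, both relaxed to 20%
at the LLOQ; calibration acceptable when ≥ 75% of levels and at least 6
back-calculate within the same tolerances; selectivity when blank analyte
response ≤ 20% of the mean LLOQ response and blank ISTD-channel response
≤ 5% of the mean ISTD. These thresholds are configurable defaults because
guidance documents state them as expectations, not all assays print them.
All comparisons are boundary-inclusive (a CV of exactly 15.0% passes), a
convention this package fixes explicitly since guidance text is silent on
ties. Verdicts are monotone: tightening any threshold can only convert
passes to fails, which is enforced by a property test.

## The synthetic-data generator

`simulation_config()` defines the study the generator emulates — the
design of a serum validation batch for an Fc-fusion assay:

* a 10-level, 2-fold calibration series from 100 µg/mL (so the LLOQ is
  100/2⁹ ≈ 0.195 µg/mL), one replicate per level, calibrator CV 5%;
* QC levels LLOQ/LQC/MQC/HQC = 0.195/0.586/9.38/80.0 µg/mL, 3 runs × 5
  replicates (the *set* concentrations actually analyzed in such
  validations; protocol texts sometimes round the top levels to 10/100);
* per-level QC CVs of 9/6/5/6%, mirroring the pooled precision a
  validated assay of this type reports (≈8.6% at the LLOQ, 5–6% above);
* ISTD areas around 10⁵ counts with 5% CV; blank channels at 2% (analyte)
  and 1% (ISTD) of the corresponding signal;
* a three-variant N-terminal mixture with true shares 0.705/0.261/0.034
  (the share decomposition of a dominant ~70% main form);
* oxidation conditions: an untreated control (monomer fraction 1) and a
  near-complete peroxide oxidation (monomer 0.0026), with a not-detected
  threshold of 10⁻³ normalized units;
* a true calibration line of slope 0.02, intercept 0 — arbitrary by
  design; every test asserts *recovery* of the truth, never its absolute
  value.

Noise is multiplicative lognormal with unit mean at the stated CV
(`σ_log² = log(1 + CV²)`, mean-log `−σ_log²/2`). Lognormal was chosen over
additive Gaussian because peak areas are positive and their dispersion is
naturally CV-parameterized; unit mean keeps accuracy unbiased so parameter
recovery is a meaningful test. Each generator seeds its own RNG stream
from `config$seed` and restores the caller's RNG state, so generators are
pure functions of their configuration and adding one kind of measurement
never shifts another.

What the generator does **not** emulate — and what passing tests therefore
cannot show about real data: chromatographic peak shape and integration,
retention-time drift, matrix effects and ionization suppression,
carry-over, inter-day trends (runs are exchangeable draws), antidrug
antibody interference, and any correlation structure between QC levels.
It produces *areas with the assumed statistical model*, which is exactly
what is needed to test the arithmetic downstream, and nothing more.

Problem sizes used by the shipped tests were chosen to make sampling error
negligible relative to the asserted tolerances: brute-force digestion
equivalence on random sequences up to 50 residues, the b/y complementarity
identity on 1000 random peptides, slope recovery over 1000 simulated
calibrations at 10% CV (asserted within 3 Monte-Carlo standard errors),
and a pinned 200-seed end-to-end battery on which the guideline verdict
must pass at least 95% of the time.

## Known limitations

* Uniqueness screening is exact string matching (after I/L collapse) on
  fully cleaved peptides; it does not model near-isobaric interferences,
  semi-tryptic background, or chromatographic co-elution.
* Only b/y series and the disulfide homodimer are modeled — no neutral
  losses, no a-ions, no isotope envelopes, no collision-energy or
  retention-time prediction.
* The calibration model is strictly linear; quadratic or 4PL responses are
  out of scope.
* Guideline coverage is the core precision/accuracy/calibration/
  selectivity set; matrix effect, carryover, dilution integrity and
  stability reduce to generic measured/nominal ratio checks on labeled
  sample roles.
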