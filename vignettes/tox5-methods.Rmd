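---
title: "Methods: HTS preprocessing, Tox5 scoring and cluster significance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: HTS preprocessing, Tox5 scoring and cluster significance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical procedures it
implements, the choices that were genuinely open, and what the test suite
does and does not demonstrate.

## The screening model

The unit of measurement is a 384-well plate (16 rows A–P × 24 columns):
one plate per endpoint × exposure time × biological replicate × serum
condition, with luminescence endpoints (CTG) read plate-wise from CSV
exports and imaging endpoints (DAPI, Caspase-3, γH2AX, 8OHG) summarized to
well-median intensities in a combined tab-separated file, DAPI as two
technical duplicates per well. Wells carry one of three roles: `treated`
(a material at one dose of a dilution series), `control` (vehicle, dose 0)
or `blank` (no cells). Metadata resolution is two-staged: per-file
coordinates (endpoint, time, replicate, cell line, serum) come from a
"files sheet" that is auto-filled from filename tokens and may be corrected
by hand; per-well coordinates (material, dose, unit, role) come from a
"front sheet" shared by all plates. Label harmonization (e.g. `HEPG2`,
`HEP-G2` → `HepG2`) is dictionary-based, case- and punctuation-insensitive,
and idempotent.

## Normalization and cleaning

Processing is endpoint-specific but built from five shared operations,
applied in this order:

1. **Technical duplicates** (DAPI) are averaged per well.
2. **DAPI cleaning.** A DAPI value of exactly 0 is ambiguous: either the
   cells are dead or the image focus failed. The package decides by the
   biological replicates at the same (material, dose, time, cell line,
   serum): if their summary statistic is ≤ 50, the 0 is kept and the other
   imaging endpoints of the same well are set to 0 (dead cells emit no
   signal — that is information); if it exceeds 50, DAPI and the associated
   endpoints become `NaN` (no usable measurement). The replicate statistic
   is the median by default with mean as an option, and associated
   endpoints consult the *duplicate-averaged raw* DAPI value of their well,
   not the already-cleaned one — otherwise a `NaN` produced for DAPI would
   mask the trigger for its associated endpoints. The threshold 50 is on
   the raw DAPI (cell count) scale. Nonzero DAPI values are never modified.
3. **0-h baseline.** Endpoints screened with a pre-exposure plate (CTG)
   are corrected by subtracting, per well, the median of the 0-h values
   across replicates. Subtraction is the default; a ratio mode is kept as
   a configuration option since both conventions circulate. The 0-h plates
   exist only as baseline: they are not themselves normalized and never
   enter the metrics.
4. **Percent of control.** Values become percentages of the plate-wise
   control median, after control outliers outside
   [Q1 − 1.5·IQR, Q3 + 1.5·IQR] are removed (quartiles by linear
   interpolation, R's default type 7 — the method had to be fixed for
   reproducibility). Viability-type endpoints (CTG, DAPI) use the
   *inhibition* convention, `(1 − x/median)·100`; damage and apoptosis
   endpoints the *effect* convention, `x/median·100`. The two sum to 100,
   and both put "larger = more toxic" on a common footing, which the
   significance thresholds below presume.
5. **Caspase cell-loss rescaling.** Apoptosis signal per well
   underestimates the effect once cells are lost, so the caspase percent is
   divided by `1 − mean(CTG%, DAPI%)/100` at the same condition; a
   denominator of 0 (all cells lost) yields `NaN` with a warning.

Whether baseline correction precedes percent-of-control is not dictated by
the arithmetic; the package defaults to baseline-then-percent, which keeps
the later-time control medians well away from zero (the 0-h level is small
relative to grown cultures), and exposes the order through
`preprocess_endpoint()` arguments.

Replicate aggregation (median by default, mean optional) ignores missing
values; a condition missing in every replicate stays missing.

## Dose–response metrics

Metrics are computed per (material × endpoint × time × cell line × serum)
from the normalized layer, against the pooled, IQR-filtered plate controls
of the same condition:

- **First significant effect dose** (2SD and 3SD cutoffs): scanning doses
  upward, the first whose replicate mean exceeds the control median +
  k·SD *and* whose replicate values differ from the control values in a
  two-tailed Welch t-test at α = 0.05. The Welch test was a choice — the
  test family is not fixed by the method description — and is isolated in
  `first_significant_dose()` so it can be swapped. Absence of a qualifying
  dose is reported as missing, not as an error: it later scores as least
  toxic. By construction the 3SD dose never precedes the 2SD dose.
- **AUC** over log₁₀ dose by the trapezoid rule, with effects below the
  control median + 2SD set to 0 *in place* (rather than dropped), so the
  dose grid — and hence comparability across materials — is preserved.
  Dose 0 rows are excluded from the x-axis (log undefined; controls define
  the threshold, not the curve) and nothing is extrapolated beyond the
  highest tested dose.
- **Maximum effect**: the median over replicates of each replicate's
  maximum across doses, robust to a single aberrant screen.

## Tox5 scoring

First-significant doses are transformed with −log₁₀(x) + 6 (lower dose →
higher score; the +6 offset keeps transformed values positive for doses in
µg/ml down to the picogram range, and negative results are clipped to 0),
AUC and maximum effect with the square root; a Yeo–Johnson transform with
maximum-likelihood λ (via `car::powerTransform`) is available for skewed
libraries. Each metric column is then min–max scaled over the material
library. Two degenerate rules are fixed deliberately: a constant column
scales to all 0 (it carries no ranking information), and missing metrics
scale to 0 (a material with no significant effect is least toxic on that
axis — low-toxicity materials may be scored by their maximum effect alone).

Auto-slicing groups the four metrics of each endpoint × time (× cell line,
× serum) condition into one slice with weights 50% (first-sig-3SD) and 1/6
each for the rest — emphasizing the most specific sensitivity metric —
with manual slices and per-metric weights available. Slice score = weighted
sum of scaled metrics; total = slice-weight-weighted mean; both lie in
[0, 1] and are monotone in every metric. Ranks use competition ranking
(ties share the smaller rank; rank 1 = most toxic).

**Bootstrap intervals.** The resampling unit is the material row: each of
`n_boot` resamples (default 1000) redraws the library with replacement,
which moves the min–max scaling bounds; all *original* materials are
rescored under those bounds (clipped to [0, 1]) and percentile 2.5/97.5
intervals are taken for every slice score, total and rank. Resampling the
library rather than underlying replicates is the cheaper and fully
deterministic-under-seed choice; it measures sensitivity of the scores to
library composition, not assay noise — replicate-level resampling would be
the natural extension.

## Cluster significance

Materials are clustered on their slice-score profiles (default: Euclidean
distance, Ward linkage via `ward.D2`; Ward is refused for non-Euclidean
metrics). The elbow rule maximizes the second difference
W(k−1) − 2W(k) + W(k+1) of the within-cluster sum of squares; degenerate
inputs fall back to k = 2. Cluster support follows the multiscale
bootstrap: at each scale r ∈ {0.5, …, 1.4}, `round(r·p)` of the p feature
columns are resampled with replacement `n_boot` times and each original
node's member set is counted when it reappears. The per-scale bootstrap
probabilities BP_r are probit-transformed and fitted by weighted least
squares to z = v·√r + c/√r, with weights the inverse delta-method variance
of z under binomial counts; AU = 1 − Φ(v − c) and BP = 1 − Φ(v + c). Only
informative scales (0 < count < n_boot) enter the fit; a node recovered in
every resample at every scale is reported as AU = BP = 1 (and a never
recovered one as 0), matching the behavior of the reference implementation
of the method. One consequence worth knowing: for a node whose BP_r is
constant at a value away from 0.5, the two basis functions split the
constant between v and c, so AU is pulled toward 0.5 rather than toward
BP — AU and BP coincide exactly only at 0.5. AU > 0.95 is the conventional
support threshold.

## The synthetic campaign generator

`simulate_material_library()` plants, per material, a Hill dose–response on
the effect-fraction scale, f(d) = emax·dʰ/(EC50ʰ + dʰ) (slope h = 2);
viability endpoints lose signal proportionally (`base·(1 − f)`), effect
endpoints gain it (`base·(1 + 2f)`). The default design mirrors a full
screen: 12-dose two-fold series from 256 µg/ml, 4 biological replicates,
± serum, imaging at 6/24/72 h, CTG additionally at 0 h, DAPI duplicated,
materials on plate rows 1–16 with doses in columns 1–12, vehicle controls
in columns 13–14 and blanks elsewhere. Noise is Gaussian on the raw
plate-reader scale with standard deviation `noise_cv` × the endpoint's
control level; 0.05 (a 5% control CV, typical of a well-behaved
luminescence assay) is the default, and `plate_effect_sd` adds an optional
log-normal per-plate multiplier that percent-of-control must cancel.
Artifacts are injected, and recorded in the truth object, as control-well
outliers (×10) and DAPI focus failures — a 0 reading in both technical
duplicates of a low-toxicity well whose other replicates are clearly
populated, so the cleaning rule must map it to `NaN`, not to cell death;
the generator deliberately spreads multiple failures over distinct
conditions, because two failures in the same condition would legitimately
look like cell death to the rule (the replicate median collapses).

What the generator does *not* emulate: optical interference by the tested
materials, edge and gradient effects within plates, heteroscedastic or
heavy-tailed noise, dose-dependent cell detachment, or imperfect
dispensing. Passing tests therefore demonstrate the pipeline's arithmetic
and its recovery of planted structure under idealized noise — not
robustness to every failure mode of real screens.

## Problem sizes and numerical conventions

The test suite and the acceptance script run small-to-full synthetic
campaigns: unit tests mostly use a reduced design (6 doses, 3 replicates,
one serum arm, one imaging time; 9 plates) with 3–6 materials, while the
design-arithmetic check generates the complete five-endpoint design (56
raw files, 58 368 well values) with 8 materials. Bootstrap runs use
100–500 resamples in tests and the acceptance script; multiscale bootstrap
uses 100–200 resamples per scale over 10 scales. These sizes were chosen so
the whole suite completes in well under a minute per file while leaving the
statistical checks (rank recovery, CI coverage, AU calibration) sharp.

Other fixed conventions: well labels accept zero-padded and plain forms
("A01" ≡ "A1"); missing values are a single `NA`/`NaN` sentinel everywhere,
distinct from 0 (the DAPI rules depend on the distinction); quantiles are
type 7; doses of exactly 0 never enter a log axis; Eq.-level dose
conversions treat well volume in µl → ml (the published formula's unit
nesting only reproduces the published material table under that reading);
and the µg/cm² column of the published table for some reference materials
implies a different plate geometry than their cm²/cm² column — both
geometries (0.1 and 0.0795 cm²/well) are supported and the discrepancy is
left as published rather than resolved.

## Limitations

- No dose–response curve *fitting* (Hill/4PL) or benchmark-dose modelling:
  the metrics are deliberately model-free.
- No spatial plate correction (B-score/median polish) or edge-effect
  handling; percent-of-control assumes plate effects are multiplicative
  and position-independent.
- The delivered-dose unit (cm²/cm² actually reaching cells) is accepted as
  a user-supplied per-material fraction; no sedimentation/diffusion
  modelling is attempted.
- Bootstrap CIs quantify library-composition uncertainty, not assay noise
  (see above).
- The NeXus layout (group naming, dense-axis order material × dose × time ×
  replicate × cell line × serum, NaN padding for unbalanced designs) is a
  documented dialect of this package; files are plain HDF5 and readable
  anywhere, but other converters may arrange groups differently.
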