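---
title: "Optimising a DLLME method from designed experiments: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimising a DLLME method from designed experiments: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dllmeopt)
```

## The problem

Dispersive liquid–liquid microextraction concentrates trace volatiles from an
aqueous sample (here: wine) into a few hundred microlitres of organic phase.
Four coupled variables govern how well this works: the extraction solvent
type and volume, and the disperser solvent type and volume. The standard
study space is 5 extraction solvents × 5 extraction volumes (500–2000 µL) ×
3 disperser solvents × 3 disperser volumes (500–1500 µL), i.e. 225 candidate
conditions — too many to run in triplicate for 36 analytes. `dllmeopt`
implements the design-based alternative: run a D-optimal subset, model each
analyte's response, and interpolate back over the full grid to pick a
consensus optimum.

## The response-surface model

For each analyte the mean response (peak area, or optionally the
internal-standard area ratio) is modelled as

$$Y = b_0 + b_1X_1 + b_2X_2 + b_{22}X_2^2 + b_3X_3 + b_4X_4 + b_{44}X_4^2
      + b_{12}X_1X_2 + b_{34}X_3X_4 + b_{13}X_1X_3 + \varepsilon$$

with the interaction set restricted to the chemically plausible pairs:
solvent type × volume within each phase, and extraction solvent × disperser
solvent (whose miscibility governs dispersion).

**Coding.** Solvent types are treatment-coded against fixed references —
chloroform for the extraction solvent, acetone for the disperser — so each
non-reference level contributes one indicator column and the intercept is
the response at the reference solvents. Volumes enter in raw microlitres
(and squared microlitres for the quadratic terms), not centred or
standardised: coefficients then read directly as "area units per µL", which
is how practitioners quote them. The full model on the standard space has 25
columns (1 + 4 + 1 + 1 + 2 + 1 + 1 + 4 + 2 + 8).

Raw-µL coding makes the columns span seven orders of magnitude, so all
internal design comparisons use `log det(XᵀX)` and the exchange optimizer
works on column-scaled candidates (a fixed rescaling that cannot change
which design is optimal). `d_criterion()` still reports the raw determinant
for problems small enough to hold it.

## D-optimal design by Fedorov exchange

An exact n-run design is a multiset of candidate conditions maximising
det(XᵀX). `d_optimal_design()` uses the classical Fedorov exchange: from a
random nonsingular starting design, each run is considered against every
candidate point, the swap with the largest determinant ratio

$$\Delta_{ij} = d(x_j) - \left[d(x_i)d(x_j) - d(x_i,x_j)^2\right] - d(x_i)$$

is applied if it improves the criterion, and passes repeat until no exchange
helps. Because only improving swaps are accepted, the returned design's
criterion dominates every intermediate design. The search restarts from
`n_starts` (default 20) random designs under one top-level seed; ties are
broken first-found, making the result reproducible. Repetition of candidate
points is allowed, as usual for exact designs. The default budget is 60 runs
(in bench triplicate), comfortably above the 25 parameters and small enough
for a GC-MS campaign.

Alternatives (coordinate exchange, KL exchange, simulated annealing) were
not needed: on this 225-candidate grid a pass costs a 225 × 25 matrix
product and the optimizer converges in well under a second, and on toy
problems small enough to enumerate, the test suite verifies the exchange
result equals the exhaustive optimum.

## Backward elimination

After fitting the full model per analyte, terms are pruned iteratively: the
eligible term with the largest p-value ≥ α (default 0.05) is removed and the
model refitted, until all remaining terms are significant. Three deliberate
choices:

* **Whole-term partial F-tests.** A categorical solvent factor is one term
  with several dummy columns; it is tested (and removed) atomically via the
  partial F comparing the model with and without all its columns. For a
  single-column term this reduces to the squared t-test, which the suite
  checks.
* **Weak heredity, on by default.** A main effect is not removable while a
  retained interaction or quadratic involves its factor. The reduced models
  this produces keep main effects alongside their interactions, which is
  how such equations are conventionally reported; setting
  `heredity = FALSE` disables the protection.
* **One term per iteration**, not batch removal — removal changes the
  remaining p-values, so they are recomputed each step.

Non-detect rows are excluded from fits rather than imputed as zero: a failed
extraction (no cloudy dispersion) carries no information about the analyte's
abundance. If a solvent fails in every run, its indicator column is all zero
and the fit would be rank-deficient; `run_pipeline()` therefore restricts
the modelling and prediction space to solvent levels with detected data, and
rank deficiency in a direct `fit_model()` call is a named error, never
silent pivoting.

With noiseless inputs (the generator at `noise_cv = 0`) the residual sum of
squares is numerically zero and F ratios degenerate to 0/0; the p-value for
a term is then defined as 1 if removing it leaves the perfect fit intact and
0 otherwise, against a relative floor of 1e-9 of the response's total sum of
squares. This makes elimination on exact data behave as the limit of the
noisy case.

One statistical property worth knowing: with α = 0.05 and five truly inert
terms in the full model, the probability that elimination retains *exactly*
the true term set is roughly 0.95⁵ ≈ 0.77–0.85 per dataset (each inert term
survives with probability ≈ α). The test suite therefore checks term
recovery across a panel of 20 fixed seeds — the true terms must survive in
all of them, the exact set in the clear majority — rather than asserting a
single dataset's outcome.

## Prediction, ranking, consensus

Each reduced model is evaluated at all 225 conditions. Negative linear
predictions are physically meaningless for peak areas and are clamped to 0
with a flag (`predicted = max(raw, 0)` is asserted as an invariant).
Analytes with no detected observations anywhere are excluded from ranking
rather than contributing all-zero rows.

Two rankings are computed on the clamped grid:

* **Total area** — conditions sorted by the sum of predictions over
  analytes.
* **Top-m counts** — each analyte nominates its `top_m = 3` best conditions
  (competition ranking: conditions tied with the m-th best are all
  included, so a constant-prediction analyte nominates every condition);
  conditions are sorted by nomination count.

Both sorts break ties by the deterministic grid enumeration order
(extraction solvent slowest, disperser volume fastest). The consensus is the
condition with the best combined standing (sum of its two ranks) among
conditions present in both top-k lists; equal standings resolve toward the
smaller total solvent volume (X₂ + X₄) — an explicit waste/cost/toxicity
preference — then enumeration order. An empty intersection is an error that
directs the user back to the two rankings, not a silent fallback.

## Validation mathematics

* Calibration: least-squares line of area ratio on concentration; σ is the
  residual standard deviation on n − 2 degrees of freedom; r² is the
  coefficient of determination.
* LOD = 3.3 σ/S, LOQ = 10 σ/S, so LOQ/LOD = 10/3.3 identically — the suite
  checks the invariant and the round-trip `quantify(fit(noiseless line))`.
* Quantification qualifiers (`ok`, `below_LOQ`, `below_LOD`, `above_range`)
  instead of censoring, so downstream summaries can choose their own
  exclusion rule; summaries here exclude `below_LOD` and keep flagged
  `below_LOQ` values.
* Recovery R = (C₀ − C_b)/C_s × 100, evaluated on replicate means.
* RSD uses the sample (n − 1) standard deviation — n is small (six
  extractions). Intra-day RSD is the mean of within-day RSDs; inter-day RSD
  pools all measurements across days, the more conservative of the two
  conventions, since a day-mean shift inflates the pooled spread.

## The synthetic generator

Wet-lab responses are emulated, not replayed: the generator evaluates a
per-analyte ground-truth linear model at each condition and multiplies by
`(1 + ε)`, ε ~ N(0, CV²), truncated at zero. Multiplicative constant-CV
noise (default CV 5%) matches how precision is reported for this kind of
assay — as a relative standard deviation, here kept under the 10% bench
acceptance bound. Three structural features mirror the motivating study:

* **Deterministic pentane failure.** Pentane does not form a stable cloudy
  dispersion, so every pentane run is a non-detect — a categorical failure,
  not a probabilistic one.
* **Never-detected analytes.** Three analytes (trans-2-hexen-1-ol,
  β-citronellol, geraniol) fail under every solvent and are excluded from
  modelling.
* **A packaged exact truth.** `ethyl_octanoate_truth()` carries a fixed
  reduced-model coefficient set (intercept 58,296; solvent effects up to
  173,542; 36 area-units/µL volume slope; negative acetonitrile/methanol
  effects; solvent-specific volume slopes). At `noise_cv = 0` the generator
  is an exact evaluator of this equation, which anchors the package's
  strongest tests: OLS on the noiseless grid must return these coefficients
  to ≤ 1e-6 relative error.

The remaining 35 analytes get randomised truths (`default_ground_truths()`):
log-normal area scales around 5 × 10⁴, mostly unfavourable non-chloroform
solvent effects, a favourable acetonitrile effect, a positive volume slope
and small solvent-specific volume slopes. These defaults encode the
qualitative structure the method optimisation is meant to discover —
chloroform + acetonitrile + large extraction volume performing best — while
leaving every quantitative outcome to the seeded draw.

What the generator does **not** emulate: chromatographic reality
(co-elution, integration artifacts, retention drift), day effects beyond a
single CV, heteroscedasticity patterns other than constant CV, non-linear
calibration, and carry-over. Passing tests therefore demonstrate that the
statistical machinery is correct under its own assumptions, not that a
specific wet-lab method is optimal; with real bench data the pipeline is run
with `simulate = FALSE` and a measured response CSV.

Calibration series default to six strictly increasing levels in duplicate;
matrix studies spike at three levels (low/medium/high) in triplicate with a
per-matrix recovery factor drawn from 0.8–1.2, so the true recovery of a
synthetic study is the factor × 100 exactly at zero noise — an identity the
suite asserts.

## Determinism and seeds

One global seed drives everything. `run_pipeline()` derives per-stage child
seeds as `seed + 1000 × stage_index` (design = 1, simulation = 2,
calibration = 3, matrix study = 4), so any stage can be rerun in isolation;
the run log records all of them. Identical configuration and seed produce
byte-identical output CSVs, which the suite checks.

## Problem sizes in the test suite

Exhaustive-search cross-checks of the exchange optimizer use ≤ 5 candidate
points and 3-run designs (35 multisets); ranking oracles use grids of ≤ 6
conditions × 4 analytes; the random-design benchmark compares the 60-run
design against 1000 random designs; elimination calibration under a null
truth uses 1000 seeds of a 20-point single-slope model; LOD unbiasedness
uses 1000 simulated six-level duplicate curves. These sizes keep the full
suite under a minute while leaving the Monte Carlo error far below the
asserted tolerances.

## Known limitations

* Only D-optimality is implemented (no A-, I- or G-criteria, blocking or
  split-plot structure).
* OLS assumes homoscedastic errors; under the generator's multiplicative
  noise, high-mean conditions have larger absolute variance, which mildly
  miscalibrates F-tests for terms aligned with the mean structure. Weighted
  least squares would correct this but is not what method-development
  practice uses here.
* Rankings are point predictions; no uncertainty is propagated into the
  consensus choice.
* The replicate structure is fitted as raw observations (not replicate
  means); with equal replication both give the same coefficients, and raw
  observations keep residual degrees of freedom for the F-tests.
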