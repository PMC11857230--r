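# dllmeopt

Design-of-experiments optimisation and validation of dispersive liquid–liquid
microextraction (DLLME) methods for GC-MS analysis of volatile compounds, in
R.

DLLME extracts trace analytes (wine aroma compounds: esters, terpenes, C6
alcohols, fatty acids, volatile phenols, ...) from an aqueous sample into a
small volume of a water-immiscible extraction solvent, dispersed as fine
droplets by a water-miscible disperser solvent. Extraction efficiency depends
jointly on the extraction solvent type (X₁) and volume (X₂) and the disperser
solvent type (X₃) and volume (X₄); optimising them one at a time misses their
interactions. `dllmeopt` implements the complete multivariate workflow a
method-development chemist needs:

1. **D-optimal design** — from the full candidate grid of factor-level
   combinations, select an exact n-run design maximising det(XᵀX) of the
   response-surface model matrix by multi-start Fedorov exchange, so all main
   effects, quadratic volume terms and the relevant two-factor interactions
   are estimable from far fewer runs than the full factorial.
2. **Per-analyte response-surface regression** — ordinary least squares of
   peak area (or internal-standard area ratio) on

   Y = b₀ + b₁X₁ + b₂X₂ + b₂₂X₂² + b₃X₃ + b₄X₄ + b₄₄X₄² + b₁₂X₁X₂ + b₃₄X₃X₄ + b₁₃X₁X₃

   with treatment-coded solvent types and raw-µL volumes, followed by
   iterative backward elimination: the least significant whole term
   (partial-F p ≥ 0.05) is removed and the model refitted until only
   significant terms remain, under weak heredity.
3. **Full-grid prediction and consensus ranking** — each reduced model is
   interpolated over every factor-level combination (negative predictions
   clamped to 0), conditions are ranked both by total predicted peak area
   and by the number of analytes for which they are a top-3 performer, and
   the consensus optimum is the condition standing highest under both
   criteria (preferring less solvent on ties).
4. **Method-validation mathematics** — internal-standard calibration curves,
   LOD = 3.3 σ/S and LOQ = 10 σ/S, quantification with reporting qualifiers,
   spike recovery R = (C₀ − C_b)/C_s × 100, and intra-/inter-day precision
   (RSD).
5. **Synthetic GC-MS response generator** — ground-truth linear models with
   multiplicative constant-CV noise, deterministic non-detects for failing
   solvents, calibration series and paired spiked/unspiked matrix studies,
   so the entire pipeline is testable without instrument data.

## Worked example

```r
library(dllmeopt)

cfg <- pipeline_config(seed = 42)   # 60-run design, triplicates, 36 analytes
res <- run_pipeline(cfg)

res$design
#> D-optimal DLLME design: 60 runs x 3 replicates, log|X'X| = 199.181

res$reduced[["ethyl octanoate"]]
#> Response-surface fit: ethyl octanoate (n = 144, R^2 = 0.9814, sigma = 4190)
#> terms: ext_solvent, ext_volume, disp_solvent, ext_solvent:ext_volume
#>                                     coefficient   std_error
#> (Intercept)                        59455.332702 1553.603635
#> ext_volume_ul                         33.948729    1.011518
#> disp_solventacetonitrile          -29533.736813  861.072893
#> ...

head(res$by_total, 3)
#>   ext_solvent ext_volume_ul disp_solvent disp_volume_ul total_area rank
#> 1  chloroform          2000 acetonitrile           1500    3132304    1
#> 2  chloroform          2000 acetonitrile            500    3129652    2
#> 3  chloroform          2000 acetonitrile           1000    3123896    3

res$consensus
#>   ext_solvent ext_volume_ul disp_solvent disp_volume_ul rank_total rank_counts
#> 1  chloroform          2000 acetonitrile           1500          1           1
```

The simulated study is generated from per-analyte ground-truth models at 5%
measurement CV; pentane runs fail to form a cloudy dispersion and are
non-detects, so pentane is dropped from the modelling space. The reduced
ethyl octanoate model retains the extraction solvent, extraction volume,
disperser solvent and the solvent × volume interaction — the four
structurally significant terms — with coefficients close to the generating
truth (true intercept 58,296, true acetonitrile effect −29,513). Both
ranking criteria agree that 2 mL chloroform with acetonitrile extracts best;
the disperser volume barely matters once its terms are eliminated, and the
consensus rule resolves near-ties toward the leaner condition.

Validation outputs accompany the optimisation: six-level duplicate
calibration curves per analyte (e.g. hexanal: r² = 1.000, LOD 0.056 µg/L,
LOQ 0.170 µg/L, and LOQ/LOD = 10/3.3 by construction) and a matrix-effect
study whose mean recoveries estimate the generating matrix factor (factor
1.079 → recoveries 102–106% in the example above).

A thin command-line wrapper is included:

```sh
Rscript inst/scripts/run_dllme.R --seed 42 --out dllme_out
```

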