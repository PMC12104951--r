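# bowmetrics

Measurement of central Bowman's layer thickness (BT) from ultra-high axial
resolution corneal OCT, as a fully synthetic, end-to-end testable pipeline.

Bowman's layer is the thin (~8–25 µm) acellular collagen layer between the
corneal epithelium and stroma. Imaged with an OCT whose axial point-spread
FWHM is 1.7 µm in tissue (group index n_G = 1.387), its central thickness can
be measured to sub-micrometre repeatability and related to central corneal
thickness (CCT): across healthy (HC), keratoconus (KC) and corneal dystrophy
(CD) eyes, central BT is about 3 % of CCT, and the BT/CCT ratio is
independent of diagnosis, age, sex, keratometry and epithelial thickness.

The package implements the whole chain on synthetic data with known ground
truth:

- **Phantom simulation** — layered corneal B-scan stacks (bulk levels +
  impulse interfaces, Gaussian axial PSF, multiplicative speckle, per-frame
  axial jitter), plus cohorts with the reference three-group clinical
  structure and a calibrated within-group BT–CCT correlation.
- **Preprocessing** — low-signal frame screening, axial-only
  cross-correlation alignment (subpixel), and averaging.
- **Graph-search segmentation** — iterative minimum-cost path extraction
  (dynamic programming, step ≤ 2 px/column) on a signed vertical-gradient
  energy, with path blocking, ridge-centre subpixel refinement, a
  programmatic labelling policy standing in for the human supervisor, and
  1–5 quality grading.
- **Thickness** — optical→geometric conversion, quasi-point BT/ET over the
  centred 450 µm window, and quality-weighted per-eye aggregation
  (scores 3/4/5 → weights 1/2/3; scores < 3 excluded).
- **Cohort statistics** — group summaries, ANOVA with Tukey post hoc, the
  BT~CCT regression, and the BT/CCT ratio independence GLM.

The minimum-cost boundary, per column x with vertical step |Δz| ≤ 2, solves

    min_path Σ_x C(z(x), x),   C = normalized −∂I/∂z (dark→bright),

and BT is the windowed mean of (z_stroma − z_epi) · Δz_optical / n_G.

## Worked example

```r
library(bowmetrics)

# one capture with default noise, end to end
spec  <- phantom_spec(bowman_thickness_um = 15, seed = 8)
m     <- process_capture(spec, capture_id = "demo")
m$bt_um          # 15.015  (true value 15; geometric µm)
m$quality_score  # 4       (usable; weight 2 of 3)

# the full synthetic cohort (18 HC / 24 KC / 20 CD), a few minutes on 1 CPU
report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> Pipeline report (config 8cb4c7b8, seed 1)
#> 62 of 62 eyes analyzable
#>   HC: BT 15.53 (SD 1.79) um, n=18
#>   KC: BT 14.31 (SD 2.21) um, n=24
#>   CD: BT 15.75 (SD 2.08) um, n=20
#> BT~CCT: R^2 = 0.165 (p = 0.00104)
#> Pooled BT/CCT: 0.0285
```

The group means recover the configured ground truth (15.41 / 14.27 /
15.65 µm) within the sampling error of cohorts this size; the pooled BT–CCT
R² lands near the calibrated 0.18 target; and the pooled BT/CCT ratio is
~2.85 %, i.e. BT ≈ 3 % of CCT.

The `analysis/` directory holds the same workflow as numbered scripts:
`01_simulate.R` (generator calibration + cohort tables), `02_pipeline.R`
(imaging pipeline, writes `results/eyes.csv` and `results/report.json`),
`03_cohort_stats.R` (summary table, ANOVA/Tukey, regression, ratio GLM).

See `vignettes/bowmetrics-methods.Rmd` for the image model, the segmentation
energy and policy, all tunable parameters with defaults and rationale, and
known limitations of the phantoms.

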