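---
title: "Measuring Bowman's layer thickness on synthetic ultra-high-resolution corneal OCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring Bowman's layer thickness on synthetic ultra-high-resolution corneal OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Bowman's layer is a thin (roughly 8--25 µm) acellular collagen layer between
the corneal epithelium and stroma. Measuring its central thickness (BT) in
vivo requires an OCT with axial resolution well below the layer thickness and
an analysis chain that can localize two interfaces of very different
contrast: the epithelium--Bowman boundary (the epithelial basement membrane)
is consistently hyper-reflective and smooth, while the Bowman--stroma
boundary is dimmer and rougher. The quantity of clinical interest is the
*quasi-point* central BT --- the mean layer thickness over a short 450 µm
lateral segment, treated as a single central measurement --- and, at cohort
level, its relation to central corneal thickness (CCT): across healthy,
keratoconic and dystrophic corneas, central BT tracks CCT at about 3 % with
the ratio independent of diagnosis, age, sex, keratometry and epithelial
thickness.

Because no patient images can ship with the package, every stage is
exercised on synthetic captures whose ground truth is known exactly. The
generator is a first-class, tested module: conclusions about the analysis
chain are only as good as the realism of the phantoms, and the final section
is explicit about what the phantoms do not model.

## The image model

A capture is a stack of up to 50 B-scan frames of a layered anterior cornea.
Each frame is built as

1. an analytic reflectivity profile per lateral column: four bulk levels
   (background above the tear film, epithelium, Bowman's layer, stroma)
   separated by three impulse reflectors (tear-film surface,
   epithelium--Bowman, Bowman--stroma). The tear-film surface follows a
   circular sag of radius 7.8 mm (a typical cornea; near-flat over the 1 mm
   field) and deeper interfaces run parallel to it;
2. axial convolution with a Gaussian point-spread function. The PSF is
   specified as FWHM in geometric tissue micrometres (default 1.7 µm) and
   applied in optical-path units via the group refractive index
   $n_G = 1.387$, so bulk transitions become error functions and reflectors
   become Gaussian ridges. `measure_psf_fwhm()` closes the loop: imaging a
   single isolated reflector and measuring the profile width recovers
   1.72 µm, within half an axial pixel of the design value;
3. a rigid per-frame axial shift (subject/device motion), drawn as
   $N(0, \sigma_j^2)$ with $\sigma_j = 2$ px by default;
4. multiplicative speckle: i.i.d. Rayleigh draws smoothed to the PSF scale
   axially (and one pixel laterally), standardized to mean 1 and SD equal to
   the `speckle_contrast` knob (default 0.25).

Depth coordinates are optical-path micrometres throughout; all thicknesses
reported to the user are geometric (optical divided by $n_G$). Sampling is
0.5 µm optical per pixel axially --- chosen so the 1.7 µm tissue FWHM
(≈ 2.36 µm optical) spans ≈ 4.7 px and subpixel interpolation is meaningful
--- and 2 µm per pixel laterally over a 1000 µm field, wide enough to centre
the 450 µm window. Resolution is a property of the device being emulated;
sampling density and field width are not, so both are package choices.

Noise defaults were fixed by one calibration pass: speckle contrast 0.25 and
jitter SD 2 px are realistic for averaged clinical captures and keep the
full pipeline's re-capture repeatability (SD of BT over ten independent
captures of one phantom) comfortably inside the 0.3 µm figure reported for
the instrument this emulates; the acceptance suite re-measures this bound on
every run.

## Preprocessing

Frames below a signal threshold are screened out before anything else
(aligning empty frames is meaningless). A frame is kept when its signal
statistic --- the 99th-percentile intensity minus the frame median --- both
exceeds 3 × the frame's median absolute deviation (rejects flat or empty
frames) and reaches 25 % of the capture's median statistic (rejects strongly
attenuated frames, which are internally consistent and would pass any
scale-invariant test).

Alignment is axial-only by contract: each frame is collapsed to its
laterally averaged depth profile, and the shift maximizing the
cross-correlation against a running-average reference (seeded by the first
frame) is refined to subpixel precision by a parabolic fit around the
correlation peak. Integer shifts are recovered exactly up to a few
hundredths of a pixel; fractional shifts to well under a quarter pixel.
Averaging applies the negated shifts by linear interpolation and crops to
the rows where every frame has support, so the mean is unbiased (no
zero-padding). For independent speckle the residual variance falls as $1/n$.

## Graph-search segmentation

Boundary tracking is a minimum-cost path problem on the pixel graph: one
node per pixel, paths move strictly left to right with a vertical step of at
most 2 px per column. The transition cost is the negative signed vertical
gradient (central differences; one-sided at the image edges), min--max
normalized with a small floor so flat regions still cost something. Minimum
cost paths therefore hug dark-to-bright transitions. The dynamic program is
exact --- its cost matches an independent Dijkstra oracle on random
instances --- and runs in $O(\text{rows} \times \text{columns})$ per path.

Two numerical details matter for accuracy. First, the gradient of an
impulse-like reflector peaks about one PSF sigma *above* the ridge, so a
path found on the gradient rides the edge of the interface, not the
interface. Extracted paths are therefore refined per column to the centre of
the local intensity ridge (brightest pixel within ±5 px, then a parabolic
subpixel fit), which is where the reflector lies. Second, the step bound
(±2 px/column) and the blocking band (±3 px) are set relative to the PSF
width (4.7 px): adjacent interfaces ≈ 50 µm apart are never mutually
blocked, while duplicate detections of the same ridge are.

Interfaces are extracted iteratively: find the current minimum-cost path,
refine it, block an axial band around it, repeat. The human supervisor of
the original workflow is replaced by a deterministic labelling policy plus
configuration overrides: the shallowest strong path (≥ 50 % of the strongest
ridge brightness) is the tear film; the next strong path at least 15 µm
(geometric) deeper is the epithelium--Bowman interface; the Bowman--stroma
interface is the brightest path lying 5--25 µm (geometric) below it, with a
relaxed brightness floor (35 %) because that interface is genuinely dimmer
--- but not zero, otherwise any bulk path inside the window would be
accepted whenever the true interface is missing. Paths matching nothing stay
unassigned; a bright spurious reflection between interfaces is extracted and
simply never labelled. Supervisor-style overrides (`blocked_regions`,
`label_overrides`, `score_override`) steer both the search and the
refinement; blocked nodes are excluded from both.

Quality grading 1--5 is inherently subjective in the original workflow; the
package uses a monotone proxy: the residual high-frequency contrast of the
stromal region just below the deepest boundary, thresholded at
0.03/0.09/0.20/0.40 (fixed from a calibration sweep: noise-free captures
grade 5, single default-noise frames grade 3, heavy speckle 1--2), with one
grade deducted for rough paths. Failed segmentations are capped at 2. Since
scores only gate (< 3 excluded) and weight (3/4/5 → 1/2/3) downstream
averaging, any monotone proxy preserves the pipeline's semantics.

## Thickness extraction and aggregation

Per column, BT is the axial separation of the two deep boundaries times the
axial pixel pitch divided by $n_G$; the quasi-point value is its mean over
the centred 450 µm window, with the within-window SD reported as local
variability. Thickness is measured along the axial direction rather than
along the surface normal: over a 450 µm window on a 7.8 mm radius the
obliquity error is below 0.2 % (≈ 0.03 µm at 15 µm), an order of magnitude
under the measurement noise, and the curved-versus-flat comparison in the
test suite confirms the difference stays under 0.1 µm.

Repeated captures of an eye are combined either as a weighted mean (weights
1/2/3 for scores 3/4/5, the default) or by taking the single best-scoring
capture (ties broken by the smallest local SD). The original description
supports both readings; both are implemented and the mode is recorded in the
output. An eye whose captures all score below 3 is a failed eye and enters
the cohort table as excluded.

## Cohort simulation and statistics

The default cohort reproduces the reference clinical group structure: 18
healthy controls, 24 keratoconus, 20 corneal dystrophy, with group means for
BT, ET, CCT, Kmax and age. The reference summaries are internally
inconsistent in one place: the BT dispersions (0.49/0.43/0.64 µm) are far
too small to be SDs given the reported min--max ranges several micrometres
wide, so the default reads them as standard errors and scales by $\sqrt{n}$
(giving
within-group SDs of 2.08/2.11/2.86 µm, consistent with the ranges); the
literal-SD reading remains available via
`default_group_params(bt_dispersion = "sd")`. The other columns'
parentheticals are plausible SDs and are used as printed.

True BT is drawn jointly with CCT through a within-group correlation shared
across groups. Only the pooled coefficient of determination of the BT~CCT
regression (0.18) is available as a reference value, so the correlation was
calibrated once by
bisection with common random numbers (`calibrate_bt_cct_corr()`, 10⁴
subjects per evaluation, group sizes scaled proportionally), giving the
frozen default 0.364. Note the pooled $R^2$ at the study's own size
($n = 62$) is a noisy estimator: a delta-method approximation gives
$\mathrm{SD}(R^2) \approx 2\rho(1-\rho^2)/\sqrt{n} \approx 0.09$, so
single-cohort values between roughly 0.04 and 0.32 are unremarkable; the
acceptance check uses exactly that band.

The statistics mirror standard practice: per-group mean/SD/min/max
summaries with ratio columns recomputed from their parts; one-way ANOVA
with Tukey HSD for group comparisons; ordinary least squares for BT on CCT;
and a general linear model of the BT/CCT ratio on diagnosis, age, sex, Kmax
and ET with marginal F tests per factor. With one observation per eye and no
repeated measures there is nothing for a random effect to absorb, so sex and
diagnosis both enter as fixed effects. For multiplicity, Tukey covers the
pairwise family and a Holm option is provided for the GLM factor family,
with raw and adjusted p-values both reported. A constant ratio (zero residual variance) makes the
marginal F tests 0/0; the implementation returns p = 1 for that degenerate
case, since a constant depends on nothing.

## Determinism and problem sizes

One master seed fans out to named substreams (cohort draws, each capture,
each repeatability re-capture) via a 32-bit hash, so any stage can be re-run
independently and an identical config + seed reproduces every output byte
for byte; reports carry a content hash of the configuration that produced
them.

Default problem sizes: 480 × 500 px frames (240 µm optical × 1000 µm), 8
frames per capture, 3 captures per eye, 62 eyes --- a full cohort runs in a
few minutes on one CPU. Eight frames rather than the instrument's maximum of
50 is a deliberate study-condition choice: with 8-frame averaging the
pipeline already sits far inside the repeatability bound the acceptance
suite checks, and the $1/n$ averaging law is verified separately at 50
frames. Unit tests use 320 × 250 px phantoms (the smallest field that still
holds the 450 µm window).

## What the phantoms do not model

The generator targets image statistics, not instrument physics: no
interferometry, dispersion or spectrometer model, and a single group index
for all layers (only one is published). Speckle is smoothed multiplicative
Rayleigh noise --- a reasonable stand-in, but real speckle is
signal-correlated interference. Corneal scarring, the dominant cause of
segmentation failure in keratoconic eyes in practice, is represented only by
an optional local contrast-degradation knob; the package's near-zero failure
rate on default phantoms therefore says nothing about clinical failure
rates, and the published reliability percentages are out of scope. Kmax is
carried as a covariate only and is not re-derived from phantom geometry.
Passing tests demonstrate that the analysis chain is correct and
self-consistent under a known image model, not that it would perform
identically on clinical captures.
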