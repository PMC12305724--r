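---
title: "Methods: FT-NIR calibration of carrot anthocyanins with anthoNIR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FT-NIR calibration of carrot anthocyanins with anthoNIR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anthoNIR)
```

## The problem

Anthocyanin-rich purple carrots are bred as a source of acylated cyanidin
pigments for natural food colorants. The reference assay (UPLC-MS/MS on
extracted root powder) is accurate but destructive and slow; FT-NIR spectra
of the same freeze-dried powder, recorded in triplicate over
3594–12489.7 cm⁻¹, can be calibrated against the reference panel to predict
ten responses: total anthocyanins (ACN), total acylated anthocyanins (AcA),
total phenolic acids (PHEN), the five individual cyanidin glycosides
(Cy3XSGG, Cy3XFGG, Cy3XCGG, Cy3XG, Cy3XGG), chlorogenic acid (3CQA) and
caffeic acid (CA), all in µg/100 g dry weight. `anthoNIR` implements the
calibration/validation machinery, the downstream composition and colour
statistics, and a synthetic-data module that stands in for the instrument
and the reference assay.

## Calibration model and assumptions

Each analyte gets a single-response PLS regression (PLS1, NIPALS) on
preprocessed spectra. The model assumes the preprocessed absorbance is
linear in the constituent concentrations (Beer–Lambert mixing), with
scatter effects removed by the preprocessing chain, and that the relevant
chemical signal lives in a low-dimensional latent subspace. NIPALS extracts
that subspace one component at a time; for a univariate response each
component converges in a single pass, but the iteration loop is kept with a
score-change tolerance of 1e-12 (cap 500 iterations) for robustness.
Components stop early when the residual covariance `X'y` is numerically
zero, with the achieved rank reported; regression coefficients are
available for every nested rank, which makes the cross-validated rank
search a single fit per fold.

Rank selection minimises RMSECV over ranks 1..10 (`max_rank`, configurable;
the vendor software's stopping criterion is unpublished, and 10 comfortably
exceeds the latent dimension of both the simulated mixtures and typical
powder spectra), breaking ties toward the smaller rank.

## Preprocessing chains

Each analyte's chain is fixed to its reported operator set and
analyte-correlated wavenumber windows (closed intervals, cm⁻¹): SNV with
the anthocyanin windows for the totals and most pigments, first derivative
+ vector normalisation for Cy3XFGG, first derivative + MSC for Total_PHEN,
first derivative + SNV for 3CQA and CA. Operator order is not stated by the
source workflow and is fixed here as derivative → scatter correction →
window restriction: the derivative must see a contiguous grid, and window
masks must index the same grid at calibration and prediction time. The
Savitzky–Golay derivative defaults to window 17, polynomial order 2 — wide
enough to suppress white noise at 7.7 cm⁻¹ spacing without eroding the
~100–200 cm⁻¹ analyte bands — and extends its polynomial fit to the edges
so the output length (and window alignment) is preserved. Whether SNV was
originally applied before or after window restriction is likewise unstated;
applying it before (full-grid statistics) is the choice here. All
data-dependent statistics (MSC reference spectrum, window mask) are frozen
at fit time and reused verbatim at prediction time; prediction-set
statistics are never used.

## Validation conventions

* `R² = 1 − SSres/SStot` on out-of-fold (or external) prediction pairs —
  not squared Pearson correlation.
* RMSECV/RMSEP use the `n` denominator; the reference SD in
  `RPD = SD(y)/RMSE` uses `n − 1`. Consequently
  `RPD² = (n/(n−1)) / (1 − R²)` exactly under these conventions, an
  identity the test suite asserts. Published R²/RPD pairs from vendor
  software need not satisfy it, since that software's conventions are not
  documented; this package documents its own instead of guessing.
* Bias is `mean(predicted − true)`; positive means overestimation.
* Folds are assigned to samples, not scans, so triplicate spectra of one
  sample never straddle a fold boundary (anything else leaks replicate
  correlation into the CV error). Samples are ordered by mean response and
  fold labels shuffled within consecutive blocks of `k`, seeded: every fold
  spans the concentration range, and the assignment is deterministic given
  the seed and invariant to scan order.
* External validation fits on a calibration set and evaluates on a
  disjoint sample set (default 50/100 samples, in triplicate), refusing
  overlapping sample ids.

## What the synthetic cohort emulates

The generator's defaults encode the study conditions: 461 samples in seven
binary root-colour phenotype groups (165 purple in at least one tissue,
296 non-purple), with group means anchored at the published summaries —
fully purple roots (`:1111`, n = 60) averaging 1799.7 µg/100 g dw total ACN
with a 69.5 % mean degree of acylation, purple-periderm-only roots
(`:1000`) at 94.6 % acylation, phenolic acids ranging from 69 (`:1000`) to
308.2 (`:1101`) µg/100 g dw, and non-purple roots at trace ACN
(0.5 µg/100 g dw). Group means and sizes not individually published are
interpolated between those anchors in proportion to tissue pigmentation.

Distributional forms are the package's own choices, since none are
published:

* **Totals** are log-normal per group, parameterised so the configured
  value is the exact expected mean; log-scale SDs (0.65 for ACN in purple
  groups, 0.8 in non-purple, 0.45 for PHEN) are set from the published
  within-group ranges.
* **Composition** is hierarchical: total cyanidin splits into
  acylated/non-acylated mass by a Beta draw (group-specific mean,
  concentration 12), the acylated mass by a Dirichlet draw over
  (Cy3XSGG, Cy3XFGG, Cy3XCGG), and the non-acylated mass between Cy3XG and
  Cy3XGG by a second Beta draw. The Dirichlet and Beta concentrations
  (α = (1.00, 0.95, 0.05), κ = 1.5) were tuned once, with the shipped
  seeded script `scripts/calibrate_generator.R`, so that the published
  cohort-level correlation structure *emerges* rather than being imposed:
  a strongly negative correlation between %Cy3XG and the degree of
  acylation (≈ −0.9) and a negative correlation between %Cy3XFGG and
  %Cy3XSGG (≈ −0.8, the two acyl donors competing for the same substrate).
* **PHEN–ACN coupling** uses one shared latent factor per sample with
  loading 0.37 on the log scale, calibrated (60-seed Monte-Carlo) to give
  the published moderate correlations between total phenolic acids and
  total anthocyanins (≈ 0.45 cohort-wide, ≈ 0.49 among purple samples).
* **Detection floor**: pigment draws below 0.05 µg/100 g dw are recorded
  as 0, mimicking below-detection trace analytes in non-purple roots;
  totals are recomputed from the floored components so `Total_ACN` is
  always the exact sum of the five glycosides.

Spectra follow a Beer–Lambert forward model on a 3594–12489.7 cm⁻¹ grid at
7.7 cm⁻¹ spacing (1156 points; the instrument defines only the scan range
and a 16 cm⁻¹ optical resolution, so the digitisation step is a free,
configurable choice). Each of the eight mixture components (five pigments,
3CQA, CA, and a PHEN_other component carrying the minor phenolic acids so
that Total_PHEN is fully spectrally active) contributes 2–4 Gaussian bands
centred inside its reported analyte-correlated windows; a shared
water/carbohydrate matrix background, roughly ten times the typical analyte
signal, is common to all samples with a 2 % log-normal per-sample amplitude
jitter. Replicate scans differ only by scatter/noise draws: multiplicative
slope 1 ± 0.05, additive baseline offset 0.02 ± 0.01 absorbance with a
linear tilt (SD 3e-7 per cm⁻¹), and white noise of SD 1e-3 absorbance —
magnitudes typical of benchtop FT-NIR drift from temperature and humidity.
Negative absorbances after these draws are clipped to zero and counted.

Steeping extracts are simulated per sample with per-analyte extraction
efficiencies anchored at the published fully-purple values (Cy3XGG 98 %,
Cy3XFGG 82.3 %, Cy3XSGG 79 %, Cy3XCGG 78 %), Gaussian spread 6 points,
clipped to [0, 110] %. The A520 − A700 signal is linear in extracted
pigment with Cy3XSGG the strongest chromophore per unit concentration;
A420 adds a pigment-independent browning term, and A700 models haze. The
response coefficients were set so a default fully-purple cohort reaches
colour densities of the published order (tens of absorbance-sum units).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: no radiative-transfer physics of diffuse
reflectance (particle-size effects enter only as the affine scatter SNV/MSC
can remove), no wavelength-dependent noise or detector artefacts, no
instrument drift between calibration and prediction sessions, no
chromatographic co-elution or recovery error in the reference values, and
Gaussian bands instead of true NIR overtone band shapes. Accuracy figures
on synthetic spectra therefore demonstrate that the pipeline is correct and
can reach the published accuracy regime under its stated noise model, not
that any particular instrument will.

## Numerical choices and degenerate inputs

* SNV rejects constant spectra; MSC rejects a constant reference and
  near-zero regression slopes (|slope| < 1e-12), naming the spectrum.
* Window bounds are closed intervals; selections retaining zero grid
  points are errors.
* Rank-0 PLS is an explicit error (the mean-only model is `mean(y)`; hiding
  it behind rank 0 invites off-by-one mistakes in rank search).
* `rpd()` returns `Inf` (not an error) for RMSE = 0, so perfect noiseless
  fits remain representable.
* Hue is NA when A420 = A700; degree of acylation is NA when both pools
  are zero; composition percentages are NA below a configurable total-ACN
  detection floor (default 1 µg/100 g dw) and excluded from correlations.
* Model files store doubles with 17 significant digits, so a save → load →
  predict round trip is bitwise identical.
* All generators restore the caller's RNG state; every stochastic output
  is a pure function of its parameters and seed.

In the noiseless limit (all scatter and noise spreads zero) the forward
model is exactly linear, and the PLS core must cross-validate every analyte
to R² = 1 at machine precision. That invariant is tested with the
window/derivative-only chain variants (`linear_chains()`): SNV, MSC and
vector normalisation are per-spectrum *nonlinear* maps (they divide by a
spectrum-dependent scale), so with the full default chains the noiseless
limit is almost, but not exactly, linear — those operators pay a small
linearity cost in exchange for removing the multiplicative scatter that
dominates real measurements. The pipeline-level noise-free check (R² ≥
0.999 for all ten analytes) uses the same linear chains for the same
reason.

## Problem sizes

The default study configuration is 160 purple samples × 3 replicate scans
× 1156 channels with 5-fold grouped CV and a rank search to 10; a full
ten-analyte pipeline run takes a few seconds on one core. The test suite
scales routine runs down (e.g. 40 × 2 scans) and reserves the full
configuration for the end-to-end accuracy checks; cohort-level statistics
are averaged over 10–20 seeded replicate cohorts to keep Monte-Carlo error
well inside the tolerances being asserted.

## Known limitations

* One model per analyte (PLS1); no multi-response PLS2, and no PLS-DA
  classification of phenotypes.
* No automated wavelength/window search: the reported windows are taken as
  fixed defaults rather than re-optimised.
* Group summaries plus plain correlations replace post-hoc multiple
  comparison letters; correlation p-values are unadjusted by default (a
  Benjamini–Hochberg adjustment can be applied by the caller via
  `p.adjust`).
* The S.H.E evenness convention is `E = H/ln S` in natural logs; published
  evenness figures using other conventions are not directly comparable.
* JCAMP-DX support covers AFFN `XYDATA=(X++(Y..Y))` and `XYPOINTS`
  tables — the dialects needed for plain-text interchange — not packed
  (SQZ/DIF) compression or proprietary binary spectra.
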