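---
title: "Voxel-wise modelling of LET-dependent salivary gland response on PSMA-PET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxel-wise modelling of LET-dependent salivary gland response on PSMA-PET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psmalet)
```

## The scientific problem

Proton therapy is planned with a constant relative biological
effectiveness (RBE) of 1.1, but radiobiology predicts that RBE rises with
the dose-weighted linear energy transfer (LET~d~), i.e. toward the distal
end of the proton range. PSMA-PET visualizes the density of secretory
(acinar) cells in salivary glands, and its uptake drops in regions that
received high radiation dose. Each PET voxel of a parotid or
submandibular gland therefore provides a continuous, spatially resolved
damage readout, and a patient contributes thousands of voxels in which
physical dose and LET~d~ vary partly independently. This package
implements the voxel-wise analysis that exploits this: relating
post-treatment uptake loss to dose *and* LET~d~, per patient, and
aggregating the LET dependence across patients.

## The response model

For a voxel with baseline uptake $\mathrm{PSMA}_0$, physical dose $D$
(Gy) and $\mathrm{LET}_d$ (keV/µm), the follow-up uptake is modelled as

$$\mathrm{PSMA}_{FU} = \mathrm{PSMA}_0\,\beta_0 \exp\!\big(-\beta_1 D\,(1 + \beta_2\,\mathrm{LET}_d)\big).$$

* $\beta_0$ (dimensionless) absorbs dose-independent global changes of
  uptake between scans (scanner calibration, tracer kinetics, systemic
  response).
* $\beta_1$ (Gy⁻¹) is the voxel-wise radiosensitivity of uptake.
* $\beta_2$ ((keV/µm)⁻¹) scales dose by an LET-dependent factor; the fit
  implies the linear RBE model $\mathrm{RBE} = 1 + \beta_2\,\mathrm{LET}_d$
  with the intercept fixed at 1 (`rbe_model()`, `rbe_at_let()`).

Voxel tables store $D$ and the exported product $D\cdot\mathrm{LET}_d$;
LET~d~ is derived on access, with LET~d~ ≔ 0 for zero-dose voxels (they
contribute no dose term, and the ratio would be 0/0). Predictions are not
clipped at the baseline: $\beta_0 > 1$ is allowed by the bounds.

Only the linear RBE–LET form is implemented; nonlinear forms are out of
scope.

## ROI adjustment

Gland delineations drawn on a planning CT do not coincide exactly with
the PET uptake volume. The pipeline therefore adjusts each ROI to *the
voxels whose centers lie within 6 mm (Euclidean, on the grid) of the
original delineation and whose baseline uptake is at least 5.0 SUV*
(`adjust_roi()`). Two interpretation choices are deliberate and
documented here because the rule can be read in more than one way:

* "within 6 mm" is measured from voxel center to the nearest voxel
  center of the original delineation (distance-transform semantics,
  implemented as dilation with a Euclidean ball); no partial-volume
  weighting.
* the SUV threshold applies to *all* candidate voxels, including those
  inside the original delineation, so low-uptake interior voxels are
  excluded too.

The adjusted ROI is non-shrinking in the margin and non-growing in the
threshold; both properties are tested. Deformable registration is out of
scope: volumes must arrive co-registered (the phantom cohort is generated
aligned, and externally resampled volumes are accepted as-is).

## Fitting

Each patient and gland set (parotid, submandibular, or combined) is
fitted individually by minimizing the voxel-wise sum of squared residuals
with a bounded generalized simulated-annealing optimizer
(`fit_gland_set()`, `dual_anneal()`): Tsallis visiting distribution
(shape 2.62), fast cooling from an initial temperature of 5230, chain
restarts once the temperature ratio falls below 2×10⁻⁴, and bounded
local polish (`nlminb`) of each restart cycle's best point. Internally
the optimizer works on the unit cube so that step sizes and polish
tolerances are comparable across parameters whose natural scales differ
by four orders of magnitude. The iteration cap defaults to 10 000; fits
are bit-reproducible given records, configuration and seed.

Choices a user should know about:

* **Loss.** The default is squared error on absolute follow-up uptake
  (`sse_followup`); `sse_relative` divides residuals by the baseline
  first so high-uptake voxels do not dominate. The model's native scale
  is absolute uptake, hence the default; both options are available
  because the choice is not dictated by the model.
* **Bounds.** $\beta_0 \in [0.05, 2]$, $\beta_1 \in [-5, 5]\times10^{-3}$
  Gy⁻¹, $\beta_2 \in [-2, 2]$ (keV/µm)⁻¹ — wide enough to contain every
  estimate a salivary-gland cohort plausibly produces (including negative
  $\beta_1$ and a strongly negative $\beta_2$) with ample margin. The
  optimizer requires finite bounds; these are design choices, not
  physical constraints.
* **Identifiability guards.** If all selected voxels share one
  (dose, LET~d~) point the design is degenerate and fitting errors out.
  If LET~d~ is constant across voxels, $\beta_2$ drops out of the model:
  the fit proceeds, but the result is flagged
  (`beta2_identifiable = FALSE`) with a warning, and only the composite
  $\beta_1(1 + \beta_2\overline{\mathrm{LET}_d})$ is determined.
* **Oracle.** `grid_search_oracle()` evaluates the objective exhaustively
  on a regular 3-D grid over the bounds; the test suite requires the
  annealing fit never to lose to the grid argmin and to land within one
  grid cell of it.

### What the data can and cannot identify

On the log scale the model is linear:
$\log(\mathrm{PSMA}_{FU}/\mathrm{PSMA}_0) = \log\beta_0 - \beta_1 D - \beta_1\beta_2\,D\,\mathrm{LET}_d$.
Two structural facts follow, and they shape everything downstream:

1. $D$ and $D\cdot\mathrm{LET}_d$ are strongly collinear whenever LET~d~
   varies little around its mean (correlations above 0.95 are typical),
   so the information about $\beta_2$ is a small residual signal.
2. $\beta_2 = (\beta_1\beta_2)/\beta_1$ is a ratio estimate whose
   precision is proportional to $\beta_1$. At the radiosensitivity scale
   these fits produce ($\beta_1 \approx 10^{-4}$ Gy⁻¹, i.e. a ≈1 %
   uptake change across the full dose range), 5 % voxel noise and a few
   thousand voxels per patient yield a per-patient $\beta_2$ standard
   error of order 0.05–0.15 — comparable to the effect being sought.
   This is not an optimizer limitation: the efficient log-scale OLS
   estimator (used as an independent oracle in the tests) shows the same
   scatter, and the test suite documents it honestly rather than
   asserting precision the data cannot support. The wide spread of
   published per-patient slopes is exactly what this analysis predicts.

A second, related pathology is a *mirror basin*: $\beta_1 < 0$ combined
with $1 + \beta_2\,\mathrm{LET}_d < 0$ also produces net uptake decay.
The basins are not exact reparametrizations, so the global optimizer can
and does rank them; but in weakly identified fits the mirrored minimum
can be globally best, parking $\beta_2$ near a bound. The multistart
(restart-cycle) polish exists largely to rank these basins reliably.

## Population aggregation

Per-patient slopes are combined by `aggregate_slopes()`: the arithmetic
mean with a Student-t 95 % interval
($\bar\beta_2 \pm t_{0.975,n-1}\,s/\sqrt{n}$) by default, or a seeded
percentile bootstrap. Both are labelled in the output because the CI
method used for the published interval is not stated and its printed
interval is not reproducible from the printed slopes; the package
therefore treats the mean slope and the positive-slope counts — not the
CI — as reference quantities. Positive-slope counting is strict
($\beta_2 > 0$) by default, so a slope printed as exactly 0.000 does not
count as positive; `strict = FALSE` is available.

## Binned summaries

`bin_uptake_by_dose()` profiles mean follow-up uptake in 2.5 Gy dose
intervals; `bin_relative_uptake_2d()` maps mean relative uptake
(follow-up / baseline) over 5.0 Gy × 25 Gy·keV/µm bins of dose and
D·LET~d~. Bins are left-closed right-open with origin 0 (the bin origin
is a design choice; no edge convention is inherited). The 2-D summary
can exclude the *union* of the lowest dose column and the lowest
D·LET~d~ row — these voxels are non-informative for an LET effect — and
reports the excluded voxel fraction so the choice can be audited; with a
mixed-gland dose distribution this fraction lands around a fifth to a
third of the voxels. Empty bins are retained with count 0 so point-size
plots show the full axes. Mass conservation (kept + excluded = total)
and refinement consistency (halved bins aggregate back exactly) are
tested invariants.

## The phantom generator

No imaging data is distributed with the analysis, so the
`synthetic_data` layer generates phantom cohorts with known ground truth
(`phantom_spec()`, `generate_phantom()`, `make_patient_cohort()`):

* **Grid.** 64×64×48 voxels at 2 mm isotropic spacing — the analysis
  grid resolution at desk scale.
* **Glands.** Two parotid and two submandibular ellipsoids (≈2600 and
  ≈700 voxels each); real gland shapes are irrelevant to the statistics
  being exercised.
* **Dose.** A parametric beam model: plateau dose (default 70 Gy, the
  prescription level) proximal to a sigmoid distal fall-off, Gaussian
  lateral profile. The distal edge crosses one parotid, so within-gland
  dose spans from under 5 Gy to over 60 Gy.
* **LET~d~.** Baseline 1 keV/µm plus an enhancement of up to 6 keV/µm
  placed just beyond the distal dose fall-off — the physically typical
  pattern — plus a small smooth texture. Within each gland the
  dose–LET~d~ Pearson correlation is steered to a configurable target
  (default −0.3, the physically expected sign) by blending the
  standardized dose with the dose-orthogonalized LET pattern and
  rescaling affinely into [baseline, baseline + enhancement]; because
  the rescale is affine, the target correlation is achieved exactly.
* **Baseline uptake.** A smooth heterogeneous field (mean 10 SUV,
  SD 2 SUV) inside glands over a low background (2 SUV); when a target
  fraction of voxels ≥ 5 SUV is configured, the field location is
  calibrated against the empirical within-gland quantile so the achieved
  fraction matches exactly.
* **Noise.** Follow-up uptake is the model prediction times
  $e^\varepsilon$, $\varepsilon \sim N(0, \sigma^2)$ i.i.d. per voxel
  (default $\sigma = 0.05$) — multiplicative lognormal because PET
  uptake is positive and heteroscedastic. Additive Gaussian noise exists
  as an option but is off by default.
* `simulate_voxel_records()` is a flat (grid-free) companion for
  statistical experiments; for a fixed seed its draws are identical
  across correlation settings, so comparisons across collinearity levels
  are paired.

What the phantom does *not* emulate: Monte Carlo transport, realistic
beam arrangements, PET reconstruction and partial-volume effects,
registration error, tracer kinetics, and intra-gland functional
subregions (e.g. the stem-cell-rich region). Passing tests on phantoms
therefore demonstrate the *pipeline's* correctness and the *statistical*
behaviour of the estimator under known truth — not that the model is an
adequate description of real glands.

## Problem sizes and numerical choices used by the test suite

* Noise-free recovery uses one full 3-D phantom (~6600 adjusted-ROI
  voxels) and a 4000-voxel flat cohort; recovered parameters must match
  the generator truth within (±0.01, ±10⁻⁵ Gy⁻¹, ±0.02).
* The noisy-recovery suite uses 20 patients × 6600 voxels at 5 % noise,
  matching the realistic per-patient scale discussed above.
* The identifiability experiment uses correlation levels 0, 0.6 and
  0.95 with 150 paired seeds per level, 1500 voxels per fit and 1 %
  noise — low noise so that the collinearity-driven error growth is the
  dominant term being measured.
* The grid oracle runs at 21³–41³ nodes on 400–1000-voxel fixtures.
* Annealing in tests runs at 500–5000 iterations (with the same polish
  machinery as the 10 000-iteration default) — the optimizer equals its
  own global optimum long before the default cap on these fixture sizes.

## Known limitations

* The per-patient $\beta_2$ is weakly identified at realistic noise and
  voxel counts (see above); population-level conclusions inherit that
  scatter. This mirrors the wide per-gland-set variation in the
  published per-patient estimates.
* The confidence interval of the population slope depends on the CI
  method, and with n = 6 patients the t-interval is fragile to single
  patients.
* The ROI rule's two ambiguities (distance metric, treatment of
  low-uptake interior voxels) are resolved by documented choices; other
  readings would change voxel counts slightly.
* The phantom's LET field is constructed per gland (each gland spans the
  full LET range); absolute LET distributions in real plans differ, so
  phantom-based identifiability results are indicative, not predictive,
  for a specific clinical plan.
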