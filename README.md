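# psmalet

Voxel-wise modelling of LET-dependent salivary gland response on
PSMA-PET after proton therapy.

## The problem

Proton therapy is planned with a constant relative biological
effectiveness (RBE) of 1.1, but RBE is expected to rise with the
dose-weighted linear energy transfer (LET_d) toward the end of the
proton range. PSMA-PET uptake in parotid and submandibular glands
reflects secretory-cell density, so the per-voxel uptake loss between a
baseline and a post-treatment scan is a continuous, spatially resolved
readout of radiation damage — thousands of data points per patient in
which dose and LET_d vary partly independently. This package is for
researchers who want to estimate the RBE–LET_d dependence from such
voxel data, and to understand — via simulation with known ground truth —
what such an analysis can and cannot identify.

## The model

Per voxel, with baseline uptake `PSMA_0`, physical dose `D` (Gy) and
`LET_d` (keV/um):

    PSMA_FU = PSMA_0 * beta0 * exp(-beta1 * D * (1 + beta2 * LET_d))

`beta0` absorbs dose-independent uptake changes, `beta1` (Gy^-1) is the
radiosensitivity, and `beta2` ((keV/um)^-1) is the RBE–LET slope,
implying the linear RBE model `RBE = 1 + beta2 * LET_d`. Fits are per
patient and gland set (parotid / submandibular / combined), by bounded
generalized simulated annealing (10 000 iterations, seeded, with local
polish), and per-patient slopes are aggregated into a population mean
with a 95 % confidence interval.

The pipeline around the model: ROI adjustment (voxels within 6 mm of the
delineation with baseline uptake >= 5.0 SUV), voxel-table extraction
(TSV), binned summaries (2.5 Gy dose profiles; 5.0 Gy x 25 Gy keV/um
relative-uptake maps with lowest-margin exclusion), NIfTI volume I/O,
and a synthetic phantom cohort generator with known ground truth.

## Worked example

```r
library(psmalet)

# Published per-patient combined-gland slopes at one month
slopes <- reference_slopes("combined", "one_month")
s <- aggregate_slopes(slopes, ci_method = "t_interval")
s
#> <slope_summary> n = 6 patients
#>   mean RBE-LET slope = 0.0745 (keV/um)^-1, 95 % CI [-0.02734; 0.1763] (t_interval)
#>   patients with positive slope: 4

count_positive_slopes(reference_slopes("parotid", "one_month"))        # 2
count_positive_slopes(reference_slopes("submandibular", "one_month"))  # 5

# End-to-end on one synthetic patient with known truth
spec <- phantom_spec(noise_sigma = 0, seed = 42L,
                     true_params = fit_parameters(0.8, 1.5e-4, 0.075))
ph  <- generate_phantom(spec)
fu  <- simulate_followup(ph$baseline, ph$dose, ph$dose_let,
                         spec$true_params, noise_sigma = 0)
rec <- phantom_voxel_table(ph, fu, patient_id = "P01")
fit <- fit_gland_set(rec, "combined", fit_config(seed = 7L))
fit
#> <fit_parameters> combined / one_month / P01
#>   beta0 = 0.8, beta1 = 0.00015 Gy^-1, beta2 = 0.075 (keV/um)^-1
#>   objective (SSE) = 1.25821e-19, seed = 7
```

The mean slope 0.0745 prints as 0.075 at three decimals; the noise-free
phantom fit recovers the generator truth (0.8, 1.5e-4, 0.075) to
optimizer precision. With realistic 5 % voxel noise the per-patient
`beta2` is far less certain — the vignette
(`vignettes/voxelwise-let-response.Rmd`) explains why, and the test
suite measures it.

## The analysis workflow

`analysis/01_simulate.R` … `05_summarize.R` run the full study on a
six-patient phantom cohort whose ground-truth parameters are the
published per-patient estimates: simulate volumes (NIfTI), adjust ROIs
and extract voxel tables, fit all gland sets per patient, aggregate
slopes, and write the binned summaries — all outputs under `results/`.

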