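# The phantom generator is tested on a reduced grid where geometry allows,
# and on the default grid where the contract concerns the defaults.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(40L, 40L, 32L),
               glands = tibble::tibble(
                 gland = c("parotid_L", "submandibular_L"),
                 cx = c(22, 50), cy = c(40, 36), cz = c(32, 20),
                 rx = c(12, 8), ry = c(14, 9), rz = c(14, 8)),
               beams = list(list(axis = "x", direction = -1, edge_mm = 16,
                                 falloff_mm = 3, plateau_gy = 70,
                                 lateral_sigma_mm = 30,
                                 lateral_center_mm = c(40, 28))),
               ...)
}

test_that("zero LET enhancement gives a constant LET_d field", {
  ph <- generate_phantom(small_spec(let_enhancement = 0, seed = 3L))
  pos <- ph$dose > 0
  letd <- ph$dose_let[pos] / ph$dose[pos]
  expect_equal(range(letd), c(1, 1))
})

test_that("zero plateau dose gives identically zero dose and D*LET_d", {
  sp <- small_spec(seed = 3L)
  sp$beams[[1]]$plateau_gy <- 0
  ph <- generate_phantom(sp)
  expect_true(all(ph$dose == 0))
  expect_true(all(ph$dose_let == 0))
})

test_that("default phantom spans the contracted dose and LET_d ranges", {
  ph <- generate_phantom(phantom_spec(seed = 42L))
  gm <- ph$mask > 0
  d <- ph$dose[gm]
  expect_lte(min(d), 5)
  expect_gte(max(d), 60)
  letd <- ph$dose_let[gm] / ph$dose[gm]
  expect_lte(min(letd), 1 + 1e-6)
  expect_gte(max(letd), 6)
  # LET_d bounded by baseline and baseline + enhancement wherever dose > 0
  pos <- ph$dose > 0
  all_letd <- ph$dose_let[pos] / ph$dose[pos]
  expect_gte(min(all_letd), 1 - 1e-9)
  expect_lte(max(all_letd), 7 + 1e-9)
})

test_that("within-gland dose-LET_d correlation hits the configured target", {
  for (target in c(-0.3, 0, 0.5)) {
    ph <- generate_phantom(phantom_spec(dose_let_correlation = target,
                                        seed = 11L))
    letd <- ifelse(ph$dose > 0, ph$dose_let / ph$dose, 0)
    for (g in seq_along(ph$gland_levels)) {
      idx <- which(ph$mask == g)
      if (length(idx) < 500) next
      expect_lt(abs(stats::cor(ph$dose[idx], letd[idx]) - target), 0.15)
    }
  }
})

test_that("baseline uptake matches the configured SUV>=5 fraction", {
  spec <- phantom_spec(uptake_frac_above = 0.9, seed = 8L)
  ph <- generate_phantom(spec)
  for (g in seq_along(ph$gland_levels)) {
    idx <- which(ph$mask == g)
    if (length(idx) < 500) next
    expect_lt(abs(mean(ph$baseline[idx] >= 5) - 0.9), 0.05)
  }
  expect_true(all(ph$baseline > 0))
})

test_that("follow-up noise law is multiplicative lognormal of the stated sd", {
  ph <- generate_phantom(small_spec(seed = 5L))
  tp <- fit_parameters(0.8, 1.5e-4, 0.1)
  pred <- simulate_followup(ph$baseline, ph$dose, ph$dose_let, tp, 0)
  fu <- simulate_followup(ph$baseline, ph$dose, ph$dose_let, tp,
                          noise_sigma = 0.05, seed = 21L)
  lr <- log(fu / pred)
  expect_gt(length(lr), 1e4)
  expect_gte(stats::sd(lr), 0.045)
  expect_lte(stats::sd(lr), 0.055)
  expect_true(all(fu > 0))
  # noise-free sanity: beta0 = 1, beta1 = 0 reproduces the baseline exactly
  ident <- simulate_followup(ph$baseline, ph$dose, ph$dose_let,
                             fit_parameters(1, 0, 0), 0)
  expect_equal(ident, ph$baseline)
})

test_that("simulate_followup rejects unregistered volumes", {
  a <- array(1, c(4, 4, 4))
  b <- array(1, c(4, 4, 5))
  expect_error(simulate_followup(a, b, b, fit_parameters(1, 0, 0), 0),
               "co-registered")
})

test_that("glands outside the grid raise a geometry error", {
  sp <- small_spec()
  sp$glands$cx[1] <- 2
  expect_error(generate_phantom(sp), "outside the grid")
})

test_that("phantom generation is bit-reproducible for a fixed seed", {
  a <- generate_phantom(small_spec(seed = 77L))
  b <- generate_phantom(small_spec(seed = 77L))
  expect_identical(a$dose, b$dose)
  expect_identical(a$dose_let, b$dose_let)
  expect_identical(a$baseline, b$baseline)
  expect_identical(a$mask, b$mask)
})

test_that("cohort manifests carry the ground truth, with distinct sub-seeds", {
  betas <- reference_slopes("combined", "one_month")
  tp_list <- lapply(betas, function(b2) fit_parameters(0.8, 1.5e-4, b2))
  sp <- small_spec(seed = 4L)
  co <- make_patient_cohort(6, sp, tp_list, seed = 4L)
  expect_equal(nrow(co$manifest), 6L)
  expect_equal(mean(co$manifest$beta2), 0.0745, tolerance = 1e-12)
  expect_equal(length(unique(co$manifest$seed)), 6L)
  one <- make_patient_cohort(1, sp, list(fit_parameters(1, 0, 0)), seed = 9L)
  expect_equal(length(one$patients), 1L)
  # determinism of the whole cohort
  co2 <- make_patient_cohort(6, sp, tp_list, seed = 4L)
  expect_identical(co$patients[[3]]$followup, co2$patients[[3]]$followup)
})

test_that("flat record simulator honours correlation and noise contracts", {
  tp <- fit_parameters(0.8, 1.5e-4, 0.1)
  rec <- simulate_voxel_records(5000, tp, dose_let_cor = 0.6,
                                noise_sigma = 0, seed = 31L)
  letd <- voxel_let_d(rec)
  expect_lt(abs(stats::cor(rec$dose_gy, letd) - 0.6), 0.02)
  expect_gte(min(letd), 1 - 1e-9)
  expect_lte(max(letd), 7 + 1e-9)
  # noise-free records sit exactly on the model surface
  pred <- predict_followup(rec$suv_baseline, rec$dose_gy, letd, tp)
  expect_equal(rec$suv_followup, pred)
  # common random numbers: dose draws identical across correlation levels
  rec2 <- simulate_voxel_records(5000, tp, dose_let_cor = 0.95,
                                 noise_sigma = 0, seed = 31L)
  expect_identical(rec$dose_gy, rec2$dose_gy)
  expect_identical(rec$suv_baseline, rec2$suv_baseline)
})
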