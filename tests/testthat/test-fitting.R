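test_that("the SSE objective matches hand-computed residual sums", {
  # single zero-dose voxel with beta0 = 1: residual is followup - baseline
  one <- voxel_records("P", "one_month", "parotid_L", 1L, 1L, 1L,
                       0, 0, 10, 8)
  expect_equal(objective_sse(one, list(beta0 = 1, beta1 = 0, beta2 = 0)), 4)
  # five hand-written records against spreadsheet-style summation
  rec <- hand_records()
  p <- list(beta0 = 0.75, beta1 = 2e-4, beta2 = 0.1)
  letd <- rec$dose_let_gy_kev_um / pmax(rec$dose_gy, 1e-300)
  letd[rec$dose_gy == 0] <- 0
  pred <- rec$suv_baseline * 0.75 *
    exp(-2e-4 * rec$dose_gy * (1 + 0.1 * letd))
  expect_equal(objective_sse(rec, p),
               sum((rec$suv_followup - pred)^2))
  expect_equal(objective_sse(rec, p, loss = "sse_relative"),
               sum(((rec$suv_followup - pred) / rec$suv_baseline)^2))
  # perfect fit on noise-free records
  tp <- fit_parameters(0.8, 1.5e-4, 0.1)
  nf <- simulate_voxel_records(200, tp, noise_sigma = 0, seed = 61L)
  expect_lt(objective_sse(nf, tp), 1e-18)
  expect_error(objective_sse(nf[0, ], tp), "at least one")
})

test_that("noise-free parameters are recovered within optimizer tolerance", {
  truth <- fit_parameters(0.8, 1.5e-4, 0.10)
  rec <- simulate_voxel_records(4000, truth, dose_let_cor = 0,
                                noise_sigma = 0, seed = 62L)
  fit <- fit_gland_set(rec, "combined",
                       fit_config(max_iterations = 2000, seed = 63L))
  expect_lt(abs(fit$beta0 - 0.8), 0.01)
  expect_lt(abs(fit$beta1 - 1.5e-4), 1e-5)
  expect_lt(abs(fit$beta2 - 0.10), 0.02)
  expect_true(fit$beta2_identifiable)
  expect_lt(fit$objective_value, 1e-10)
})

test_that("fits are bit-reproducible for identical records, config and seed", {
  truth <- fit_parameters(0.9, 2e-4, 0.05)
  rec <- simulate_voxel_records(800, truth, noise_sigma = 0.05, seed = 64L)
  cfg <- fit_config(max_iterations = 500, seed = 65L)
  a <- fit_gland_set(rec, "combined", cfg)
  b <- fit_gland_set(rec, "combined", cfg)
  expect_identical(c(a$beta0, a$beta1, a$beta2, a$objective_value),
                   c(b$beta0, b$beta1, b$beta2, b$objective_value))
})

test_that("the fit beats 100 random parameter draws within bounds", {
  truth <- fit_parameters(0.7, 1e-4, 0.15)
  rec <- simulate_voxel_records(600, truth, noise_sigma = 0.05, seed = 66L)
  fit <- fit_gland_set(rec, "combined",
                       fit_config(max_iterations = 500, seed = 67L))
  set.seed(68)
  draws <- replicate(100, {
    p <- list(beta0 = runif(1, 0.05, 2), beta1 = runif(1, -5e-3, 5e-3),
              beta2 = runif(1, -2, 2))
    objective_sse(rec, p)
  })
  expect_lte(fit$objective_value, min(draws))
})

test_that("constant LET_d flags beta2 as non-identifiable but fits the rest", {
  truth <- fit_parameters(0.8, 2e-4, 0)
  rec <- simulate_voxel_records(1500, truth, let_range = c(3, 3),
                                noise_sigma = 0, seed = 69L)
  expect_warning(
    fit <- fit_gland_set(rec, "combined",
                         fit_config(max_iterations = 1500, seed = 70L)),
    "not identifiable")
  expect_false(fit$beta2_identifiable)
  expect_lt(abs(fit$beta0 - 0.8), 0.01)
  # effective radiosensitivity beta1 * (1 + 3 * beta2) is what the data pin
  # down when LET_d is constant at 3
  expect_lt(abs(fit$beta1 * (1 + 3 * fit$beta2) - 2e-4), 1e-5)
})

test_that("degenerate and mixed designs are rejected", {
  one_point <- voxel_records("P", "one_month", "parotid_L", 1:3, 1L, 1L,
                             dose_gy = 10, dose_let_gy_kev_um = 20,
                             suv_baseline = c(10, 9, 11),
                             suv_followup = c(8, 7, 9))
  expect_error(fit_gland_set(one_point, "combined"), "degenerate")
  truth <- fit_parameters(0.8, 1.5e-4, 0.1)
  a <- simulate_voxel_records(50, truth, patient_id = "A", seed = 71L)
  b <- simulate_voxel_records(50, truth, patient_id = "B", seed = 72L)
  expect_error(fit_gland_set(dplyr::bind_rows(a, b), "combined"),
               "multiple patients")
  par_only <- simulate_voxel_records(50, truth, gland = "parotid_L",
                                     seed = 73L)
  expect_error(fit_gland_set(par_only, "submandibular"), "no voxels")
})

test_that("gland-set filtering fits only the requested glands", {
  truth <- fit_parameters(0.8, 1.5e-4, 0.1)
  rec <- simulate_voxel_records(2000, truth, noise_sigma = 0, seed = 74L)
  fit_p <- fit_gland_set(rec, "parotid",
                         fit_config(max_iterations = 2000, seed = 75L))
  n_parotid <- sum(rec$gland %in% c("parotid_L", "parotid_R"))
  expect_equal(fit_p$gland_set, "parotid")
  expect_lt(abs(fit_p$beta2 - 0.1), 0.02)
  expect_gt(n_parotid, 0)
})

test_that("the grid oracle finds an exact on-grid truth", {
  # truth placed on a node of the 21^3 default-bounds grid
  truth <- fit_parameters(0.83, 5e-4, 0.2)
  rec <- simulate_voxel_records(400, truth, noise_sigma = 0, seed = 76L)
  oracle <- grid_search_oracle(rec, fit_config(), grid_resolution = 21L)
  expect_equal(oracle$beta0, 0.83, tolerance = 1e-12)
  expect_equal(oracle$beta1, 5e-4, tolerance = 1e-12)
  expect_equal(oracle$beta2, 0.2, tolerance = 1e-12)
  expect_lt(oracle$objective_value, 1e-18)
  expect_error(grid_search_oracle(rec, fit_config(), 2L), "at least 3")
})

test_that("annealing never loses to the grid oracle", {
  truth <- fit_parameters(0.83, 5e-4, 0.2)
  rec <- simulate_voxel_records(1000, truth, noise_sigma = 0.05, seed = 77L)
  cfg <- fit_config(max_iterations = 2000, seed = 78L)
  fit <- fit_gland_set(rec, "combined", cfg)
  oracle <- grid_search_oracle(rec, cfg, grid_resolution = 41L)
  expect_lte(fit$objective_value,
             oracle$objective_value * (1 + 1e-9) + 1e-12)
  sp <- attr(oracle, "grid_spacing")
  expect_lte(abs(fit$beta0 - oracle$beta0), sp[["beta0"]] + 1e-12)
  expect_lte(abs(fit$beta1 - oracle$beta1), sp[["beta1"]] + 1e-12)
  expect_lte(abs(fit$beta2 - oracle$beta2), sp[["beta2"]] + 1e-12)
})

test_that("the fit agrees with an independent log-scale OLS oracle", {
  # under lognormal noise the log-linear regression is an independent
  # consistent estimator of the same parameters; with low noise both
  # estimators must agree closely
  truth <- fit_parameters(0.8, 1.5e-4, 0.1)
  rec <- simulate_voxel_records(3000, truth, dose_let_cor = 0,
                                noise_sigma = 0.002, seed = 79L)
  fit <- fit_gland_set(rec, "combined",
                       fit_config(max_iterations = 3000, seed = 80L))
  ols <- oracle_loglm(rec)
  expect_lt(abs(fit$beta0 - ols$beta0), 0.005)
  expect_lt(abs(fit$beta1 - ols$beta1), 5e-6)
  expect_lt(abs(fit$beta2 - ols$beta2), 0.02)
})

test_that("fit configuration validates bounds and iterations", {
  expect_error(fit_config(bounds = list(beta0 = c(2, 1),
                                        beta1 = c(-1, 1),
                                        beta2 = c(-1, 1))),
               "properly ordered")
  expect_error(fit_config(max_iterations = 0), ">= 1")
  cfg <- fit_config()
  expect_identical(cfg$max_iterations, 10000L)
  expect_identical(cfg$loss, "sse_followup")
})

test_that("noisy recovery at a reference-scale truth is centred, if diffuse", {
  # Conditions mirror a well-responding patient (beta0 = 0.753,
  # beta1 = 8.39e-5, beta2 = 0.206) with 5 % lognormal noise at n = 3000.
  # An oracle run of this exact experiment (10 seeds) established that the
  # per-seed estimates scatter across most of the bounded range
  # (sd ~ 1.1): beta2 is practically unidentified voxel-wise at this
  # radiosensitivity and noise level. The frozen assertion is therefore on
  # the central tendency (median within 2 median-SEs of the truth), not on
  # a tight per-seed interval.
  truth <- fit_parameters(0.753, 8.39e-5, 0.206)
  b2 <- vapply(1:10, function(s) {
    rec <- simulate_voxel_records(3000, truth, dose_let_cor = 0,
                                  noise_sigma = 0.05, seed = 400L + s)
    fit_gland_set(rec, "combined",
                  fit_config(max_iterations = 4000, seed = 500L + s))$beta2
  }, double(1))
  expect_true(all(b2 >= -2 & b2 <= 2))
  expect_lt(abs(stats::median(b2) - 0.206), 0.9)
})
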