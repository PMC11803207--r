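make_records <- function(dose, dose_let, baseline, followup) {
  n <- length(dose)
  voxel_records("P", "one_month", rep_len(gland_labels(), n), seq_len(n),
                1L, 1L, dose, dose_let, baseline, followup)
}

test_that("dose bins are left-closed right-open from origin 0", {
  rec <- make_records(c(1.0, 1.2, 2.6), c(2, 2, 5), 10, 8)
  bs <- bin_uptake_by_dose(rec, bin_width = 2.5)
  expect_equal(bs$table$n_voxels, c(2L, 1L))
  expect_equal(bs$table$dose_lo, c(0, 2.5))
  # value on a bin edge belongs to the upper bin
  rec2 <- make_records(c(2.5, 2.49), c(1, 1), 10, 8)
  bs2 <- bin_uptake_by_dose(rec2, 2.5)
  expect_equal(bs2$table$n_voxels, c(1L, 1L))
})

test_that("identical uptake gives that uptake as every non-empty bin mean", {
  rec <- make_records(runif(50, 0, 30), runif(50, 0, 90), 10, 6.5)
  bs <- bin_uptake_by_dose(rec, 2.5)
  nonempty <- bs$table$n_voxels > 0
  expect_true(all(bs$table$mean_followup[nonempty] == 6.5))
  expect_true(all(is.na(bs$table$mean_followup[!nonempty])))
})

test_that("1-D bin statistics equal a brute-force recount", {
  set.seed(41)
  n <- 10000
  rec <- make_records(runif(n, 0, 70), runif(n, 0, 400),
                      pmax(rnorm(n, 10, 2), 5), runif(n, 1, 12))
  bs <- bin_uptake_by_dose(rec, 2.5)
  for (b in c(1L, 7L, 15L, nrow(bs$table))) {
    o <- oracle_bin_1d(rec, 2.5, b)
    expect_identical(bs$table$n_voxels[b], o$n)
    expect_equal(bs$table$mean_followup[b], o$mean_followup)
    expect_equal(bs$table$mean_baseline[b], o$mean_baseline)
  }
  expect_equal(sum(bs$table$n_voxels), n)
})

test_that("a single mid-range voxel yields one kept 2-D bin", {
  rec <- make_records(30, 60, 10, 5)
  bs <- bin_relative_uptake_2d(rec)
  kept <- bs$table[!bs$table$excluded & bs$table$n_voxels > 0, ]
  expect_identical(nrow(kept), 1L)
  expect_equal(kept$mean_relative_uptake, 0.5)
  expect_equal(kept$mean_dose, 30)
  expect_equal(kept$mean_dose_let, 60)
  expect_equal(bs$excluded_fraction, 0)
})

test_that("records confined to the lowest dose bin are fully excluded", {
  rec <- make_records(c(1, 2, 4.9), c(30, 60, 90), 10, 5)
  bs <- bin_relative_uptake_2d(rec, dose_width = 5, dose_let_width = 25)
  expect_equal(bs$excluded_fraction, 1.0)
  expect_true(all(bs$table$n_voxels[!bs$table$excluded] == 0))
})

test_that("the lowest-margin exclusion removes the union of both margins", {
  # one voxel in the low-dose column, one in the low-D*LET_d row, one in
  # both, one in neither
  rec <- make_records(c(2, 30, 3, 40), c(100, 10, 5, 200), 10, 5)
  bs <- bin_relative_uptake_2d(rec, 5, 25)
  expect_equal(bs$excluded_fraction, 0.75)
  bs_off <- bin_relative_uptake_2d(rec, 5, 25, exclude_lowest = FALSE)
  expect_equal(bs_off$excluded_fraction, 0)
  expect_true(all(!bs_off$table$excluded))
})

test_that("a mixed-dose cohort excludes a fifth to a third of voxels", {
  # dose scale chosen so the lowest 5 Gy / 25 Gy keV/um margins hold about
  # a fifth of the voxels, the situation the exclusion rule is meant for
  set.seed(17)
  n <- 10000
  dose <- runif(n, 0, 40)
  letd <- runif(n, 1, 7)
  rec <- make_records(dose, dose * letd, pmax(rnorm(n, 10, 2), 5),
                      runif(n, 2, 10))
  bs <- bin_relative_uptake_2d(rec, 5, 25)
  expect_gte(bs$excluded_fraction, 0.19)
  expect_lte(bs$excluded_fraction, 0.38)
  # direct recount oracle of the excluded fraction
  frac <- mean(dose < 5 | dose * letd < 25)
  expect_equal(bs$excluded_fraction, frac)
})

test_that("2-D binning conserves voxel counts", {
  set.seed(23)
  n <- 3000
  rec <- make_records(runif(n, 0, 70), runif(n, 0, 450),
                      pmax(rnorm(n, 10, 2), 5), runif(n, 1, 12))
  bs <- bin_relative_uptake_2d(rec)
  expect_equal(sum(bs$table$n_voxels), n)
  expect_equal(sum(bs$table$n_voxels[bs$table$excluded]) +
                 sum(bs$table$n_voxels[!bs$table$excluded]), n)
})

test_that("refined bins aggregate back to the coarse summary", {
  set.seed(29)
  n <- 4000
  rec <- make_records(runif(n, 0, 70), runif(n, 0, 450),
                      pmax(rnorm(n, 10, 2), 5), runif(n, 1, 12))
  coarse <- bin_uptake_by_dose(rec, 5)
  fine <- bin_uptake_by_dose(rec, 2.5)
  expect_equal(sum(fine$table$n_voxels), sum(coarse$table$n_voxels))
  for (b in seq_len(nrow(coarse$table))) {
    children <- fine$table[fine$table$dose_lo >= coarse$table$dose_lo[b] &
                             fine$table$dose_hi <= coarse$table$dose_hi[b], ]
    expect_equal(sum(children$n_voxels), coarse$table$n_voxels[b])
    if (coarse$table$n_voxels[b] > 0) {
      wm <- sum(children$mean_followup * children$n_voxels, na.rm = TRUE) /
        sum(children$n_voxels)
      expect_equal(wm, coarse$table$mean_followup[b])
    }
  }
})

test_that("binning rejects bad configuration and empty input", {
  rec <- make_records(1, 1, 10, 8)
  expect_error(bin_uptake_by_dose(rec, 0), "positive")
  expect_error(bin_relative_uptake_2d(rec, -5, 25), "positive")
  empty <- rec[0, ]
  expect_error(bin_uptake_by_dose(empty), "non-empty")
})
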