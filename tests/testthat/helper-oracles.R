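# Independent oracles used to validate the implementation.

# Log-scale OLS estimate of the model parameters. Under the generator's
# multiplicative lognormal noise, log(FU/B) = log(beta0) - beta1*D -
# beta1*beta2*D*L + eps is an exact linear model, so ordinary least squares
# is an independent (and efficient) estimator of the same parameters.
oracle_loglm <- function(records) {
  D <- records$dose_gy
  L <- voxel_let_d(records)
  B <- records$suv_baseline
  FU <- records$suv_followup
  co <- stats::coef(stats::lm(log(FU / B) ~ D + I(D * L)))
  a <- -co[[2]]
  b <- -co[[3]]
  list(beta0 = exp(co[[1]]), beta1 = a, beta2 = b / a)
}

# Brute-force ROI oracle: for every voxel of the grid, scan the distance to
# every voxel center of the original mask and apply the SUV threshold.
oracle_adjust_roi <- function(mask, baseline, margin_mm, suv_threshold,
                              spacing) {
  dm <- dim(mask)
  sp <- if (length(spacing) == 1L) rep(spacing, 3L) else spacing
  mask_idx <- which(mask != 0)
  mask_ijk <- arrayInd(mask_idx, dm)
  keep <- logical(prod(dm))
  for (v in seq_len(prod(dm))) {
    ijk <- arrayInd(v, dm)
    d2 <- (mask_ijk[, 1] - ijk[1])^2 * sp[1]^2 +
      (mask_ijk[, 2] - ijk[2])^2 * sp[2]^2 +
      (mask_ijk[, 3] - ijk[3])^2 * sp[3]^2
    keep[v] <- any(d2 <= margin_mm^2 + 1e-9) && baseline[v] >= suv_threshold
  }
  which(keep)
}

# Brute-force 1-D binning recount by explicit filtering.
oracle_bin_1d <- function(records, width, bin) {
  lo <- (bin - 1) * width
  hi <- bin * width
  sel <- records$dose_gy >= lo & records$dose_gy < hi
  list(n = sum(sel),
       mean_followup = if (any(sel)) mean(records$suv_followup[sel]) else NA,
       mean_baseline = if (any(sel)) mean(records$suv_baseline[sel]) else NA)
}

# Small deterministic record table written out by hand for objective checks.
hand_records <- function() {
  voxel_records(
    patient_id = "H", timepoint = "one_month",
    gland = c("parotid_L", "parotid_L", "parotid_R",
              "submandibular_L", "submandibular_R"),
    i = 1:5, j = 1L, k = 1L,
    dose_gy = c(0, 10, 20, 40, 70),
    dose_let_gy_kev_um = c(0, 20, 50, 120, 350),
    suv_baseline = c(10, 8, 12, 6, 9),
    suv_followup = c(7.5, 6.0, 8.8, 4.1, 5.9)
  )
}
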