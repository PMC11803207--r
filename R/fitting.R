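# Per-patient model fitting: bounded stochastic global optimization of the
# three-parameter response model, plus an exhaustive grid-search oracle used
# for validation.

#' Fit configuration
#'
#' Parameter bounds and optimizer settings for [fit_gland_set()]. The named
#' optimizer requires finite box bounds; the defaults are chosen wide enough
#' to contain every plausible estimate with margin (beta0 up to 2, beta1 up
#' to +-5e-3 Gy^-1, beta2 up to +-2 (keV/um)^-1). The iteration cap defaults
#' to 10000.
#'
#' @param bounds Named list of length-2 numeric intervals for `beta0`,
#'   `beta1`, `beta2`.
#' @param max_iterations Annealing iteration cap (>= 1).
#' @param seed Integer optimizer seed (fits are deterministic given records,
#'   config and seed).
#' @param loss `"sse_followup"` (voxel-wise sum of squared residuals on
#'   absolute follow-up SUV; default) or `"sse_relative"` (residuals divided
#'   by baseline SUV first, so high-uptake voxels do not dominate).
#' @param polish Enable bounded local refinement after annealing (default
#'   `TRUE`; recorded in fit metadata).
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(bounds = list(beta0 = c(0.05, 2.0),
                                     beta1 = c(-5e-3, 5e-3),
                                     beta2 = c(-2.0, 2.0)),
                       max_iterations = 10000L,
                       seed = 1L,
                       loss = c("sse_followup", "sse_relative"),
                       polish = TRUE) {
  loss <- match.arg(loss)
  stopifnot(is.list(bounds),
            all(c("beta0", "beta1", "beta2") %in% names(bounds)))
  for (nm in c("beta0", "beta1", "beta2")) {
    b <- bounds[[nm]]
    if (length(b) != 2L || !all(is.finite(b)) || b[1] >= b[2]) {
      stop(sprintf("`bounds$%s` must be a finite, properly ordered interval",
                   nm), call. = FALSE)
    }
  }
  if (max_iterations < 1) stop("`max_iterations` must be >= 1", call. = FALSE)
  structure(list(bounds = bounds,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed), loss = loss,
                 polish = isTRUE(polish)),
            class = "fit_config")
}

# Extract the numeric vectors the objective needs, once.
fit_data <- function(records) {
  list(D = records$dose_gy,
       L = voxel_let_d(records),
       B = records$suv_baseline,
       FU = records$suv_followup)
}

sse_at <- function(dat, p, loss) {
  pred <- dat$B * p[1] * exp(-p[2] * dat$D * (1 + p[3] * dat$L))
  r <- dat$FU - pred
  if (loss == "sse_relative") r <- r / dat$B
  sum(r * r)
}

#' Voxel-wise sum-of-squares objective
#'
#' The objective minimized by [fit_gland_set()]: for `loss = "sse_followup"`,
#' `sum((suv_followup - predicted)^2)` over all records; for
#' `"sse_relative"`, residuals are divided by the baseline SUV first.
#'
#' @param records Non-empty voxel-record table.
#' @param params [fit_parameters()] or named beta list.
#' @param loss See [fit_config()].
#' @return Non-negative finite scalar.
#' @export
objective_sse <- function(records, params,
                          loss = c("sse_followup", "sse_relative")) {
  loss <- match.arg(loss)
  if (nrow(records) == 0L) {
    stop("`records` must contain at least one voxel", call. = FALSE)
  }
  b <- as_beta(params)
  sse_at(fit_data(records), unname(b), loss)
}

#' Fit the response model for one patient and gland set
#'
#' Filters the records to the requested gland set and minimizes the
#' voxel-wise sum of squared residuals of the model
#' `PSMA_FU = PSMA_0 * beta0 * exp(-beta1 * Dose * (1 + beta2 * LET_d))`
#' by bounded generalized simulated annealing ([dual_anneal()]) with local
#' polish, seeded and iteration-capped per `config`. Each patient and
#' timepoint is fitted individually: mixed patients or timepoints are an
#' error.
#'
#' If the selected voxels have (numerically) constant LET_d, `beta2` drops
#' out of the model; the fit proceeds for `beta0`/`beta1` but `beta2` is
#' flagged non-identifiable with a warning. If all voxels share a single
#' (dose, LET_d) point the design is degenerate and an error is raised.
#'
#' @param records Voxel-record table for a single patient and timepoint.
#' @param gland_set `"parotid"`, `"submandibular"` or `"combined"`.
#' @param config A [fit_config()].
#' @return A [fit_parameters()] object with objective value, seed and
#'   identifiability metadata.
#' @export
fit_gland_set <- function(records, gland_set = "combined",
                          config = fit_config()) {
  gland_set <- match.arg(gland_set, GLAND_SETS)
  stopifnot(inherits(config, "fit_config"))
  rec <- records[records$gland %in% gland_set_members(gland_set), ,
                 drop = FALSE]
  if (nrow(rec) == 0L) {
    stop(sprintf("no voxels in gland set '%s'", gland_set), call. = FALSE)
  }
  pid <- unique(rec$patient_id)
  tp <- unique(rec$timepoint)
  if (length(pid) != 1L) {
    stop("records mix multiple patients; fit one patient at a time",
         call. = FALSE)
  }
  if (length(tp) != 1L) {
    stop("records mix multiple timepoints; fit one timepoint at a time",
         call. = FALSE)
  }
  dat <- fit_data(rec)
  if (length(unique(paste(dat$D, dat$L))) == 1L) {
    stop("degenerate design: all voxels share a single (dose, LET_d) point; the model is unidentifiable",
         call. = FALSE)
  }
  pos <- dat$D > 0
  identifiable <- any(pos) && stats::sd(dat$L[pos]) > 1e-9
  if (!identifiable) {
    warning("LET_d is constant across the fitted voxels; beta2 is not identifiable",
            call. = FALSE)
  }
  lo <- c(config$bounds$beta0[1], config$bounds$beta1[1],
          config$bounds$beta2[1])
  hi <- c(config$bounds$beta0[2], config$bounds$beta1[2],
          config$bounds$beta2[2])
  obj <- function(p) sse_at(dat, p, config$loss)
  res <- dual_anneal(obj, lo, hi, maxiter = config$max_iterations,
                     seed = config$seed, polish = config$polish)
  fit_parameters(res$par[1], res$par[2], res$par[3],
                 gland_set = gland_set, timepoint = tp,
                 objective_value = res$value, seed = config$seed,
                 converged = TRUE, beta2_identifiable = identifiable,
                 patient_id = pid)
}

#' Exhaustive grid-search oracle
#'
#' Brute-force evaluation of the fit objective on a regular 3-D grid of
#' parameter values spanning the configured bounds, returning the grid
#' argmin. Intended as an independent validation oracle for
#' [fit_gland_set()] on small fixtures, not as a production fitter.
#'
#' @param records Voxel-record table (small; a few thousand voxels at most).
#' @param config A [fit_config()] (bounds and loss are used).
#' @param grid_resolution Nodes per parameter axis (>= 3).
#' @return A [fit_parameters()] at the grid argmin; the per-axis grid
#'   spacing is attached as attribute `"grid_spacing"`.
#' @export
grid_search_oracle <- function(records, config = fit_config(),
                               grid_resolution = 41L) {
  stopifnot(inherits(config, "fit_config"))
  if (grid_resolution < 3L) {
    stop("`grid_resolution` must be at least 3 to bracket the bounds",
         call. = FALSE)
  }
  if (nrow(records) == 0L) stop("`records` must be non-empty", call. = FALSE)
  dat <- fit_data(records)
  g0 <- seq(config$bounds$beta0[1], config$bounds$beta0[2],
            length.out = grid_resolution)
  g1 <- seq(config$bounds$beta1[1], config$bounds$beta1[2],
            length.out = grid_resolution)
  g2 <- seq(config$bounds$beta2[1], config$bounds$beta2[2],
            length.out = grid_resolution)
  w <- if (config$loss == "sse_relative") 1 / dat$B else rep(1, length(dat$B))
  fu_w <- dat$FU * w
  s3 <- sum(fu_w^2)
  best <- c(NA_real_, NA_real_, NA_real_)
  fbest <- Inf
  for (b1 in g1) {
    for (b2 in g2) {
      pred0 <- dat$B * exp(-b1 * dat$D * (1 + b2 * dat$L)) * w
      s1 <- sum(pred0^2)
      s2 <- sum(fu_w * pred0)
      sse <- g0 * g0 * s1 - 2 * g0 * s2 + s3
      m <- which.min(sse)
      if (sse[m] < fbest) {
        # clamp tiny negative values from floating-point cancellation
        fbest <- max(sse[m], 0)
        best <- c(g0[m], b1, b2)
      }
    }
  }
  tp <- unique(records$timepoint)
  pid <- unique(records$patient_id)
  out <- fit_parameters(best[1], best[2], best[3],
                        gland_set = "combined",
                        timepoint = if (length(tp) == 1L) tp else "one_month",
                        objective_value = fbest, seed = NA_integer_,
                        converged = TRUE,
                        patient_id = if (length(pid) == 1L) pid else NA)
  attr(out, "grid_spacing") <- c(beta0 = diff(g0[1:2]), beta1 = diff(g1[1:2]),
                                 beta2 = diff(g2[1:2]))
  out
}

#' Tabulate a list of fits
#'
#' Flattens [fit_parameters()] objects into one row each, mirroring the
#' per-patient results-table layout (patient, timepoint, gland set, betas,
#' objective, seed).
#'
#' @param fits A single `fit_parameters` or a list of them.
#' @return A tibble.
#' @export
fits_table <- function(fits) {
  if (inherits(fits, "fit_parameters")) fits <- list(fits)
  tibble::tibble(
    patient_id = vapply(fits, function(f) f$patient_id, character(1)),
    timepoint = vapply(fits, function(f) f$timepoint, character(1)),
    gland_set = vapply(fits, function(f) f$gland_set, character(1)),
    beta0 = vapply(fits, function(f) f$beta0, double(1)),
    beta1 = vapply(fits, function(f) f$beta1, double(1)),
    beta2 = vapply(fits, function(f) f$beta2, double(1)),
    objective = vapply(fits, function(f) f$objective_value, double(1)),
    seed = vapply(fits, function(f) as.integer(f$seed), integer(1)),
    beta2_identifiable = vapply(fits, function(f)
      isTRUE(f$beta2_identifiable), logical(1))
  )
}
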