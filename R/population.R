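# Population aggregation of per-patient RBE-LET slopes.

#' Aggregate per-patient RBE-LET slopes
#'
#' Combines the fitted `beta2` slopes of individual patients into a
#' population mean with a 95 % (by default) confidence interval. The
#' default interval is the Student-t interval on patient-level slopes,
#' `mean +- t(1 - alpha/2, n - 1) * sd / sqrt(n)`; a seeded percentile
#' bootstrap over resampled patient means is available as an alternative,
#' and `ci_method = "none"` returns the mean alone.
#'
#' @param slopes Numeric vector of per-patient `beta2` values
#'   ((keV/um)^-1); at least one for the mean, at least two for any CI.
#' @param ci_method `"t_interval"` (default), `"percentile_bootstrap"` or
#'   `"none"`.
#' @param conf_level Confidence level (default 0.95).
#' @param bootstrap_reps Bootstrap resamples (default 2000).
#' @param seed Seed for the bootstrap (`NULL` = current stream).
#' @param gland_set,timepoint Optional metadata stored in the summary.
#' @param strict Count semantics for positive slopes (see
#'   [count_positive_slopes()]).
#' @return Object of class `slope_summary`: list with `n_patients`,
#'   `mean_slope`, `ci_low`, `ci_high`, `ci_method`, `conf_level`,
#'   `n_positive`, `gland_set`, `timepoint`.
#' @export
aggregate_slopes <- function(slopes,
                             ci_method = c("t_interval",
                                           "percentile_bootstrap", "none"),
                             conf_level = 0.95, bootstrap_reps = 2000L,
                             seed = NULL, gland_set = NA_character_,
                             timepoint = NA_character_, strict = TRUE) {
  ci_method <- match.arg(ci_method)
  slopes <- as.double(slopes)
  if (length(slopes) == 0L) {
    stop("`slopes` must contain at least one value", call. = FALSE)
  }
  stop_if_not_finite(slopes, "slopes")
  n <- length(slopes)
  m <- mean(slopes)
  ci <- c(NA_real_, NA_real_)
  if (ci_method != "none") {
    if (n < 2L) {
      stop("at least two slopes are required for a confidence interval",
           call. = FALSE)
    }
    alpha <- 1 - conf_level
    if (ci_method == "t_interval") {
      half <- stats::qt(1 - alpha / 2, df = n - 1) *
        stats::sd(slopes) / sqrt(n)
      ci <- c(m - half, m + half)
    } else {
      ci <- with_seed(seed, {
        means <- vapply(seq_len(bootstrap_reps), function(b) {
          mean(sample(slopes, n, replace = TRUE))
        }, double(1))
        unname(stats::quantile(means, c(alpha / 2, 1 - alpha / 2),
                               type = 7))
      })
    }
  }
  structure(list(gland_set = gland_set, timepoint = timepoint,
                 n_patients = n, mean_slope = m,
                 ci_low = ci[1], ci_high = ci[2],
                 ci_method = ci_method, conf_level = conf_level,
                 n_positive = count_positive_slopes(slopes, strict = strict)),
            class = "slope_summary")
}

#' @export
print.slope_summary <- function(x, ...) {
  cat(sprintf(
    "<slope_summary> n = %d patients%s\n  mean RBE-LET slope = %.4g (keV/um)^-1",
    x$n_patients,
    if (is.na(x$gland_set)) "" else sprintf(" (%s, %s)", x$gland_set,
                                            x$timepoint),
    x$mean_slope))
  if (!is.na(x$ci_low)) {
    cat(sprintf(", %d %% CI [%.4g; %.4g] (%s)",
                round(100 * x$conf_level), x$ci_low, x$ci_high, x$ci_method))
  }
  cat(sprintf("\n  patients with positive slope: %d\n", x$n_positive))
  invisible(x)
}

#' Count patients with a positive RBE-LET slope
#'
#' @param slopes Non-empty numeric vector of per-patient `beta2` values.
#' @param strict Count `beta2 > 0` (default); `FALSE` counts `beta2 >= 0`,
#'   so a slope printed as exactly zero is included.
#' @return Integer count.
#' @export
count_positive_slopes <- function(slopes, strict = TRUE) {
  if (length(slopes) == 0L) {
    stop("`slopes` must be non-empty", call. = FALSE)
  }
  if (strict) sum(slopes > 0) else sum(slopes >= 0)
}

#' Write a slope summary as a flat key-value report
#'
#' @param summary A `slope_summary`.
#' @param path Output path (YAML-compatible key-value lines).
#' @return `summary`, invisibly.
#' @export
write_slope_summary <- function(summary, path) {
  stopifnot(inherits(summary, "slope_summary"))
  write_flat_config(unclass(summary)[c("gland_set", "timepoint",
                                       "n_patients", "mean_slope",
                                       "ci_low", "ci_high", "ci_method",
                                       "conf_level", "n_positive")],
                    path)
  invisible(summary)
}
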