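# Bounded generalized simulated annealing (dual-annealing style): Tsallis
# visiting distribution with a fast cooling schedule, Metropolis acceptance,
# chain restarts when the temperature bottoms out, and periodic bounded
# local polish (stats::nlminb) from the incumbent best.

# Draw n steps from the Tsallis visiting distribution at the given
# temperature (visiting shape parameter qv in (1, 3)).
tsallis_visit <- function(n, qv, temp) {
  factor2 <- exp((4 - qv) * log(qv - 1))
  factor3 <- exp((2 - qv) * log(2) / (qv - 1))
  factor4p <- sqrt(pi) * exp(log(temp) / (qv - 1)) * factor2 /
    (factor3 * (3 - qv))
  factor5 <- 1 / (qv - 1) - 0.5
  d1 <- 2 - factor5
  factor6 <- pi * (1 - factor5) / sin(pi * (1 - factor5)) / gamma(d1)
  sigmax <- exp(-(qv - 1) * log(factor6 / factor4p) / (3 - qv))
  x <- sigmax * stats::rnorm(n)
  y <- stats::rnorm(n)
  den <- exp((qv - 1) * log(abs(y)) / (3 - qv))
  v <- x / den
  # cap pathological tail draws so folded candidates stay meaningful
  tail_limit <- 1e8
  big <- abs(v) > tail_limit
  if (any(big)) v[big] <- sign(v[big]) * tail_limit * stats::runif(sum(big))
  v
}

# Fold a candidate back into [lower, upper] by modular wrapping.
fold_bounds <- function(x, lower, upper) {
  rng <- upper - lower
  w <- (x - lower) %% rng
  w[!is.finite(w)] <- rng[!is.finite(w)] / 2
  lower + w
}

#' Bounded generalized simulated annealing
#'
#' Minimizes `fn` over a box by generalized simulated annealing: candidate
#' steps are drawn from a heavy-tailed Tsallis visiting distribution whose
#' scale shrinks with a fast cooling schedule, uphill moves are accepted by a
#' Metropolis rule, the chain restarts from a random point when the
#' temperature ratio falls below `restart_temp_ratio`, and the incumbent best
#' is periodically polished with bounded [stats::nlminb()]. With a fixed
#' `seed` the result is bit-reproducible.
#'
#' @param fn Objective function of a numeric vector; must return a finite
#'   scalar inside the bounds.
#' @param lower,upper Numeric bounds (finite, `lower < upper`).
#' @param maxiter Maximum number of annealing iterations (temperature steps);
#'   each iteration proposes one full-vector move plus one per-coordinate
#'   move.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param initial_temp,restart_temp_ratio,visit Annealing schedule constants
#'   (initial temperature, restart threshold, visiting shape).
#' @param polish Run bounded local refinement from the best point (default
#'   `TRUE`).
#' @return List with `par`, `value`, `iterations`, `n_polish`, `polished`.
#' @export
dual_anneal <- function(fn, lower, upper, maxiter = 10000, seed = NULL,
                        initial_temp = 5230, restart_temp_ratio = 2e-4,
                        visit = 2.62, polish = TRUE) {
  lower <- as.double(lower); upper <- as.double(upper)
  d <- length(lower)
  stopifnot(length(upper) == d, all(is.finite(lower)), all(is.finite(upper)),
            all(lower < upper), maxiter >= 1)
  # optimize on the unit cube so step sizes and local-polish tolerances are
  # comparable across parameters of very different magnitudes
  rng0 <- upper - lower
  fnu <- function(z) fn(lower + z * rng0)
  u_lower <- rep(0, d)
  u_upper <- rep(1, d)
  with_seed(seed, {
    x <- stats::runif(d)
    fx <- fnu(x)
    best <- x; fbest <- fx
    cyc_best <- x; f_cyc_best <- fx
    t1 <- 2^(visit - 1) - 1
    it_local <- 0L
    n_polish <- 0L
    f_at_last_polish <- Inf

    # polish a candidate and fold the improvement into the global best
    do_polish <- function(z) {
      fit <- tryCatch(
        stats::nlminb(z, fnu, lower = u_lower, upper = u_upper,
                      control = list(abs.tol = 0, iter.max = 300L,
                                     eval.max = 600L)),
        error = function(e) NULL)
      if (!is.null(fit) && is.finite(fit$objective)) {
        zp <- fold_bounds(fit$par, u_lower, u_upper)
        fzp <- fnu(zp)
        if (fzp < fbest) { best <<- zp; fbest <<- fzp }
      }
      f_at_last_polish <<- fbest
      n_polish <<- n_polish + 1L
    }

    for (it in seq_len(maxiter)) {
      it_local <- it_local + 1L
      temp <- initial_temp * t1 / ((1 + it_local)^(visit - 1) - 1)
      if (temp / initial_temp < restart_temp_ratio) {
        # temperature exhausted: polish this cycle's own best (so each
        # annealing cycle acts as an independent start even when its raw
        # best is worse than an earlier polished one), then restart the
        # chain from a fresh random point
        if (polish) do_polish(cyc_best)
        it_local <- 1L
        temp <- initial_temp * t1 / (2^(visit - 1) - 1)
        x <- stats::runif(d)
        fx <- fnu(x)
        cyc_best <- x; f_cyc_best <- fx
      }
      for (j in 0:d) {
        if (j == 0L) {
          cand <- fold_bounds(x + tsallis_visit(d, visit, temp),
                              u_lower, u_upper)
        } else {
          cand <- x
          cand[j] <- fold_bounds(x[j] + tsallis_visit(1L, visit, temp),
                                 0, 1)
        }
        fc <- fnu(cand)
        accept <- if (fc <= fx) TRUE else {
          stats::runif(1) < exp(-(fc - fx) / max(temp, .Machine$double.eps))
        }
        if (accept) {
          x <- cand; fx <- fc
          if (fx < fbest) { best <- x; fbest <- fx }
          if (fx < f_cyc_best) { cyc_best <- x; f_cyc_best <- fx }
        }
      }
      if (polish && it %% 200L == 0L && n_polish < 60L &&
          fbest < f_at_last_polish) {
        do_polish(best)
      }
    }
    if (polish) {
      do_polish(cyc_best)
      do_polish(best)
    }
    list(par = lower + best * rng0, value = fbest,
         iterations = as.integer(maxiter),
         n_polish = n_polish, polished = isTRUE(polish))
  })
}
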