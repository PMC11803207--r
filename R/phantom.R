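# Synthetic phantom cohorts: co-registered dose, D*LET_d, baseline-uptake
# and follow-up-uptake volumes plus gland label masks, with known ground
# truth, standing in for clinical imaging data that is not publicly
# deposited.

#' Default gland geometry of the phantom
#'
#' Four ellipsoidal glands (two parotid, two submandibular) positioned on a
#' head-and-neck-like grid; centers and radii in mm. Real gland shapes are
#' irrelevant to the statistics the phantom exercises.
#'
#' @return A tibble with columns `gland`, `cx`, `cy`, `cz`, `rx`, `ry`, `rz`.
#' @export
default_gland_geometry <- function() {
  tibble::tibble(
    gland = GLANDS,
    cx = c(30, 96, 47, 79),
    cy = c(70, 70, 52, 52),
    cz = c(55, 55, 25, 25),
    rx = c(14, 14, 10, 10),
    ry = c(18, 18, 12, 12),
    rz = c(20, 20, 11, 11)
  )
}

#' Default beam model of the phantom
#'
#' A single lateral beam entering from the +x side (direction -1) with a
#' dose plateau proximal to a sigmoid distal fall-off, and a broad Gaussian
#' lateral profile. The distal edge is placed so that the far parotid sits
#' across the fall-off, giving a wide within-gland dose range.
#'
#' @return A list of beam definitions; each beam is a list with `axis`
#'   (`"x"`, `"y"` or `"z"`), `direction` (+1/-1 along the axis),
#'   `edge_mm` (distal-edge coordinate), `falloff_mm` (sigmoid width),
#'   `plateau_gy` (plateau dose), `lateral_sigma_mm` and
#'   `lateral_center_mm` (length-2, in the two orthogonal axes in x,y,z
#'   order).
#' @export
default_beams <- function() {
  list(list(axis = "x", direction = -1, edge_mm = 36, falloff_mm = 3,
            plateau_gy = 70, lateral_sigma_mm = 40,
            lateral_center_mm = c(70, 45)))
}

#' Phantom specification
#'
#' All generator knobs for one synthetic patient: grid, gland geometry,
#' parametric beam/dose model, LET_d field (baseline plus distal-edge
#' enhancement), the within-gland dose-LET_d correlation target, baseline
#' uptake distribution, ground-truth model parameters, follow-up noise and
#' seed. With a fixed seed, generation is bit-reproducible.
#'
#' @param grid_shape Voxel counts per axis (default 64 x 64 x 48).
#' @param spacing Voxel spacing in mm (scalar or length-3; default 2 mm
#'   isotropic, matching a 2 mm isotropic dose grid).
#' @param glands Gland geometry table, see [default_gland_geometry()].
#' @param beams Beam list, see [default_beams()].
#' @param let_baseline Baseline LET_d (keV/um) in the irradiated volume.
#' @param let_enhancement Additional LET_d at the distal enhancement peak
#'   (keV/um); 0 gives a constant LET_d field.
#' @param let_falloff_offset_mm Offset of the LET rise beyond the dose
#'   distal edge (mm).
#' @param let_texture_sd Small-scale smooth texture added to the LET spatial
#'   pattern (fraction of pattern range) so the field is never exactly
#'   degenerate.
#' @param dose_let_correlation Target Pearson correlation between dose and
#'   LET_d within each gland (achieved exactly per gland, by construction).
#' @param uptake_mean,uptake_sd Mean and spatial-heterogeneity SD of the
#'   baseline SUV inside glands.
#' @param uptake_frac_above Optional target fraction of gland voxels with
#'   baseline SUV at or above `suv_threshold`; when given, the gland mean is
#'   derived from it instead of `uptake_mean`.
#' @param suv_threshold SUV threshold referenced by `uptake_frac_above`
#'   (default 5.0 g/ml, the ROI-adjustment threshold).
#' @param uptake_background Baseline SUV outside glands.
#' @param uptake_floor Hard positive floor applied to the baseline volume.
#' @param true_params Ground-truth [fit_parameters()] of the patient.
#' @param noise_sigma SD of the multiplicative lognormal noise on follow-up
#'   uptake (`0` = noise-free).
#' @param noise_model `"lognormal"` (default) or `"gaussian"` (additive;
#'   available as an option, off by default, because PET uptake is positive
#'   and heteroscedastic).
#' @param seed Integer seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L, 48L),
                         spacing = 2,
                         glands = default_gland_geometry(),
                         beams = default_beams(),
                         let_baseline = 1,
                         let_enhancement = 6,
                         let_falloff_offset_mm = 4,
                         let_texture_sd = 0.05,
                         dose_let_correlation = -0.3,
                         uptake_mean = 10,
                         uptake_sd = 2,
                         uptake_frac_above = NULL,
                         suv_threshold = 5,
                         uptake_background = 2,
                         uptake_floor = 0.2,
                         true_params = fit_parameters(0.8, 1.5e-4, 0.075),
                         noise_sigma = 0.05,
                         noise_model = c("lognormal", "gaussian"),
                         seed = 1L) {
  noise_model <- match.arg(noise_model)
  spacing <- if (length(spacing) == 1L) rep(as.double(spacing), 3L)
             else as.double(spacing)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 4),
            length(spacing) == 3L, all(spacing > 0),
            is.data.frame(glands), nrow(glands) >= 1L,
            let_baseline >= 0, let_enhancement >= 0,
            abs(dose_let_correlation) <= 1,
            uptake_sd >= 0, noise_sigma >= 0)
  for (b in beams) {
    if (b$plateau_gy < 0 || b$plateau_gy > 80) {
      stop("beam plateau dose must lie in [0, 80] Gy", call. = FALSE)
    }
  }
  mean_eff <- if (!is.null(uptake_frac_above)) {
    suv_threshold + uptake_sd * stats::qnorm(uptake_frac_above)
  } else {
    uptake_mean
  }
  if (mean_eff <= suv_threshold) {
    stop("gland baseline mean SUV must exceed the SUV threshold so adjusted ROIs are non-empty",
         call. = FALSE)
  }
  stopifnot(inherits(true_params, "fit_parameters"))
  structure(list(
    grid_shape = as.integer(grid_shape), spacing = spacing,
    glands = glands, beams = beams,
    let_baseline = as.double(let_baseline),
    let_enhancement = as.double(let_enhancement),
    let_falloff_offset_mm = as.double(let_falloff_offset_mm),
    let_texture_sd = as.double(let_texture_sd),
    dose_let_correlation = as.double(dose_let_correlation),
    uptake_mean = as.double(mean_eff), uptake_sd = as.double(uptake_sd),
    uptake_frac_above = if (is.null(uptake_frac_above)) NULL
                        else as.double(uptake_frac_above),
    suv_threshold = as.double(suv_threshold),
    uptake_background = as.double(uptake_background),
    uptake_floor = as.double(uptake_floor),
    true_params = true_params,
    noise_sigma = as.double(noise_sigma), noise_model = noise_model,
    seed = as.integer(seed)), class = "phantom_spec")
}

# Smooth standardized 3-D noise field (box-filtered white noise), drawn from
# the current RNG stream.
smooth_noise_field <- function(dim, width = 5L, passes = 2L) {
  x <- array(stats::rnorm(prod(dim)), dim)
  k <- rep(1, width) / width
  for (p in seq_len(passes)) {
    for (ax in 1:3) x <- filter_along(x, k, ax)
  }
  (x - mean(x)) / stats::sd(x)
}

filter_along <- function(a, k, axis) {
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  d <- dim(ap)
  m <- matrix(ap, nrow = d[1])
  mf <- stats::filter(m, k, sides = 2, circular = TRUE)
  out <- array(as.numeric(mf), d)
  aperm(out, order(perm))
}

standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < 1e-12) return(rep(0, length(x)))
  (x - mean(x)) / s
}

rescale01 <- function(x) {
  r <- range(x)
  if (!is.finite(r[1]) || (r[2] - r[1]) < 1e-12) {
    return(rep(0.5, length(x)))
  }
  (x - r[1]) / (r[2] - r[1])
}

#' Generate one phantom patient
#'
#' Produces four co-registered volumes on the spec's grid: physical dose
#' (Gy), the D*LET_d product (Gy keV/um), baseline PSMA uptake (SUV) and an
#' integer gland label mask. The dose field is a parametric beam model
#' (plateau with sigmoid distal fall-off, Gaussian lateral profile); LET_d
#' rises at the distal fall-off, and within each gland the dose-LET_d
#' Pearson correlation is steered to `spec$dose_let_correlation` exactly by
#' blending the standardized dose with the dose-orthogonalized LET spatial
#' pattern and rescaling affinely into
#' `[let_baseline, let_baseline + let_enhancement]`.
#'
#' @param spec A [phantom_spec()].
#' @return An object of class `phantom`: a list with arrays `dose`,
#'   `dose_let`, `baseline`, `mask`, plus `let` (the LET_d field used),
#'   `spacing`, `gland_levels` (label integer -> gland name) and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dm <- spec$grid_shape
    sp <- spec$spacing
    ax <- lapply(1:3, function(a) (seq_len(dm[a]) - 1) * sp[a])
    tmpl <- array(0, dm)
    X <- array(ax[[1]][slice.index(tmpl, 1)], dm)
    Y <- array(ax[[2]][slice.index(tmpl, 2)], dm)
    Z <- array(ax[[3]][slice.index(tmpl, 3)], dm)
    extent <- (dm - 1) * sp

    mask <- array(0L, dm)
    for (g in seq_len(nrow(spec$glands))) {
      gg <- spec$glands[g, ]
      if (gg$cx - gg$rx < 0 || gg$cx + gg$rx > extent[1] ||
          gg$cy - gg$ry < 0 || gg$cy + gg$ry > extent[2] ||
          gg$cz - gg$rz < 0 || gg$cz + gg$rz > extent[3]) {
        stop(sprintf("gland '%s' extends outside the grid", gg$gland),
             call. = FALSE)
      }
      inside <- ((X - gg$cx) / gg$rx)^2 + ((Y - gg$cy) / gg$ry)^2 +
        ((Z - gg$cz) / gg$rz)^2 <= 1
      mask[inside] <- g
    }

    dose <- tmpl
    wpat <- tmpl
    wsum <- tmpl
    for (b in spec$beams) {
      co <- switch(b$axis, x = X, y = Y, z = Z)
      lat <- switch(b$axis, x = list(Y, Z), y = list(X, Z), z = list(X, Y))
      prof <- if (b$direction < 0) {
        stats::plogis((co - b$edge_mm) / b$falloff_mm)
      } else {
        stats::plogis((b$edge_mm - co) / b$falloff_mm)
      }
      latf <- exp(-0.5 * ((lat[[1]] - b$lateral_center_mm[1])^2 +
                          (lat[[2]] - b$lateral_center_mm[2])^2) /
                    b$lateral_sigma_mm^2)
      db <- b$plateau_gy * prof * latf
      # LET_d pattern: high just beyond the distal dose edge
      pb <- if (b$direction < 0) {
        stats::plogis((b$edge_mm + spec$let_falloff_offset_mm - co) /
                        (2 * b$falloff_mm))
      } else {
        stats::plogis((co - b$edge_mm + spec$let_falloff_offset_mm) /
                        (2 * b$falloff_mm))
      }
      dose <- dose + db
      wpat <- wpat + (db + 1e-6) * pb
      wsum <- wsum + db + 1e-6
    }
    pattern <- wpat / wsum + spec$let_texture_sd * smooth_noise_field(dm)

    let <- array(spec$let_baseline, dm)
    if (spec$let_enhancement > 0) {
      let <- spec$let_baseline +
        spec$let_enhancement * array(rescale01(pattern), dm)
      r <- spec$dose_let_correlation
      for (g in seq_len(nrow(spec$glands))) {
        idx <- which(mask == g)
        if (length(idx) < 10L) next
        zP <- standardize(pattern[idx])
        zD <- standardize(dose[idx])
        lstar <- if (stats::sd(dose[idx]) > 1e-9) {
          res <- zP - stats::cor(zP, zD) * zD
          if (stats::sd(res) < 1e-9) res <- stats::rnorm(length(idx))
          r * zD + sqrt(1 - r^2) * standardize(res)
        } else {
          zP
        }
        let[idx] <- spec$let_baseline +
          spec$let_enhancement * rescale01(lstar)
      }
    }
    dose_let <- dose * let

    baseline <- array(spec$uptake_background, dm) +
      0.1 * smooth_noise_field(dm)
    ufield <- smooth_noise_field(dm)
    for (g in seq_len(nrow(spec$glands))) {
      idx <- which(mask == g)
      z <- standardize(ufield[idx])
      if (!is.null(spec$uptake_frac_above)) {
        # calibrate the location so the achieved fraction of voxels at or
        # above the SUV threshold matches the configured fraction exactly,
        # whatever the shape of the within-gland field distribution
        q <- stats::quantile(z, 1 - spec$uptake_frac_above, type = 7,
                             names = FALSE)
        baseline[idx] <- spec$suv_threshold +
          spec$uptake_sd * (z - q) + 1e-12
      } else {
        baseline[idx] <- spec$uptake_mean + spec$uptake_sd * z
      }
    }
    baseline <- array(pmax(baseline, spec$uptake_floor), dm)

    structure(list(dose = dose, dose_let = dose_let, baseline = baseline,
                   mask = mask, let = let, spacing = sp,
                   gland_levels = stats::setNames(seq_len(nrow(spec$glands)),
                                                  spec$glands$gland),
                   spec = spec),
              class = "phantom")
  })
}

#' Simulate a follow-up uptake volume from the forward model
#'
#' Applies [predict_followup()] voxel-wise to co-registered baseline, dose
#' and D*LET_d volumes and adds multiplicative lognormal noise:
#' `followup = predicted * exp(eps)`, `eps ~ N(0, noise_sigma^2)` i.i.d. per
#' voxel. With `noise_sigma = 0` the model is reproduced exactly. An
#' additive Gaussian option exists (`noise_model = "gaussian"`), clamped to
#' stay positive.
#'
#' @param baseline,dose,dose_let Co-registered numeric arrays.
#' @param true_params [fit_parameters()] used as ground truth.
#' @param noise_sigma Noise SD (lognormal: SD of log; gaussian: SUV units).
#' @param seed Integer seed (`NULL` = current stream).
#' @param noise_model `"lognormal"` (default) or `"gaussian"`.
#' @return Follow-up uptake array, strictly positive.
#' @export
simulate_followup <- function(baseline, dose, dose_let, true_params,
                              noise_sigma = 0, seed = NULL,
                              noise_model = c("lognormal", "gaussian")) {
  noise_model <- match.arg(noise_model)
  if (!identical(dim(baseline), dim(dose)) ||
      !identical(dim(baseline), dim(dose_let))) {
    stop("volumes are not co-registered: dimensions differ", call. = FALSE)
  }
  let_d <- ifelse(dose > 0, dose_let / dose, 0)
  pred <- predict_followup(baseline, dose, let_d, true_params)
  if (noise_sigma == 0) return(pred)
  with_seed(seed, {
    eps <- stats::rnorm(length(pred), 0, noise_sigma)
    out <- if (noise_model == "lognormal") {
      pred * exp(eps)
    } else {
      pmax(pred + eps, .Machine$double.eps)
    }
    array(out, dim(pred) %||% length(pred))
  })
}

#' Generate a phantom patient cohort
#'
#' Generates `n_patients` independent phantoms from a spec template with
#' distinct derived sub-seeds, simulates each patient's follow-up volume
#' from their ground-truth parameters, and records the truth in a manifest.
#'
#' @param n_patients Number of patients (>= 1).
#' @param spec Template [phantom_spec()]; per-patient specs differ only in
#'   seed and ground-truth parameters.
#' @param true_params_list Optional list of [fit_parameters()], one per
#'   patient; defaults to the template's `true_params` for everyone.
#' @param seed Cohort seed (defaults to the template seed); patient
#'   sub-seeds are derived deterministically from it.
#' @return An object of class `phantom_cohort`: list with `patients` (each
#'   a list of `patient_id`, `phantom`, `followup`, `true_params`, `seed`)
#'   and a `manifest` tibble.
#' @export
make_patient_cohort <- function(n_patients, spec = phantom_spec(),
                                true_params_list = NULL,
                                seed = spec$seed) {
  stopifnot(n_patients >= 1)
  if (is.null(true_params_list)) {
    true_params_list <- rep(list(spec$true_params), n_patients)
  }
  stopifnot(length(true_params_list) == n_patients)
  patients <- vector("list", n_patients)
  for (i in seq_len(n_patients)) {
    sub_seed <- derive_seed(seed, i)
    spec_i <- spec
    spec_i$seed <- sub_seed
    spec_i$true_params <- true_params_list[[i]]
    ph <- generate_phantom(spec_i)
    fu <- simulate_followup(ph$baseline, ph$dose, ph$dose_let,
                            spec_i$true_params,
                            noise_sigma = spec_i$noise_sigma,
                            seed = derive_seed(sub_seed, 1L),
                            noise_model = spec_i$noise_model)
    patients[[i]] <- list(patient_id = sprintf("P%02d", i), phantom = ph,
                          followup = fu,
                          true_params = spec_i$true_params, seed = sub_seed)
  }
  manifest <- tibble::tibble(
    patient_id = vapply(patients, function(p) p$patient_id, character(1)),
    seed = vapply(patients, function(p) p$seed, integer(1)),
    beta0 = vapply(patients, function(p) p$true_params$beta0, double(1)),
    beta1 = vapply(patients, function(p) p$true_params$beta1, double(1)),
    beta2 = vapply(patients, function(p) p$true_params$beta2, double(1)),
    noise_sigma = spec$noise_sigma
  )
  structure(list(patients = patients, manifest = manifest, seed = seed),
            class = "phantom_cohort")
}

#' Simulate flat voxel records without a 3-D grid
#'
#' A lightweight companion to [generate_phantom()] for statistical
#' experiments (parameter recovery, identifiability): draws dose uniformly
#' over `dose_range`, constructs LET_d with a specified Pearson correlation
#' to dose (exact in-sample, by blending the standardized dose with an
#' independent standardized draw and rescaling affinely into `let_range`),
#' draws baseline SUV, and simulates follow-up uptake from the forward model
#' with multiplicative lognormal noise.
#'
#' For a fixed seed, the underlying draws (dose, LET noise, baseline,
#' measurement noise) are identical across values of `dose_let_cor`; only
#' the mixing weight changes. This common-random-numbers design makes
#' comparisons across correlation levels well paired.
#'
#' @param n Number of voxels.
#' @param true_params [fit_parameters()] ground truth.
#' @param dose_range,let_range Ranges for dose (Gy) and LET_d (keV/um).
#' @param dose_let_cor Target dose-LET_d Pearson correlation.
#' @param baseline_mean,baseline_sd Baseline SUV distribution (floored at 5
#'   so the records resemble adjusted-ROI voxels).
#' @param noise_sigma Lognormal noise SD on follow-up uptake.
#' @param patient_id,timepoint,gland Metadata; `gland = NULL` cycles over
#'   all four gland labels.
#' @param seed Integer seed.
#' @return A voxel-record tibble.
#' @export
simulate_voxel_records <- function(n, true_params,
                                   dose_range = c(0, 70),
                                   let_range = c(1, 7),
                                   dose_let_cor = 0,
                                   baseline_mean = 10, baseline_sd = 2,
                                   noise_sigma = 0.05,
                                   patient_id = "SIM",
                                   timepoint = "one_month",
                                   gland = NULL,
                                   seed = NULL) {
  stopifnot(n >= 2, abs(dose_let_cor) <= 1)
  with_seed(seed, {
    dose <- stats::runif(n, dose_range[1], dose_range[2])
    zl <- stats::rnorm(n)
    zb <- stats::rnorm(n)
    eps <- stats::rnorm(n)
    r <- dose_let_cor
    lstar <- r * standardize(dose) + sqrt(1 - r^2) * standardize(zl)
    let_d <- let_range[1] + (let_range[2] - let_range[1]) * rescale01(lstar)
    base <- pmax(baseline_mean + baseline_sd * zb, 5)
    pred <- predict_followup(base, dose, let_d, true_params)
    fu <- pred * exp(noise_sigma * eps)
    gl <- if (is.null(gland)) rep_len(GLANDS, n) else rep_len(gland, n)
    voxel_records(patient_id, timepoint, gl,
                  i = seq_len(n), j = 1L, k = 1L,
                  dose_gy = dose, dose_let_gy_kev_um = dose * let_d,
                  suv_baseline = base, suv_followup = fu)
  })
}
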