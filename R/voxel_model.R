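# Voxel-level response model: exponential PSMA uptake loss with an
# LET_d-dependent RBE weighting of the physical dose.

GLANDS <- c("parotid_L", "parotid_R", "submandibular_L", "submandibular_R")
TIMEPOINTS <- c("one_month", "six_month")
GLAND_SETS <- c("parotid", "submandibular", "combined")

#' Salivary gland labels used throughout the pipeline
#'
#' @return Character vector of the four gland labels: both parotid and both
#'   submandibular glands.
#' @export
gland_labels <- function() GLANDS

#' Members of a gland set
#'
#' Maps an analysis gland set (parotid-only, submandibular-only, or both
#' combined) to the individual gland labels it contains.
#'
#' @param gland_set One of `"parotid"`, `"submandibular"`, `"combined"`.
#' @return Character vector of gland labels.
#' @export
gland_set_members <- function(gland_set) {
  gland_set <- match.arg(gland_set, GLAND_SETS)
  switch(gland_set,
    parotid = GLANDS[1:2],
    submandibular = GLANDS[3:4],
    combined = GLANDS
  )
}

#' Fit parameters of the voxel response model
#'
#' Bundles the three model parameters with fit metadata. `beta0` is a
#' dose-independent scaling of follow-up uptake (dimensionless), `beta1` the
#' radiosensitivity (Gy^-1), and `beta2` the RBE-LET slope ((keV/um)^-1):
#' the fitted model is
#' `PSMA_FU = PSMA_0 * beta0 * exp(-beta1 * Dose * (1 + beta2 * LET_d))`.
#'
#' @param beta0,beta1,beta2 Model parameters (see above).
#' @param gland_set Gland set the parameters refer to.
#' @param timepoint Follow-up timepoint, `"one_month"` or `"six_month"`.
#' @param objective_value Sum of squared residuals at the fit (SUV^2).
#' @param seed Optimizer seed used for the fit.
#' @param converged Logical flag from the optimizer.
#' @param beta2_identifiable `FALSE` when the fitted voxel set had constant
#'   LET_d, in which case `beta2` carries no information.
#' @param patient_id Optional patient identifier.
#' @return An object of class `fit_parameters`.
#' @export
fit_parameters <- function(beta0, beta1, beta2,
                           gland_set = "combined",
                           timepoint = "one_month",
                           objective_value = NA_real_,
                           seed = NA_integer_,
                           converged = NA,
                           beta2_identifiable = NA,
                           patient_id = NA_character_) {
  stopifnot(is.numeric(beta0), is.numeric(beta1), is.numeric(beta2),
            length(beta0) == 1L, length(beta1) == 1L, length(beta2) == 1L)
  gland_set <- match.arg(gland_set, GLAND_SETS)
  timepoint <- match.arg(timepoint, TIMEPOINTS)
  if (!is.na(objective_value) && objective_value < 0) {
    stop("`objective_value` must be non-negative", call. = FALSE)
  }
  structure(
    list(beta0 = as.double(beta0), beta1 = as.double(beta1),
         beta2 = as.double(beta2), gland_set = gland_set,
         timepoint = timepoint, objective_value = as.double(objective_value),
         seed = as.integer(seed), converged = converged,
         beta2_identifiable = beta2_identifiable,
         patient_id = as.character(patient_id)),
    class = "fit_parameters"
  )
}

#' @export
print.fit_parameters <- function(x, ...) {
  cat(sprintf(
    "<fit_parameters> %s / %s%s\n  beta0 = %.4g, beta1 = %.4g Gy^-1, beta2 = %.4g (keV/um)^-1\n",
    x$gland_set, x$timepoint,
    if (is.na(x$patient_id)) "" else paste0(" / ", x$patient_id),
    x$beta0, x$beta1, x$beta2))
  if (!is.na(x$objective_value)) {
    cat(sprintf("  objective (SSE) = %.6g, seed = %s\n",
                x$objective_value, x$seed))
  }
  if (isFALSE(x$beta2_identifiable)) {
    cat("  note: LET_d was constant; beta2 is not identifiable\n")
  }
  invisible(x)
}

# Accept a fit_parameters object or anything with named beta0/beta1/beta2.
as_beta <- function(params) {
  if (inherits(params, "fit_parameters")) {
    return(c(beta0 = params$beta0, beta1 = params$beta1, beta2 = params$beta2))
  }
  p <- unlist(params[c("beta0", "beta1", "beta2")])
  if (length(p) != 3L || any(is.na(names(p)))) {
    stop("`params` must provide beta0, beta1 and beta2", call. = FALSE)
  }
  p
}

#' Predict follow-up PSMA uptake
#'
#' Evaluates `PSMA_0 * beta0 * exp(-beta1 * dose * (1 + beta2 * let_d))`,
#' the voxel-wise forward model for post-treatment uptake. The RBE-weighted
#' dose is `dose * (1 + beta2 * let_d)`, so at `dose = 0` the prediction is
#' `uptake_baseline * beta0` regardless of LET_d.
#'
#' @param uptake_baseline Baseline SUV (g/ml); strictly positive.
#' @param dose Physical dose (Gy); non-negative.
#' @param let_d Dose-weighted LET (keV/um); non-negative.
#' @param params A [fit_parameters()] object or named list with
#'   `beta0`, `beta1`, `beta2`.
#' @return Predicted follow-up SUV; strictly positive. Inputs recycle as in
#'   ordinary R arithmetic, and arrays keep their dimensions.
#' @export
predict_followup <- function(uptake_baseline, dose, let_d, params) {
  stop_if_not_finite(uptake_baseline, "uptake_baseline")
  stop_if_not_finite(dose, "dose")
  stop_if_not_finite(let_d, "let_d")
  if (any(uptake_baseline <= 0)) {
    stop("`uptake_baseline` must be strictly positive", call. = FALSE)
  }
  if (any(dose < 0)) stop("`dose` must be non-negative", call. = FALSE)
  if (any(let_d < 0)) stop("`let_d` must be non-negative", call. = FALSE)
  b <- as_beta(params)
  stop_if_not_finite(b, "params")
  uptake_baseline * b[["beta0"]] *
    exp(-b[["beta1"]] * dose * (1 + b[["beta2"]] * let_d))
}

#' Linear RBE-LET model
#'
#' The fitted response model implies a relative biological effectiveness of
#' the form `RBE = 1 + slope * LET_d`; the intercept is fixed at 1 so that
#' zero-LET protons carry the reference effectiveness.
#'
#' @param slope RBE increase per unit LET_d ((keV/um)^-1).
#' @return An object of class `rbe_model`.
#' @export
rbe_model <- function(slope) {
  stopifnot(is.numeric(slope), length(slope) == 1L, is.finite(slope))
  structure(list(slope = as.double(slope), intercept = 1.0),
            class = "rbe_model")
}

#' Evaluate an RBE-LET model
#'
#' @param model An [rbe_model()] object, or a single numeric slope.
#' @param let_d LET_d values (keV/um); non-negative.
#' @return `1 + slope * let_d`.
#' @export
rbe_at_let <- function(model, let_d) {
  if (is.numeric(model)) model <- rbe_model(model)
  stopifnot(inherits(model, "rbe_model"))
  stop_if_not_finite(let_d, "let_d")
  if (any(let_d < 0)) stop("`let_d` must be non-negative", call. = FALSE)
  model$intercept + model$slope * let_d
}

#' Relative PSMA uptake per voxel
#'
#' Follow-up uptake divided by baseline uptake, the continuous voxel-level
#' damage readout (lower means more secretory-cell loss).
#'
#' @param records A voxel-record table (see [voxel_records()]).
#' @return Numeric vector of follow-up/baseline ratios, one per record.
#' @export
relative_uptake <- function(records) {
  b <- records$suv_baseline
  f <- records$suv_followup
  stop_if_not_finite(b, "suv_baseline")
  stop_if_not_finite(f, "suv_followup")
  if (any(b <= 0)) {
    stop("`suv_baseline` must be strictly positive for relative uptake",
         call. = FALSE)
  }
  f / b
}

#' Derived LET_d of voxel records
#'
#' Voxel tables store physical dose and the exported product D*LET_d;
#' LET_d is derived on access as `dose_let / dose`. Zero-dose voxels are
#' assigned LET_d = 0 (they contribute no dose term to the model, and the
#' ratio would otherwise be 0/0).
#'
#' @param records A voxel-record table.
#' @return Numeric LET_d vector (keV/um).
#' @export
voxel_let_d <- function(records) {
  d <- records$dose_gy
  dl <- records$dose_let_gy_kev_um
  ifelse(d > 0, dl / d, 0)
}

#' Construct a voxel-record table
#'
#' One row per PET voxel: the atomic datum of the analysis, carrying the
#' physical dose, the exported D*LET_d product, baseline and follow-up SUV,
#' gland label, grid indices and patient/timepoint metadata.
#'
#' @param patient_id Patient identifier (recycled).
#' @param timepoint `"one_month"` or `"six_month"` (recycled).
#' @param gland Gland label per voxel (see [gland_labels()]).
#' @param i,j,k Integer grid indices.
#' @param dose_gy Physical dose (Gy), non-negative.
#' @param dose_let_gy_kev_um D*LET_d (Gy keV/um), non-negative.
#' @param suv_baseline Baseline SUV (g/ml), strictly positive.
#' @param suv_followup Follow-up SUV (g/ml), non-negative.
#' @return A tibble with the columns above, validated.
#' @export
voxel_records <- function(patient_id, timepoint, gland, i, j, k,
                          dose_gy, dose_let_gy_kev_um,
                          suv_baseline, suv_followup) {
  out <- tibble::tibble(
    patient_id = as.character(patient_id),
    timepoint = as.character(timepoint),
    gland = as.character(gland),
    i = as.integer(i), j = as.integer(j), k = as.integer(k),
    dose_gy = as.double(dose_gy),
    dose_let_gy_kev_um = as.double(dose_let_gy_kev_um),
    suv_baseline = as.double(suv_baseline),
    suv_followup = as.double(suv_followup)
  )
  validate_voxel_records(out)
}

voxel_record_columns <- function() {
  c("patient_id", "timepoint", "gland", "i", "j", "k",
    "dose_gy", "dose_let_gy_kev_um", "suv_baseline", "suv_followup")
}

validate_voxel_records <- function(records) {
  missing_cols <- setdiff(voxel_record_columns(), names(records))
  if (length(missing_cols)) {
    stop("voxel table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- which(!is.finite(records$dose_gy) | records$dose_gy < 0 |
               !is.finite(records$dose_let_gy_kev_um) |
               records$dose_let_gy_kev_um < 0 |
               !is.finite(records$suv_baseline) | records$suv_baseline <= 0 |
               !is.finite(records$suv_followup) | records$suv_followup < 0)
  if (length(bad)) {
    stop(sprintf(
      "invalid voxel record(s) at row(s) %s: dose and D*LET_d must be non-negative, baseline SUV positive, follow-up SUV non-negative",
      paste(utils::head(bad, 10L), collapse = ", ")), call. = FALSE)
  }
  unknown_tp <- setdiff(unique(records$timepoint), TIMEPOINTS)
  if (length(unknown_tp)) {
    stop("unknown timepoint(s): ", paste(unknown_tp, collapse = ", "),
         call. = FALSE)
  }
  records
}
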