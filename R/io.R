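# File I/O: voxel tables (TSV), volumes (NIfTI-1), fit tables and flat
# key-value run configuration. TSV rather than CSV throughout, so
# decimal-comma locales can never corrupt the numbers; doubles are written
# with 17 significant digits and parsed via strtod, so tables round-trip
# bit-exactly.

#' Write a voxel-record table as TSV
#'
#' Columns: `patient_id`, `timepoint`, `gland`, `i`, `j`, `k`, `dose_gy`,
#' `dose_let_gy_kev_um`, `suv_baseline`, `suv_followup`. Numbers round-trip
#' exactly through [read_voxel_table()].
#'
#' @param records A voxel-record tibble.
#' @param path Output path.
#' @return `records`, invisibly.
#' @export
write_voxel_table <- function(records, path) {
  validate_voxel_records(records)
  out <- records[voxel_record_columns()]
  # 17 significant digits guarantee an exact double round trip
  for (col in c("dose_gy", "dose_let_gy_kev_um", "suv_baseline",
                "suv_followup")) {
    out[[col]] <- sprintf("%.17g", out[[col]])
  }
  readr::write_tsv(out, path)
  invisible(records)
}

#' Read a voxel-record table from TSV
#'
#' Validates the header and every row (non-negative dose and D*LET_d,
#' positive baseline SUV); offending row indices are named in the error.
#'
#' @param path TSV path with the declared header.
#' @return A validated voxel-record tibble (possibly empty).
#' @export
read_voxel_table <- function(path) {
  # suppress readr's column-name chatter; the explicit checks below give a
  # clearer error for malformed tables
  records <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    patient_id = readr::col_character(),
    timepoint = readr::col_character(),
    gland = readr::col_character(),
    i = readr::col_integer(),
    j = readr::col_integer(),
    k = readr::col_integer(),
    dose_gy = readr::col_character(),
    dose_let_gy_kev_um = readr::col_character(),
    suv_baseline = readr::col_character(),
    suv_followup = readr::col_character()
  ), progress = FALSE))
  missing_cols <- setdiff(voxel_record_columns(), names(records))
  if (length(missing_cols)) {
    stop("voxel table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  # convert through strtod for a correctly rounded (exact) round trip
  for (col in c("dose_gy", "dose_let_gy_kev_um", "suv_baseline",
                "suv_followup")) {
    records[[col]] <- as.double(records[[col]])
  }
  validate_voxel_records(records)
}

#' Write a fit table as TSV
#'
#' One row per fit, mirroring the per-patient results-table layout.
#'
#' @param fits A `fit_parameters` or list of them (see [fits_table()]).
#' @param path Output path.
#' @return The tabulated fits, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  tab <- fits_table(fits)
  readr::write_tsv(tab, path)
  invisible(tab)
}

#' Write a 3-D volume as NIfTI-1
#'
#' @param array Numeric 3-D array.
#' @param spacing Voxel spacing in mm (scalar or length-3).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype Storage datatype (default `"double"` so values
#'   round-trip to full precision; use `"int16"` for label masks).
#' @return `path`, invisibly.
#' @export
write_volume <- function(array, spacing, path, datatype = "double") {
  if (length(dim(array)) != 3L) {
    stop("`array` must be a 3-D volume", call. = FALSE)
  }
  spacing <- if (length(spacing) == 1L) rep(as.double(spacing), 3L)
             else as.double(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) ||
      any(spacing <= 0)) {
    stop("`spacing` must be positive (scalar or length-3, mm)",
         call. = FALSE)
  }
  im <- RNifti::asNifti(array)
  RNifti::pixdim(im) <- spacing
  RNifti::writeNifti(im, path, datatype = datatype)
  invisible(path)
}

#' Read a 3-D volume from NIfTI-1
#'
#' @param path NIfTI path.
#' @return List with `data` (plain 3-D array) and `spacing` (length-3 mm).
#' @export
read_volume <- function(path) {
  im <- RNifti::readNifti(path)
  if (length(dim(im)) != 3L) {
    stop(sprintf("'%s' is not a 3-D volume", path), call. = FALSE)
  }
  sp <- RNifti::pixdim(im)
  if (length(sp) < 3L || any(!is.finite(sp[1:3])) || any(sp[1:3] <= 0)) {
    stop(sprintf("'%s' carries no valid voxel spacing", path),
         call. = FALSE)
  }
  list(data = array(as.double(im), dim(im)), spacing = as.double(sp[1:3]))
}

# ---- flat key-value configuration -----------------------------------------

format_config_value <- function(v) {
  if (is.character(v)) {
    vals <- sprintf('"%s"', v)
  } else if (is.logical(v)) {
    vals <- ifelse(v, "true", "false")
  } else {
    vals <- vapply(v, function(x) format(x, digits = 17, scientific = NA),
                   character(1))
  }
  if (length(vals) == 1L) vals else paste0("[", paste(vals, collapse = ", "),
                                           "]")
}

flatten_config <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v)) {
      out <- c(out, flatten_config(v, key))
    } else if (!is.null(v)) {
      out[[key]] <- v
    }
  }
  out
}

unflatten_config <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    out <- insert_nested(out, parts, flat[[key]])
  }
  out
}

insert_nested <- function(x, parts, value) {
  if (length(parts) == 1L) {
    x[[parts]] <- value
    return(x)
  }
  head_part <- parts[1]
  if (is.null(x[[head_part]])) x[[head_part]] <- list()
  x[[head_part]] <- insert_nested(x[[head_part]], parts[-1], value)
  x
}

# Write a flat (possibly nested, dotted-key) key-value config file.
write_flat_config <- function(x, path) {
  flat <- flatten_config(x)
  lines <- vapply(names(flat), function(k) {
    paste0(k, ": ", format_config_value(flat[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Run configuration
#'
#' The serializable knobs of an end-to-end run: global seed, cohort size,
#' scalar phantom parameters, fit settings, CI method and bin widths. The
#' gland geometry and beam arrangement are code-level defaults
#' ([default_gland_geometry()], [default_beams()]), not config entries.
#'
#' @param seed Global seed.
#' @param n_patients Cohort size.
#' @param phantom Named list of scalar overrides for [phantom_spec()]
#'   (e.g. `noise_sigma`, `dose_let_correlation`, `let_enhancement`).
#' @param fit Named list of scalar fit settings (`max_iterations`, `loss`).
#' @param ci_method CI method for [aggregate_slopes()].
#' @param dose_bin_width,dose_let_bin_width,profile_bin_width Binning
#'   widths (Gy, Gy keV/um, Gy).
#' @return A nested list of class `run_config`, losslessly serializable via
#'   [write_run_config()] / [read_run_config()].
#' @export
run_config <- function(seed = 1L, n_patients = 6L,
                       phantom = list(noise_sigma = 0.05,
                                      dose_let_correlation = -0.3,
                                      let_baseline = 1,
                                      let_enhancement = 6,
                                      uptake_mean = 10,
                                      uptake_sd = 2),
                       fit = list(max_iterations = 10000L,
                                  loss = "sse_followup"),
                       ci_method = "t_interval",
                       dose_bin_width = 5.0,
                       dose_let_bin_width = 25.0,
                       profile_bin_width = 2.5) {
  structure(list(seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 phantom = phantom, fit = fit, ci_method = ci_method,
                 dose_bin_width = dose_bin_width,
                 dose_let_bin_width = dose_let_bin_width,
                 profile_bin_width = profile_bin_width),
            class = "run_config")
}

#' Write a run configuration as a flat key-value file
#'
#' Nested entries are flattened with dotted keys (`fit.max_iterations`);
#' the format is YAML-compatible and numbers are written with 17
#' significant digits so the round trip is lossless.
#'
#' @param config A [run_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  write_flat_config(unclass(config), path)
}

#' Read a run configuration from a flat key-value file
#'
#' @param path Config path written by [write_run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  flat <- yaml::read_yaml(path)
  cfg <- unflatten_config(flat)
  cfg$seed <- as.integer(cfg$seed)
  cfg$n_patients <- as.integer(cfg$n_patients)
  if (!is.null(cfg$fit$max_iterations)) {
    cfg$fit$max_iterations <- as.integer(cfg$fit$max_iterations)
  }
  structure(cfg, class = "run_config")
}
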