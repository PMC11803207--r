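# ROI adjustment and voxel-table extraction. The delineated gland masks are
# adjusted to include every voxel whose center lies within a fixed margin of
# the original delineation and whose baseline uptake reaches an SUV
# threshold; per-voxel analysis tables are then extracted from the
# co-registered volumes.

# Integer voxel offsets whose physical displacement is within margin_mm.
ball_offsets <- function(margin_mm, spacing) {
  mi <- pmax(floor(margin_mm / spacing), 0)
  off <- expand.grid(di = -mi[1]:mi[1], dj = -mi[2]:mi[2], dk = -mi[3]:mi[3])
  d2 <- (off$di * spacing[1])^2 + (off$dj * spacing[2])^2 +
    (off$dk * spacing[3])^2
  off[d2 <= margin_mm^2 + 1e-9, , drop = FALSE]
}

# Morphological dilation of a logical 3-D mask with a Euclidean ball:
# equivalent to thresholding the distance from each voxel center to the
# nearest mask voxel center.
dilate_mask <- function(mask, margin_mm, spacing) {
  dm <- dim(mask)
  off <- ball_offsets(margin_mm, spacing)
  out <- array(FALSE, dm)
  for (r in seq_len(nrow(off))) {
    di <- off$di[r]; dj <- off$dj[r]; dk <- off$dk[r]
    si <- max(1, 1 - di):min(dm[1], dm[1] - di)
    sj <- max(1, 1 - dj):min(dm[2], dm[2] - dj)
    sk <- max(1, 1 - dk):min(dm[3], dm[3] - dk)
    out[si + di, sj + dj, sk + dk] <-
      out[si + di, sj + dj, sk + dk] | mask[si, sj, sk]
  }
  out
}

#' Adjust a gland ROI by distance margin and SUV threshold
#'
#' Returns the voxels whose centers lie within `margin_mm` (Euclidean, on
#' the grid) of any voxel center of the original delineation AND whose
#' baseline uptake is at least `suv_threshold` (default 6 mm and
#' 5.0 g/ml). The threshold applies to all candidate voxels, including those
#' inside the original delineation, so low-uptake interior voxels are
#' excluded as well. Membership is decided at voxel centers; there is no
#' partial-volume weighting. Deterministic.
#'
#' @param mask Logical or 0/1 3-D array: the original delineation.
#' @param baseline Baseline uptake volume (SUV), co-registered with `mask`.
#' @param margin_mm Dilation margin in mm (>= 0).
#' @param suv_threshold Minimum baseline SUV (g/ml).
#' @param spacing Voxel spacing in mm (scalar or length-3).
#' @param gland Gland label stored in the result.
#' @return An object of class `gland_roi`: list with `gland`,
#'   `voxel_indices` (sorted linear indices into the grid), `dim`,
#'   `margin_mm`, `suv_threshold` and `source = "adjusted"`. An empty
#'   original mask yields a warning and an empty ROI.
#' @export
adjust_roi <- function(mask, baseline, margin_mm = 6.0, suv_threshold = 5.0,
                       spacing = 2, gland = "gland") {
  stopifnot(margin_mm >= 0)
  spacing <- if (length(spacing) == 1L) rep(as.double(spacing), 3L)
             else as.double(spacing)
  m <- mask != 0
  if (!identical(dim(m), dim(baseline))) {
    stop("mask and baseline volume are not co-registered: dimensions differ",
         call. = FALSE)
  }
  if (!any(m)) {
    warning(sprintf("original delineation of '%s' is empty; adjusted ROI is empty",
                    gland), call. = FALSE)
    return(structure(list(gland = gland, voxel_indices = integer(0),
                          dim = dim(m), margin_mm = margin_mm,
                          suv_threshold = suv_threshold,
                          source = "adjusted"),
                     class = "gland_roi"))
  }
  candidate <- dilate_mask(m, margin_mm, spacing)
  adjusted <- candidate & (baseline >= suv_threshold)
  structure(list(gland = gland,
                 voxel_indices = which(adjusted),
                 dim = dim(m), margin_mm = margin_mm,
                 suv_threshold = suv_threshold, source = "adjusted"),
            class = "gland_roi")
}

#' @export
print.gland_roi <- function(x, ...) {
  cat(sprintf("<gland_roi> %s: %d voxels (margin %.1f mm, SUV >= %.1f)\n",
              x$gland, length(x$voxel_indices), x$margin_mm,
              x$suv_threshold))
  invisible(x)
}

#' Adjusted ROIs for every gland of a phantom
#'
#' Convenience wrapper applying [adjust_roi()] to each label of a phantom's
#' gland mask.
#'
#' @param phantom A `phantom` from [generate_phantom()].
#' @param margin_mm,suv_threshold As in [adjust_roi()].
#' @return Named list of `gland_roi` objects.
#' @export
gland_rois <- function(phantom, margin_mm = 6.0, suv_threshold = 5.0) {
  out <- lapply(names(phantom$gland_levels), function(g) {
    adjust_roi(phantom$mask == phantom$gland_levels[[g]], phantom$baseline,
               margin_mm = margin_mm, suv_threshold = suv_threshold,
               spacing = phantom$spacing, gland = g)
  })
  stats::setNames(out, names(phantom$gland_levels))
}

#' Extract the per-voxel analysis table
#'
#' Exports dose, D*LET_d, baseline and follow-up uptake for every
#' adjusted-ROI voxel of every gland, one record per voxel per gland, in
#' deterministic grid-scan order (first index fastest). Volumes must be
#' pre-aligned: the pipeline accepts externally resampled volumes but does
#' no registration itself. A voxel contained in several gland ROIs is
#' assigned to each of them, with a warning (anatomical glands are
#' disjoint, so overlap indicates a delineation problem).
#'
#' @param rois A `gland_roi` or list of them.
#' @param dose,dose_let,baseline,followup Co-registered volumes.
#' @param patient_id,timepoint Metadata stamped on every record.
#' @return A voxel-record tibble (see [voxel_records()]).
#' @export
extract_voxel_table <- function(rois, dose, dose_let, baseline, followup,
                                patient_id, timepoint = "one_month") {
  if (inherits(rois, "gland_roi")) rois <- list(rois)
  dm <- dim(dose)
  for (v in list(dose_let = dose_let, baseline = baseline,
                 followup = followup)) {
    if (!identical(dim(v), dm)) {
      stop("volumes are not co-registered: dimensions differ", call. = FALSE)
    }
  }
  for (roi in rois) {
    if (!identical(roi$dim, dm)) {
      stop("ROI grid does not match the volumes: dimensions differ",
           call. = FALSE)
    }
  }
  all_idx <- unlist(lapply(rois, function(r) r$voxel_indices))
  if (anyDuplicated(all_idx)) {
    warning(sprintf("%d voxel(s) belong to more than one gland ROI",
                    sum(duplicated(all_idx))), call. = FALSE)
  }
  pieces <- lapply(rois, function(roi) {
    ind <- sort(roi$voxel_indices)
    if (length(ind) == 0L) return(NULL)
    ijk <- arrayInd(ind, dm)
    voxel_records(patient_id, timepoint, roi$gland,
                  i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                  dose_gy = dose[ind], dose_let_gy_kev_um = dose_let[ind],
                  suv_baseline = baseline[ind], suv_followup = followup[ind])
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    return(voxel_records(character(0), character(0), character(0),
                         integer(0), integer(0), integer(0),
                         double(0), double(0), double(0), double(0)))
  }
  dplyr::bind_rows(pieces)
}

#' Extract the voxel table of a whole phantom patient
#'
#' Runs the ROI-adjustment rule on every gland of a phantom and extracts
#' the per-voxel analysis table against a simulated follow-up volume.
#'
#' @param phantom A `phantom`.
#' @param followup Follow-up uptake volume (e.g. [simulate_followup()]).
#' @param patient_id,timepoint Metadata.
#' @param margin_mm,suv_threshold ROI-adjustment parameters.
#' @return A voxel-record tibble.
#' @export
phantom_voxel_table <- function(phantom, followup, patient_id = "P01",
                                timepoint = "one_month",
                                margin_mm = 6.0, suv_threshold = 5.0) {
  rois <- gland_rois(phantom, margin_mm = margin_mm,
                     suv_threshold = suv_threshold)
  extract_voxel_table(rois, phantom$dose, phantom$dose_let,
                      phantom$baseline, followup,
                      patient_id = patient_id, timepoint = timepoint)
}
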