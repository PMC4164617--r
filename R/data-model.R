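#' @keywords internal
"_PACKAGE"

## Error helpers: every user-facing failure is a classed condition so callers
## (and the pipeline's failure manifest) can distinguish bad inputs from bugs.

stop_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dwi_validation_error", "dwi_error")))
}

stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dwi_format_error", "dwi_error")))
}

stop_degenerate <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("dwi_degenerate_error", "dwi_error")))
}

#' Multi-b-value diffusion-weighted imaging study
#'
#' Container for one DWI session: a stack of 3D magnitude volumes, one per
#' diffusion weighting, together with the b-value list and voxel geometry.
#' Volumes are stored in a 4D array with axis order (x, y, slice, b-index)
#' and are always kept sorted by ascending b-value.
#'
#' @param volumes 4D numeric array (x, y, slice, b) of non-negative signal
#'   intensities, or a list of equally sized 3D arrays (one per b-value).
#' @param bvalues Numeric vector of diffusion weightings in s/mm^2, strictly
#'   increasing and all positive (the pipeline assumes no b = 0 acquisition;
#'   the fitted S0 is extrapolated).
#' @param voxel_size Length-2 numeric, in-plane voxel spacing in mm.
#' @param slice_thickness Slice thickness in mm.
#' @param slice_gap Gap between slices in mm (>= 0).
#' @param study_id Free-text identifier.
#'
#' @return An object of class `dwi_study`.
#' @export
dwi_study <- function(volumes, bvalues, voxel_size = c(1, 1),
                      slice_thickness = 2, slice_gap = 0.4,
                      study_id = "study") {
  if (is.list(volumes)) {
    dims <- lapply(volumes, dim)
    if (length(unique(lapply(dims, as.integer))) != 1L)
      stop_validation("all volumes must share identical dimensions")
    volumes <- array(unlist(volumes, use.names = FALSE),
                     dim = c(dims[[1]], length(volumes)))
  }
  if (length(dim(volumes)) != 4L)
    stop_validation("volumes must be a 4D array or list of 3D arrays")
  bvalues <- as.numeric(bvalues)
  if (dim(volumes)[4] != length(bvalues))
    stop_format("number of volumes (%d) does not match number of b-values (%d)",
                dim(volumes)[4], length(bvalues))
  if (anyDuplicated(bvalues))
    stop_validation("duplicate b-values are not supported")
  if (any(bvalues <= 0))
    stop_validation("all b-values must be > 0")
  ord <- order(bvalues)
  bvalues <- bvalues[ord]
  volumes <- volumes[, , , ord, drop = FALSE]
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 2L)
  if (any(voxel_size <= 0) || slice_thickness <= 0 || slice_gap < 0)
    stop_validation("voxel_size and slice_thickness must be > 0, slice_gap >= 0")
  structure(list(volumes = volumes, bvalues = bvalues,
                 voxel_size = voxel_size, slice_thickness = slice_thickness,
                 slice_gap = slice_gap, study_id = as.character(study_id)),
            class = "dwi_study")
}

#' @export
print.dwi_study <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("DWI study '%s': %dx%dx%d voxels, %d b-values (%s s/mm^2)\n",
              x$study_id, d[1], d[2], d[3], d[4],
              paste(x$bvalues, collapse = ", ")))
  cat(sprintf("  voxel %.3g x %.3g mm, slice %.3g mm + %.3g mm gap\n",
              x$voxel_size[1], x$voxel_size[2], x$slice_thickness, x$slice_gap))
  invisible(x)
}

#' Voxelwise apparent diffusion coefficient map
#'
#' @param values 3D array of ADC in units of 1e-3 mm^2/s (so free water is
#'   about 3). Voxels where the fit failed carry `NA`.
#' @param s0 3D array of fitted S0 (signal units), `NA` where invalid.
#' @param valid 3D logical array: `TRUE` where the fit converged.
#' @param voxel_size,slice_thickness,slice_gap Geometry in mm.
#'
#' @return An object of class `adc_map`.
#' @export
adc_map <- function(values, s0, valid, voxel_size = c(1, 1),
                    slice_thickness = 2, slice_gap = 0.4) {
  if (!identical(dim(values), dim(s0)) || !identical(dim(values), dim(valid)))
    stop_validation("values, s0 and valid must share dimensions")
  storage.mode(valid) <- "logical"
  values[!valid] <- NA_real_
  s0[!valid] <- NA_real_
  structure(list(values = values, s0 = s0, valid = valid,
                 voxel_size = as.numeric(voxel_size),
                 slice_thickness = slice_thickness, slice_gap = slice_gap),
            class = "adc_map")
}

#' @export
print.adc_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("ADC map %dx%dx%d, %d/%d valid voxels, median %.3f x1e-3 mm^2/s\n",
              d[1], d[2], d[3], sum(x$valid), length(x$valid),
              stats::median(x$values[x$valid])))
  invisible(x)
}

#' Binary 3D volume of interest
#'
#' A tumor mask sharing the geometry of the image it annotates.
#'
#' @param mask 3D logical (or strictly 0/1) array.
#' @param voxel_size Length-2 in-plane spacing, mm.
#' @param slice_thickness,slice_gap Through-plane geometry, mm.
#'
#' @return An object of class `voi_mask`.
#' @export
voi_mask <- function(mask, voxel_size = c(1, 1), slice_thickness = 2,
                     slice_gap = 0.4) {
  if (length(dim(mask)) != 3L)
    stop_validation("mask must be a 3D array")
  if (!is.logical(mask)) {
    if (!all(mask %in% c(0, 1)))
      stop_validation("mask voxels must be strictly 0/1")
    mask <- array(mask == 1, dim = dim(mask))
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 2L)
  if (any(voxel_size <= 0) || slice_thickness <= 0 || slice_gap < 0)
    stop_validation("invalid mask geometry")
  structure(list(mask = mask, voxel_size = voxel_size,
                 slice_thickness = slice_thickness, slice_gap = slice_gap),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  d <- dim(x$mask)
  cat(sprintf("VOI mask %dx%dx%d, %d voxels set (%.1f mm^3)\n",
              d[1], d[2], d[3], sum(x$mask), mask_volume(x)))
  invisible(x)
}

#' Assemble a per-animal cohort table
#'
#' One row per animal with baseline/follow-up tumor ADC (units 1e-3 mm^2/s)
#' and volume (mm^3). Change metrics are recomputed from the four base
#' fields: `d_adc = adc_f - adc_b` (absolute) and
#' `d_vol_pct = 100 * (vol_f - vol_b) / vol_b` (percent of baseline).
#'
#' @param animal_id Character vector of unique identifiers.
#' @param group Character/factor vector with levels "therapy" and "control".
#' @param adc_b,adc_f Baseline/follow-up median tumor ADC, 1e-3 mm^2/s, > 0.
#' @param vol_b,vol_f Baseline/follow-up tumor volume, mm^3, > 0.
#' @param provenance Free-text data source tag.
#'
#' @return A `data.frame` of class `cohort_table` with columns `animal_id`,
#'   `group`, `adc_b`, `adc_f`, `vol_b`, `vol_f`, `d_adc`, `d_vol_pct`.
#' @export
cohort_table <- function(animal_id, group, adc_b, adc_f, vol_b, vol_f,
                         provenance = "constructed") {
  group <- as.character(group)
  bad <- setdiff(unique(group), c("therapy", "control"))
  if (length(bad))
    stop_validation("unknown group label(s): %s", paste(bad, collapse = ", "))
  if (anyDuplicated(animal_id))
    stop_validation("animal_ids must be unique")
  if (any(vol_b <= 0) || any(vol_f <= 0))
    stop_validation("volumes must be > 0")
  if (any(adc_b <= 0) || any(adc_f <= 0))
    stop_validation("ADC values must be > 0")
  df <- data.frame(animal_id = as.character(animal_id), group = group,
                   adc_b = as.numeric(adc_b), adc_f = as.numeric(adc_f),
                   vol_b = as.numeric(vol_b), vol_f = as.numeric(vol_f),
                   stringsAsFactors = FALSE)
  df$d_adc <- df$adc_f - df$adc_b
  df$d_vol_pct <- 100 * (df$vol_f - df$vol_b) / df$vol_b
  attr(df, "provenance") <- provenance
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("Cohort: %d animals (%d therapy, %d control) [%s]\n",
              nrow(x), sum(x$group == "therapy"), sum(x$group == "control"),
              attr(x, "provenance")))
  print.data.frame(x, ...)
  invisible(x)
}

## internal: geometry of a study/map/mask as a comparable list
geometry_of <- function(x) {
  list(voxel_size = as.numeric(x$voxel_size),
       slice_thickness = as.numeric(x$slice_thickness),
       slice_gap = as.numeric(x$slice_gap))
}
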