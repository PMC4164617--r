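#' Median tumor ADC inside a VOI
#'
#' The representative tumor ADC is the median of the ADC distribution over
#' the valid voxels inside the mask (invalid fits are excluded, not
#' zero-filled). With an even voxel count the mean of the two central order
#' statistics is returned.
#'
#' @param map An [adc_map()].
#' @param mask A [voi_mask()] with the same grid dimensions.
#' @return Median ADC in 1e-3 mm^2/s.
#' @export
median_adc <- function(map, mask) {
  if (!identical(dim(map$values), dim(mask$mask)))
    stop_validation("mask dimensions do not match ADC map")
  if (!any(mask$mask))
    stop_degenerate("empty VOI")
  vals <- map$values[mask$mask & map$valid]
  if (length(vals) == 0)
    stop_degenerate("VOI contains no valid ADC voxels")
  stats::median(vals)
}

#' Voxel-count tumor volume of a VOI
#'
#' `count * voxel_x * voxel_y * (slice_thickness + slice_gap)` in mm^3; each
#' voxel is credited with its share of the inter-slice gap, so a gapless
#' acquisition reduces to count times the voxel volume.
#'
#' @param mask A [voi_mask()].
#' @return Volume in mm^3 (0 with a warning for an empty mask).
#' @export
mask_volume <- function(mask) {
  n <- sum(mask$mask)
  if (n == 0) warning("empty mask: volume is 0")
  n * mask$voxel_size[1] * mask$voxel_size[2] *
    (mask$slice_thickness + mask$slice_gap)
}

#' Relative change in percent of baseline
#'
#' @param baseline Positive baseline value.
#' @param followup Follow-up value.
#' @return `100 * (followup - baseline) / baseline`.
#' @export
relative_change <- function(baseline, followup) {
  if (any(baseline <= 0))
    stop_validation("baseline must be > 0")
  100 * (followup - baseline) / baseline
}

#' Caliper tumor volume
#'
#' The standard three-axis caliper estimate `a * b * c * 0.5` (mm^3), used
#' to track xenograft growth before imaging.
#'
#' @param a,b,c Tumor dimensions in mm, all > 0.
#' @return Volume in mm^3.
#' @export
caliper_volume <- function(a, b, c) {
  if (any(c(a, b, c) <= 0))
    stop_validation("caliper dimensions must be > 0")
  a * b * c * 0.5
}

#' Build a cohort table from per-animal session measurements
#'
#' Assembles per-animal baseline/follow-up measurements into a
#' [cohort_table()], deriving `d_adc` (absolute) and `d_vol_pct` (percent of
#' baseline). Any missing session value is a validation error. Group-level
#' change summaries must always be computed on these per-animal deltas — the
#' median of per-animal changes is not the change of group medians.
#'
#' @param animal_id,group Identifiers and group labels ("therapy"/"control").
#' @param adc_b,adc_f Baseline/follow-up median tumor ADC (1e-3 mm^2/s).
#' @param vol_b,vol_f Baseline/follow-up tumor volume (mm^3).
#' @param provenance Free-text source tag.
#' @return A [cohort_table()].
#' @export
build_records <- function(animal_id, group, adc_b, adc_f, vol_b, vol_f,
                          provenance = "measured") {
  vals <- list(adc_b = adc_b, adc_f = adc_f, vol_b = vol_b, vol_f = vol_f)
  n <- length(animal_id)
  for (nm in names(vals)) {
    if (length(vals[[nm]]) != n || any(is.na(vals[[nm]])))
      stop_validation("missing or incomplete session measurement: %s", nm)
  }
  cohort_table(animal_id, group, adc_b, adc_f, vol_b, vol_f,
               provenance = provenance)
}
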