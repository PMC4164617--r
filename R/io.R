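#' Read a DWI study from NIfTI plus a b-value sidecar
#'
#' The image must be a 4D NIfTI volume with one 3D sub-volume per b-value.
#' The sidecar is either an FSL-style whitespace-separated `.bval` text file
#' or a JSON file with a `bvalues` field (a bare JSON array also works).
#' Volumes are reordered to ascending b-value on read, so on-disk ordering
#' does not matter.
#'
#' @param image_path Path to a `.nii`/`.nii.gz` 4D image.
#' @param bvalue_path Path to the b-value sidecar.
#' @param study_id Identifier; defaults to the image file name.
#'
#' @return A [dwi_study()].
#' @export
read_dwi_study <- function(image_path, bvalue_path,
                           study_id = basename(image_path)) {
  img <- RNifti::readNifti(image_path)
  if (length(dim(img)) != 4L)
    stop_format("expected a 4D image, got %d dimensions", length(dim(img)))
  bvalues <- read_bvalues(bvalue_path)
  if (length(bvalues) != dim(img)[4])
    stop_format("sidecar lists %d b-values but image has %d volumes",
                length(bvalues), dim(img)[4])
  pd <- RNifti::pixdim(img)
  dwi_study(volumes = array(as.numeric(img), dim = dim(img)),
            bvalues = bvalues,
            voxel_size = pd[1:2], slice_thickness = pd[3], slice_gap = 0,
            study_id = study_id)
}

read_bvalues <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    parsed <- jsonlite::read_json(path, simplifyVector = TRUE)
    b <- if (is.list(parsed) && !is.null(parsed$bvalues)) parsed$bvalues else parsed
    return(as.numeric(unlist(b)))
  }
  as.numeric(scan(path, what = numeric(), quiet = TRUE))
}

#' Write a DWI study as NIfTI plus sidecars
#'
#' Writes the 4D image, an FSL-style `.bval` text sidecar and a JSON sidecar
#' carrying b-values and geometry. Numeric text is written with 12
#' significant digits so a read-back round-trips the b-values.
#'
#' @param study A [dwi_study()].
#' @param image_path Output `.nii`/`.nii.gz` path; sidecars are written next
#'   to it with `.bval` and `.json` extensions.
#' @return Invisibly, the image path.
#' @export
write_dwi_study <- function(study, image_path) {
  arr <- study$volumes
  attr(arr, "pixdim") <- c(study$voxel_size, study$slice_thickness, 1)
  RNifti::writeNifti(RNifti::asNifti(arr), image_path)
  base <- sub("\\.nii(\\.gz)?$", "", image_path)
  writeLines(paste(format(study$bvalues, digits = 12, trim = TRUE),
                   collapse = " "), paste0(base, ".bval"))
  jsonlite::write_json(list(bvalues = study$bvalues,
                            voxel_size = study$voxel_size,
                            slice_thickness = study$slice_thickness,
                            slice_gap = study$slice_gap,
                            study_id = study$study_id),
                       paste0(base, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' Read or write a binary VOI mask as NIfTI
#'
#' Mask voxels must be strictly 0/1 on disk.
#'
#' @param path NIfTI path.
#' @param slice_gap Gap between slices in mm; NIfTI does not carry it, so it
#'   is supplied by the caller (default 0).
#' @return A [voi_mask()].
#' @export
read_voi_mask <- function(path, slice_gap = 0) {
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop_format("expected a 3D mask, got %d dimensions", length(dim(img)))
  pd <- RNifti::pixdim(img)
  voi_mask(array(as.numeric(img), dim = dim(img)),
           voxel_size = pd[1:2], slice_thickness = pd[3],
           slice_gap = slice_gap)
}

#' @rdname read_voi_mask
#' @param mask A [voi_mask()] to write.
#' @export
write_voi_mask <- function(mask, path) {
  arr <- array(as.integer(mask$mask), dim = dim(mask$mask))
  attr(arr, "pixdim") <- c(mask$voxel_size, mask$slice_thickness)
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "uint8")
  invisible(path)
}

#' Write an ADC map as NIfTI with a JSON provenance sidecar
#'
#' Values are stored as float32 in units of 1e-3 mm^2/s; invalid voxels are
#' NaN on disk. The sidecar records the b-values and fit settings used.
#'
#' @param map An [adc_map()].
#' @param path Output NIfTI path.
#' @param provenance Named list merged into the JSON sidecar (b-values,
#'   bounds, registration settings, ...).
#' @return Invisibly, `path`.
#' @export
write_adc_map <- function(map, path, provenance = list()) {
  arr <- map$values
  attr(arr, "pixdim") <- c(map$voxel_size, map$slice_thickness)
  RNifti::writeNifti(RNifti::asNifti(arr), path, datatype = "float")
  base <- sub("\\.nii(\\.gz)?$", "", path)
  meta <- c(list(units = "1e-3 mm^2/s", n_valid = sum(map$valid),
                 slice_gap = map$slice_gap), provenance)
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Expects header columns `animal_id, group, adc_b, adc_f, vol_b, vol_f`;
#' columns `d_adc` and `d_vol_pct` are optional. When present they are
#' cross-checked against recomputation from the base fields (relative
#' tolerance 1e-6) and a mismatch is a consistency error; when absent they
#' are computed. Numerics use '.' as decimal separator.
#'
#' @param path CSV path.
#' @return A [cohort_table()].
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("animal_id", "group", "adc_b", "adc_f", "vol_b", "vol_f")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop_format("cohort CSV missing column(s): %s",
                paste(missing, collapse = ", "))
  tab <- cohort_table(df$animal_id, df$group, df$adc_b, df$adc_f,
                      df$vol_b, df$vol_f, provenance = path)
  for (col in c("d_adc", "d_vol_pct")) {
    if (!col %in% names(df)) next
    got <- as.numeric(df[[col]])
    want <- tab[[col]]
    rel <- abs(got - want) / pmax(abs(want), 1)
    if (any(rel > 1e-6))
      stop_validation("column %s disagrees with recomputation from base fields (max rel. err %.2g)",
                      col, max(rel))
  }
  tab
}

#' Write a cohort table to CSV
#'
#' Numerics are written with 12 significant digits so that a read-back
#' reproduces all fields to text precision.
#'
#' @param cohort A [cohort_table()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_cohort_csv <- function(cohort, path) {
  out <- as.data.frame(cohort)
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 12, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Import a supplementary-style XLSX cohort sheet
#'
#' Helper for per-animal workbooks laid out one row per animal with the same
#' columns as the CSV format. Requires the readxl package.
#'
#' @param path XLSX path.
#' @param sheet Sheet name or index (default first).
#' @return A [cohort_table()].
#' @export
read_cohort_xlsx <- function(path, sheet = 1) {
  if (!requireNamespace("readxl", quietly = TRUE))
    stop("the readxl package is required for XLSX import")
  df <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(df, tmp, row.names = FALSE)
  read_cohort_csv(tmp)
}
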