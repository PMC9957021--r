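#' CT volume container
#'
#' A minimal in-memory CT volume: a 3-D array of Hounsfield units plus the
#' voxel spacing. The third array axis is, by convention, the axial
#' (superior-inferior) direction; annotations index slices along it.
#' Voxel coordinates are 0-based throughout the ROI interface.
#'
#' @param data 3-D numeric array of HU values.
#' @param spacing Voxel spacing in mm, length 3, all positive.
#' @param orientation Axis orientation label (informational), default
#'   `"LPS"`.
#' @return A `ct_volume` object.
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1), orientation = "LPS") {
  if (!is.array(data) || length(dim(data)) != 3) {
    abort("`data` must be a 3-D array.", class = "tcmbmd_domain_error")
  }
  if (any(!is.finite(data))) {
    abort("CT volume contains non-finite HU values.",
          class = "tcmbmd_domain_error")
  }
  check_number(spacing, "spacing", positive = TRUE)
  if (length(spacing) != 3) {
    abort("`spacing` must have length 3.", class = "tcmbmd_domain_error")
  }
  structure(list(data = data, spacing = as.numeric(spacing),
                 orientation = orientation),
            class = "ct_volume")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume>  %s voxels, spacing %s mm, HU range [%.0f, %.0f]\n",
              paste(dim(x$data), collapse = " x "),
              paste(signif(x$spacing, 3), collapse = " x "),
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Load a CT volume from NIfTI
#'
#' Reads a `.nii`/`.nii.gz` file; voxel values are taken as already being
#' in Hounsfield units (NIfTI stores any scaling in its header, which
#' RNifti applies on read). Anisotropic spacing is preserved. DICOM series
#' directories are not supported by this build; DICOM stored values can be
#' converted with [hu_rescale()] once read by an external tool.
#'
#' @param path Path to a NIfTI file.
#' @return A [ct_volume()].
#' @export
load_ct_volume <- function(path) {
  if (dir.exists(path)) {
    abort(paste("Directory input (DICOM series) is not supported;",
                "convert the series to NIfTI first."),
          class = "tcmbmd_io_error")
  }
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "tcmbmd_io_error")
  }
  img <- RNifti::readNifti(path)
  spacing <- attr(img, "pixdim")[1:3]
  ct_volume(array(as.numeric(img), dim = dim(img)), spacing = spacing)
}

#' @param volume A [ct_volume()].
#' @rdname load_ct_volume
#' @export
write_ct_volume <- function(volume, path) {
  stopifnot(inherits(volume, "ct_volume"))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' DICOM rescale to Hounsfield units
#'
#' Applies the standard modality rescale: `HU = slope * stored + intercept`.
#' Both tags are mandatory for CT; a missing value errors rather than
#' passing raw stored values through silently.
#'
#' @param stored Stored pixel values.
#' @param slope,intercept Rescale slope and intercept from the DICOM
#'   header.
#' @return Values in HU.
#' @export
#' @examples
#' hu_rescale(1024, slope = 1, intercept = -1024) # 0 HU
hu_rescale <- function(stored, slope, intercept) {
  if (is.null(slope) || is.null(intercept) ||
      any(is.na(slope)) || any(is.na(intercept))) {
    abort("Missing rescale slope/intercept; refusing to pass raw values.",
          class = "tcmbmd_io_error")
  }
  check_number(stored, "stored")
  slope * stored + intercept
}

#' Elliptical ROI on an axial slice
#'
#' @param slice 0-based axial slice index (third volume axis).
#' @param cx,cy Ellipse center, 0-based voxel coordinates on the first two
#'   volume axes.
#' @param a,b Semi-axes in voxel units, both positive.
#' @return An `ellipse_roi` object.
#' @export
ellipse_roi <- function(slice, cx, cy, a, b) {
  check_number(c(slice, cx, cy), "slice/cx/cy")
  check_number(a, "a", positive = TRUE)
  check_number(b, "b", positive = TRUE)
  structure(list(slice = as.integer(slice), cx = cx, cy = cy, a = a, b = b),
            class = "ellipse_roi")
}

#' Median cross-section of a vertebral body
#'
#' The mid-slice of an axial index range, mirroring the protocol of
#' picking the cross-section through the center of the vertebral body on
#' the sagittal view. For an even-length range the lower of the two middle
#' indices is returned.
#'
#' @param z_range Integer vector `c(lo, hi)` of 0-based axial indices,
#'   inclusive, `lo <= hi`.
#' @return The middle axial index.
#' @export
#' @examples
#' median_cross_section(c(10, 20)) # 15
#' median_cross_section(c(10, 11)) # 10
median_cross_section <- function(z_range) {
  check_number(z_range, "z_range")
  if (length(z_range) != 2 || z_range[2] < z_range[1]) {
    abort("`z_range` must be c(lo, hi) with lo <= hi.",
          class = "tcmbmd_domain_error")
  }
  as.integer(z_range[1] + (z_range[2] - z_range[1]) %/% 2)
}

#' Mean CT number inside an elliptical ROI
#'
#' Averages the voxels of one axial slice whose centers satisfy
#' `((x - cx)/a)^2 + ((y - cy)/b)^2 <= 1`. The voxel-center inclusion rule
#' is deterministic and makes the included count monotone in each
#' semi-axis; partial-volume weighting is deliberately not attempted.
#'
#' @param volume A [ct_volume()].
#' @param roi An [ellipse_roi()].
#' @return A list with `mean_hu` and `n_voxels` (returned for
#'   noise-propagation estimates).
#' @export
elliptical_roi_mean <- function(volume, roi) {
  stopifnot(inherits(volume, "ct_volume"), inherits(roi, "ellipse_roi"))
  dims <- dim(volume$data)
  if (roi$slice < 0 || roi$slice >= dims[3]) {
    abort("ROI slice lies outside the volume.", class = "tcmbmd_domain_error")
  }
  slice <- volume$data[, , roi$slice + 1]
  x <- seq_len(dims[1]) - 1
  y <- seq_len(dims[2]) - 1
  inside <- outer(((x - roi$cx) / roi$a)^2, ((y - roi$cy) / roi$b)^2, "+") <= 1
  n <- sum(inside)
  if (n == 0) {
    abort("Elliptical ROI contains no voxel centers.",
          class = "tcmbmd_empty_roi")
  }
  list(mean_hu = mean(slice[inside]), n_voxels = n)
}

#' Read vertebra annotations
#'
#' Annotation JSON format: an object with `subject` and `vertebrae`, the
#' latter an array of `{vertebra, z_range: [lo, hi], ellipse: {cx, cy, a,
#' b}}` with 0-based voxel coordinates. Manual ROI drawing is replaced by
#' this explicit, reproducible file format.
#'
#' @param path Path to an annotation JSON file.
#' @return A tibble with columns `subject`, `vertebra`, `z_lo`, `z_hi`,
#'   `cx`, `cy`, `a`, `b`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Annotation file not found: %s", path),
          class = "tcmbmd_io_error")
  }
  ann <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  if (is.null(ann$vertebrae)) {
    abort("Annotation file lacks a `vertebrae` array.",
          class = "tcmbmd_io_error")
  }
  purrr::map_dfr(ann$vertebrae, function(v) {
    tibble::tibble(
      subject = ann$subject %||% NA_character_,
      vertebra = v$vertebra,
      z_lo = v$z_range[[1]], z_hi = v$z_range[[2]],
      cx = v$ellipse$cx, cy = v$ellipse$cy,
      a = v$ellipse$a, b = v$ellipse$b
    )
  })
}

#' Measure vBMD of annotated vertebrae
#'
#' For each annotated vertebra: picks the median axial cross-section of
#' the vertebral body, averages the trabecular CT number inside the
#' elliptical ROI, and converts it to BVF and vBMD under the calibration.
#' The conventional targets are L1-L4; a subset is accepted with a
#' warning.
#'
#' @param volume A [ct_volume()].
#' @param annotations Tibble as returned by [read_annotations()], or a
#'   path to an annotation JSON file.
#' @param calib A [reference_calibration()].
#' @param clamp Clamp BVF to `[0, 1]`? See [measure_vbmd()].
#' @return A tibble with one row per vertebra: `subject`, `vertebra`,
#'   `slice`, `mean_hu`, `n_voxels`, `bvf`, `vbmd`, `clamped`.
#' @export
measure_vertebrae <- function(volume, annotations, calib, clamp = FALSE) {
  stopifnot(inherits(volume, "ct_volume"))
  if (is.character(annotations)) {
    annotations <- read_annotations(annotations)
  }
  missing <- setdiff(c("L1", "L2", "L3", "L4"), annotations$vertebra)
  if (length(missing) > 0) {
    warn(sprintf("Annotations missing for: %s",
                 paste(missing, collapse = ", ")))
  }
  purrr::map_dfr(seq_len(nrow(annotations)), function(i) {
    row <- annotations[i, ]
    slice <- median_cross_section(c(row$z_lo, row$z_hi))
    roi <- ellipse_roi(slice, row$cx, row$cy, row$a, row$b)
    m <- elliptical_roi_mean(volume, roi)
    res <- measure_vbmd(m$mean_hu, calib, clamp = clamp)
    tibble::tibble(
      subject = row$subject %||% NA_character_,
      vertebra = row$vertebra,
      slice = slice,
      mean_hu = m$mean_hu,
      n_voxels = m$n_voxels,
      bvf = res$bvf,
      vbmd = res$vbmd,
      clamped = res$clamped
    )
  })
}
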