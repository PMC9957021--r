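#' Specification of the K2HPO4 calibration phantom
#'
#' A digital stand-in for the self-made lumbar-spine calibration phantom:
#' cuboid compartments (default 30 x 15 x 15 mm each, matching the
#' physical 3 x 1.5 x 1.5 cm sectors) filled with pure water and nine
#' K2HPO4 solutions spanning 0.02-1.5 g/cm^3, embedded in a water
#' background. The physical phantom holds five compartments filled twice;
#' the simulator renders all ten solutions in one volume, since the
#' geometry does not enter the ROI-mean measurement. The 1.0 g/cm^3
#' solution doubles as the cortical-bone-equivalent calibration reference.
#'
#' @param concentrations K2HPO4 concentrations (g/cm^3), one per
#'   compartment; must be non-negative and include 0 (water) and 1.0 (the
#'   cortical reference) for a calibratable phantom.
#' @param compartment_mm Extent of one compartment, `c(x, y, z)` in mm.
#' @param voxel_mm Isotropic voxel size (mm).
#' @param gap_mm Water-filled gap between compartments and margin (mm).
#' @return A `tcm_phantom_spec`: list with the compartment table (tibble
#'   with `compartment`, `concentration` and box extents in mm) and the
#'   voxel size.
#' @export
#' @examples
#' phantom_spec()
phantom_spec <- function(concentrations = c(0, 0.02, 0.05, 0.1, 0.2, 0.4,
                                            0.6, 0.8, 1.0, 1.5),
                         compartment_mm = c(15, 15, 30),
                         voxel_mm = 0.5,
                         gap_mm = 2) {
  check_number(concentrations, "concentrations")
  if (any(concentrations < 0)) {
    abort("`concentrations` must be non-negative.",
          class = "tcmbmd_domain_error")
  }
  check_number(voxel_mm, "voxel_mm", positive = TRUE)
  check_number(gap_mm, "gap_mm")
  n <- length(concentrations)
  ncol_grid <- ceiling(n / 2)
  nrow_grid <- min(n, 2)
  idx <- seq_len(n) - 1
  col <- idx %% ncol_grid
  row <- idx %/% ncol_grid
  x0 <- gap_mm + col * (compartment_mm[1] + gap_mm)
  y0 <- gap_mm + row * (compartment_mm[2] + gap_mm)
  compartments <- tibble::tibble(
    compartment = seq_len(n),
    concentration = concentrations,
    x0 = x0, x1 = x0 + compartment_mm[1],
    y0 = y0, y1 = y0 + compartment_mm[2],
    z0 = gap_mm, z1 = gap_mm + compartment_mm[3]
  )
  extent <- c(
    max(compartments$x1) + gap_mm,
    ncol_grid * 0 + max(compartments$y1) + gap_mm,
    max(compartments$z1) + gap_mm
  )
  structure(
    list(compartments = compartments, voxel_mm = voxel_mm, extent_mm = extent),
    class = "tcm_phantom_spec"
  )
}

#' @export
print.tcm_phantom_spec <- function(x, ...) {
  cat(sprintf("<tcm_phantom_spec>  %d compartments, voxel %.2g mm, extent %s mm\n",
              nrow(x$compartments), x$voxel_mm,
              paste(round(x$extent_mm, 1), collapse = " x ")))
  invisible(x)
}

#' Render the calibration phantom as a CT volume
#'
#' Each voxel receives the CT number of its material under the given
#' spectrum -- `1000 * (mu_eff / mu_eff_water - 1)`, where `mu_eff` is the
#' spectrum-weighted linear attenuation -- plus i.i.d. Gaussian noise.
#' Streaks, scatter and beam hardening are not modelled: ROI means are the
#' only statistic consumed downstream.
#'
#' @param spec A [phantom_spec()].
#' @param spectrum A `tcm_spectrum` (see [make_spectrum()]).
#' @param noise_sd_hu Per-voxel Gaussian noise standard deviation (HU).
#' @param seed Integer seed making the render reproducible.
#' @return A `tcm_phantom_render`: list with `volume` (a [ct_volume()]),
#'   `labels` (integer array, 0 = background, otherwise compartment id),
#'   the `spec`, `spectrum` and `noise_sd_hu`.
#' @export
#' @examples
#' ph <- render_phantom(phantom_spec(voxel_mm = 2), make_spectrum(120),
#'                      noise_sd_hu = 0)
render_phantom <- function(spec, spectrum, noise_sd_hu = 10, seed = NULL) {
  stopifnot(inherits(spec, "tcm_phantom_spec"),
            inherits(spectrum, "tcm_spectrum"))
  check_number(noise_sd_hu, "noise_sd_hu")
  if (noise_sd_hu < 0) {
    abort("`noise_sd_hu` must be non-negative.", class = "tcmbmd_domain_error")
  }
  comp <- spec$compartments
  vox <- spec$voxel_mm
  dims <- pmax(1L, as.integer(ceiling(spec$extent_mm / vox)))
  mu_water <- spectrum_weighted_attenuation(material("water"), spectrum)
  hu_comp <- vapply(comp$concentration, function(conc) {
    hu_from_attenuation(
      spectrum_weighted_attenuation(solution_material(conc), spectrum),
      mu_water
    )
  }, numeric(1))

  hu <- array(0, dim = dims) # water background: 0 HU by definition
  labels <- array(0L, dim = dims)
  # voxel-center inclusion: voxel i covers ((i-1)*vox, i*vox], center (i-0.5)*vox
  rng <- function(lo, hi, n) {
    i <- which((seq_len(n) - 0.5) * vox >= lo & (seq_len(n) - 0.5) * vox <= hi)
    i
  }
  for (k in seq_len(nrow(comp))) {
    ix <- rng(comp$x0[k], comp$x1[k], dims[1])
    iy <- rng(comp$y0[k], comp$y1[k], dims[2])
    iz <- rng(comp$z0[k], comp$z1[k], dims[3])
    if (any(labels[ix, iy, iz] != 0L)) {
      abort("Overlapping phantom compartments.", class = "tcmbmd_domain_error")
    }
    hu[ix, iy, iz] <- hu_comp[k]
    labels[ix, iy, iz] <- comp$compartment[k]
  }
  if (!is.null(seed)) set.seed(seed)
  if (noise_sd_hu > 0) {
    hu <- hu + array(rnorm(prod(dims), 0, noise_sd_hu), dim = dims)
  }
  structure(
    list(
      volume = ct_volume(hu, spacing = rep(vox, 3)),
      labels = labels,
      spec = spec,
      spectrum = spectrum,
      noise_sd_hu = noise_sd_hu,
      seed = seed
    ),
    class = "tcm_phantom_render"
  )
}

#' @export
print.tcm_phantom_render <- function(x, ...) {
  cat(sprintf("<tcm_phantom_render %s>  %s voxels, noise SD %g HU\n",
              x$spectrum$label,
              paste(dim(x$labels), collapse = " x "), x$noise_sd_hu))
  invisible(x)
}

# mean HU of every labelled compartment of a render
compartment_means <- function(render) {
  comp <- render$spec$compartments
  hu <- render$volume$data
  labels <- render$labels
  tibble::tibble(
    compartment = comp$compartment,
    concentration = comp$concentration,
    n_voxels = vapply(comp$compartment,
                      function(k) sum(labels == k), integer(1)),
    mean_hu = vapply(comp$compartment,
                     function(k) mean(hu[labels == k]), numeric(1))
  )
}

#' Calibrate the two-compartment model from a phantom render
#'
#' The marrow reference is the mean CT number of the water compartment and
#' the cortical reference that of the 1.0 g/cm^3 K2HPO4 compartment, both
#' measured from the rendered volume itself (as in-scan calibration does).
#'
#' @param render A [render_phantom()] result.
#' @param rho_cortical Density assigned to the cortical compartment
#'   (g/cm^3); the default 1 equates phantom vBMD with concentration.
#' @return A [reference_calibration()] carrying the spectrum label.
#' @export
calibrate_phantom <- function(render, rho_cortical = 1) {
  stopifnot(inherits(render, "tcm_phantom_render"))
  means <- compartment_means(render)
  water <- means$mean_hu[means$concentration == 0]
  cortical <- means$mean_hu[means$concentration == 1]
  if (length(water) == 0 || length(cortical) == 0) {
    abort(paste("Calibration requires a water (0) and a 1.0 g/cm^3",
                "compartment in the phantom."),
          class = "tcmbmd_missing_reference")
  }
  reference_calibration(
    ct_marrow = water[1], ct_cortical = cortical[1],
    rho_cortical = rho_cortical,
    kvp_label = render$spectrum$label
  )
}

#' Validate the two-compartment model against a phantom render
#'
#' Measures every compartment's mean CT number, converts it to vBMD under
#' the calibration, and compares against the theoretical vBMD (the K2HPO4
#' concentration). Relative differences are reported both per theoretical
#' value (`rel_diff`, undefined for water) and per full scale
#' (`rel_diff_fs`, relative to the largest concentration), since either
#' convention is used for phantom accuracy statements.
#'
#' @param render A [render_phantom()] result.
#' @param calib Optional [reference_calibration()]; defaults to
#'   [calibrate_phantom()] on the same render.
#' @return A `tcm_phantom_validation` tibble with columns `compartment`,
#'   `concentration`, `n_voxels`, `mean_hu`, `vbmd`, `abs_diff`,
#'   `rel_diff`, `rel_diff_fs`, and the OLS fit of measured vs theoretical
#'   vBMD accessible via [glance()].
#' @export
#' @examples
#' ph <- render_phantom(phantom_spec(voxel_mm = 2), make_spectrum(120),
#'                      noise_sd_hu = 0)
#' glance(validate_phantom(ph))
validate_phantom <- function(render, calib = NULL) {
  stopifnot(inherits(render, "tcm_phantom_render"))
  calib <- calib %||% calibrate_phantom(render)
  means <- compartment_means(render)
  res <- measure_vbmd(means$mean_hu, calib)
  out <- dplyr::mutate(
    means,
    vbmd = res$vbmd,
    abs_diff = abs(.data$vbmd - .data$concentration),
    rel_diff = ifelse(.data$concentration > 0,
                      .data$abs_diff / .data$concentration, NA_real_),
    rel_diff_fs = .data$abs_diff / max(.data$concentration)
  )
  fit <- lm(vbmd ~ concentration, data = out)
  # direct R^2: summary.lm warns on the (expected) noiseless perfect fit
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((out$vbmd - mean(out$vbmd))^2)
  structure(
    out,
    class = c("tcm_phantom_validation", class(out)),
    fit = list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = 1 - ss_res / ss_tot
    ),
    calibration = calib
  )
}

#' @rdname validate_phantom
#' @param x A `tcm_phantom_validation`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.tcm_phantom_validation <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble::tibble(
    kvp_label = attr(x, "calibration")$kvp_label %||% NA_character_,
    slope = fit$slope,
    intercept = fit$intercept,
    r_squared = fit$r_squared,
    mean_rel_diff = mean(x$rel_diff, na.rm = TRUE),
    max_rel_diff = max(x$rel_diff, na.rm = TRUE),
    max_rel_diff_fs = max(x$rel_diff_fs),
    n_compartments = nrow(x)
  )
}

#' Write a phantom render to disk
#'
#' The volume goes to NIfTI; the ground truth (compartment boxes,
#' concentrations, spectrum, noise, seed) to a JSON sidecar next to it.
#'
#' @param render A [render_phantom()] result.
#' @param path Output NIfTI path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_phantom <- function(render, path) {
  stopifnot(inherits(render, "tcm_phantom_render"))
  write_ct_volume(render$volume, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(
      compartments = render$spec$compartments,
      voxel_mm = render$spec$voxel_mm,
      spectrum = list(kvp = render$spectrum$kvp,
                      label = render$spectrum$label),
      noise_sd_hu = render$noise_sd_hu,
      seed = render$seed
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
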