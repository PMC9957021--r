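#' The two-compartment model of trabecular bone
#'
#' Trabecular bone is modelled as a volume-weighted mixture of two
#' compartments: cortical-bone-equivalent mineral (a 1.0 g/cm^3 K2HPO4
#' solution in the calibration phantom) and marrow-equivalent water. Because
#' a CT number is, by definition, the attenuation of a voxel relative to
#' water, the bone volume fraction (BVF) of a trabecular ROI follows from
#' its mean CT number and the CT numbers of the two reference materials
#' measured under the same X-ray spectrum:
#'
#' \deqn{BVF = (CT_{tra} - CT_{mar}) / (CT_{cor} - CT_{mar})}
#' \deqn{vBMD = BVF \times \rho_{cor}}
#'
#' The spectrum dependence of the attenuation coefficients cancels in the
#' ratio, which is what makes the resulting volumetric bone mineral density
#' (vBMD) independent of tube voltage.
#'
#' @name tcm-model
NULL

#' CT number from spectrum-weighted linear attenuation
#'
#' The Hounsfield scale: water maps to 0 HU and vacuum to -1000 HU.
#'
#' @param mu_mix Spectrum-weighted linear attenuation of the voxel material
#'   (1/cm). Vectorized.
#' @param mu_water Spectrum-weighted linear attenuation of water (1/cm),
#'   under the same spectrum. Must be positive.
#' @return CT number(s) in HU: `1000 * (mu_mix / mu_water - 1)`.
#' @export
#' @examples
#' hu_from_attenuation(0.21, 0.21) # water: 0 HU
#' hu_from_attenuation(0, 0.21)    # vacuum: -1000 HU
hu_from_attenuation <- function(mu_mix, mu_water) {
  check_number(mu_mix, "mu_mix")
  if (!is.numeric(mu_water) || any(!is.finite(mu_water)) || any(mu_water <= 0)) {
    abort("`mu_water` must be positive and finite.",
          class = "tcmbmd_invalid_calibration")
  }
  if (any(mu_mix < 0)) {
    abort("`mu_mix` must be non-negative.", class = "tcmbmd_domain_error")
  }
  1000 * (mu_mix / mu_water - 1)
}

#' Volume-weighted mixture attenuation
#'
#' Linear attenuation of a two-component mixture in which component `a`
#' occupies volume fraction `v_a`.
#'
#' @param v_a Volume fraction of component `a`, in `[0, 1]`. Vectorized.
#' @param mu_a,mu_b Spectrum-weighted linear attenuations (1/cm) of the two
#'   pure components.
#' @return `v_a * mu_a + (1 - v_a) * mu_b`.
#' @export
mixture_attenuation <- function(v_a, mu_a, mu_b) {
  check_number(v_a, "v_a")
  if (any(v_a < 0 | v_a > 1)) {
    abort("`v_a` must lie in [0, 1].", class = "tcmbmd_domain_error")
  }
  check_number(mu_a, "mu_a")
  check_number(mu_b, "mu_b")
  v_a * mu_a + (1 - v_a) * mu_b
}

#' Volume fraction from CT numbers
#'
#' Inverts the linear mixing of CT numbers: the volume fraction of
#' component `a` in a mixture whose mean CT number is `ct_mix`, given the
#' CT numbers of the pure components under the same spectrum. This is the
#' bone volume fraction when `ct_a` is the cortical-bone-equivalent and
#' `ct_b` the marrow-equivalent reference.
#'
#' @param ct_mix CT number of the mixture (HU). Vectorized.
#' @param ct_a CT number of pure component `a` (HU).
#' @param ct_b CT number of pure component `b` (HU).
#' @return `(ct_mix - ct_b) / (ct_a - ct_b)`. May fall outside `[0, 1]`
#'   when `ct_mix` lies outside the span of the references (e.g. noise).
#' @export
volume_fraction <- function(ct_mix, ct_a, ct_b) {
  check_number(ct_mix, "ct_mix")
  check_number(ct_a, "ct_a")
  check_number(ct_b, "ct_b")
  if (any(ct_a == ct_b)) {
    abort("Degenerate calibration: `ct_a` and `ct_b` are equal.",
          class = "tcmbmd_degenerate_calibration")
  }
  (ct_mix - ct_b) / (ct_a - ct_b)
}

#' vBMD from bone volume fraction
#'
#' @param bvf Bone volume fraction (dimensionless). Vectorized.
#' @param rho_cortical Physical density assigned to the cortical
#'   compartment (g/cm^3); must be positive.
#' @return Volumetric bone mineral density `bvf * rho_cortical` (g/cm^3).
#' @export
vbmd_from_bvf <- function(bvf, rho_cortical) {
  check_number(bvf, "bvf")
  check_number(rho_cortical, "rho_cortical", positive = TRUE)
  bvf * rho_cortical
}

#' Reference calibration for the two-compartment model
#'
#' Bundles the two reference CT numbers measured from the calibration
#' phantom (marrow-equivalent water and cortical-equivalent 1.0 g/cm^3
#' K2HPO4 solution) with the density assigned to the cortical compartment.
#'
#' The default `rho_cortical = 1` makes the vBMD of a phantom compartment
#' equal its K2HPO4 concentration, so the phantom's theoretical and
#' measured vBMD can be compared on the identity line. Users preferring a
#' physiological cortical density can pass 0.884 g/cm^3 (population mean
#' cortical density).
#'
#' @param ct_marrow CT number of the marrow-equivalent reference (HU).
#' @param ct_cortical CT number of the cortical-equivalent reference (HU);
#'   must exceed `ct_marrow`.
#' @param rho_cortical Density of the cortical compartment (g/cm^3).
#' @param kvp_label Optional free-text label of the tube voltage the
#'   references were measured at (e.g. `"120kVp"`).
#' @return An object of class `tcm_calibration`.
#' @export
#' @examples
#' reference_calibration(0, 1450, kvp_label = "120kVp")
reference_calibration <- function(ct_marrow, ct_cortical, rho_cortical = 1,
                                  kvp_label = NULL) {
  check_number(ct_marrow, "ct_marrow")
  check_number(ct_cortical, "ct_cortical")
  check_number(rho_cortical, "rho_cortical", positive = TRUE)
  if (ct_cortical <= ct_marrow) {
    abort("Invalid calibration: `ct_cortical` must exceed `ct_marrow`.",
          class = "tcmbmd_invalid_calibration")
  }
  structure(
    list(ct_marrow = ct_marrow, ct_cortical = ct_cortical,
         rho_cortical = rho_cortical, kvp_label = kvp_label),
    class = "tcm_calibration"
  )
}

#' @export
print.tcm_calibration <- function(x, ...) {
  cat(sprintf(
    "<tcm_calibration%s>  CT_mar = %.2f HU, CT_cor = %.2f HU, rho_cor = %g g/cm^3\n",
    if (is.null(x$kvp_label)) "" else paste0(" ", x$kvp_label),
    x$ct_marrow, x$ct_cortical, x$rho_cortical
  ))
  invisible(x)
}

#' Read / write a calibration file
#'
#' Flat JSON (or YAML, by extension) with keys `ct_marrow`, `ct_cortical`,
#' `rho_cortical` and optionally `kvp_label`.
#'
#' @param path File path (`.json`, `.yaml` or `.yml`).
#' @return `read_calibration()` returns a `tcm_calibration`;
#'   `write_calibration()` returns `path` invisibly.
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Calibration file not found: %s", path),
          class = "tcmbmd_io_error")
  }
  vals <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path)
  }
  for (key in c("ct_marrow", "ct_cortical")) {
    if (is.null(vals[[key]])) {
      abort(sprintf("Calibration file lacks key `%s`.", key),
            class = "tcmbmd_io_error")
    }
  }
  reference_calibration(
    ct_marrow = vals$ct_marrow, ct_cortical = vals$ct_cortical,
    rho_cortical = vals$rho_cortical %||% 1,
    kvp_label = vals$kvp_label
  )
}

#' @param calib A `tcm_calibration` object.
#' @rdname read_calibration
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "tcm_calibration"))
  vals <- calib[!vapply(calib, is.null, logical(1))]
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(vals, path)
  } else {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Measure vBMD of a trabecular ROI
#'
#' Composes [volume_fraction()] and [vbmd_from_bvf()]: converts the mean CT
#' number of a trabecular ROI into bone volume fraction and vBMD under a
#' reference calibration.
#'
#' BVF is not clamped by default: values slightly outside `[0, 1]` carry
#' diagnostic information about noise and calibration quality. With
#' `clamp = TRUE` the BVF is truncated to `[0, 1]` and the `clamped` flag
#' records where truncation happened.
#'
#' @param ct_trabecular Mean CT number(s) of the trabecular ROI (HU).
#' @param calib A [reference_calibration()] object.
#' @param clamp Truncate BVF to `[0, 1]`?
#' @return A tibble with columns `mean_hu`, `bvf`, `vbmd` (g/cm^3) and
#'   `clamped`.
#' @export
#' @examples
#' calib <- reference_calibration(0, 1450)
#' measure_vbmd(c(0, 290, 1450), calib)
measure_vbmd <- function(ct_trabecular, calib, clamp = FALSE) {
  stopifnot(inherits(calib, "tcm_calibration"))
  bvf <- volume_fraction(ct_trabecular, calib$ct_cortical, calib$ct_marrow)
  clamped <- rep(FALSE, length(bvf))
  if (clamp) {
    clamped <- bvf < 0 | bvf > 1
    bvf <- pmin(pmax(bvf, 0), 1)
  }
  tibble::tibble(
    mean_hu = ct_trabecular,
    bvf = bvf,
    vbmd = vbmd_from_bvf(bvf, calib$rho_cortical),
    clamped = clamped
  )
}
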