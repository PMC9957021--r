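#' X-ray tube spectrum
#'
#' A filtered bremsstrahlung spectrum on a 1 keV grid: Kramers-form fluence
#' weights proportional to `(kVp - E)` from 10 keV up to the tube voltage,
#' attenuated by an aluminum filtration thickness, then normalized to unit
#' sum. Characteristic lines are not modelled; only spectrum-weighted mean
#' attenuations are consumed downstream, for which the smooth continuum is
#' sufficient.
#'
#' @param kvp Tube voltage (kV), in `[40, 150]`.
#' @param filtration_mm_al Aluminum filtration thickness (mm), `>= 0`.
#' @return A `tcm_spectrum`: list with `kvp`, `energies` (keV) and
#'   normalized `weights`.
#' @export
#' @examples
#' s <- make_spectrum(120)
#' sum(s$weights)
#' spectrum_mean_energy(s)
make_spectrum <- function(kvp, filtration_mm_al = 2.5) {
  check_number(kvp, "kvp")
  if (length(kvp) != 1 || kvp < 40 || kvp > 150) {
    abort("`kvp` must be a single value in [40, 150].",
          class = "tcmbmd_domain_error")
  }
  check_number(filtration_mm_al, "filtration_mm_al")
  if (filtration_mm_al < 0) {
    abort("`filtration_mm_al` must be non-negative.",
          class = "tcmbmd_domain_error")
  }
  energies <- seq(10, kvp, by = 1)
  al <- material("aluminum")
  weights <- (kvp - energies) * exp(-al$mu(energies) * filtration_mm_al / 10)
  total <- sum(weights)
  if (total <= 0) {
    # kvp == 10 edge: single zero-weight line
    weights <- rep(1 / length(energies), length(energies))
  } else {
    weights <- weights / total
  }
  new_spectrum(kvp, energies, weights,
               label = sprintf("%gkVp", kvp))
}

new_spectrum <- function(kvp, energies, weights, label = NULL) {
  structure(list(kvp = kvp, energies = energies, weights = weights,
                 label = label %||% sprintf("%gkVp", kvp)),
            class = "tcm_spectrum")
}

#' Monoenergetic spectrum
#'
#' Degenerate single-line spectrum, mainly useful for testing: the
#' spectrum-weighted attenuation reduces to the attenuation at that energy.
#'
#' @param energy_kev Photon energy (keV).
#' @return A `tcm_spectrum` with a single unit weight.
#' @export
monoenergetic_spectrum <- function(energy_kev) {
  check_number(energy_kev, "energy_kev", positive = TRUE)
  stopifnot(length(energy_kev) == 1)
  new_spectrum(energy_kev, energy_kev, 1,
               label = sprintf("%g keV", energy_kev))
}

#' @export
print.tcm_spectrum <- function(x, ...) {
  cat(sprintf("<tcm_spectrum %s>  %d lines, mean energy %.1f keV\n",
              x$label, length(x$energies), spectrum_mean_energy(x)))
  invisible(x)
}

#' Mean energy of a spectrum
#'
#' @param spectrum A `tcm_spectrum`.
#' @return Fluence-weighted mean photon energy (keV).
#' @export
spectrum_mean_energy <- function(spectrum) {
  stopifnot(inherits(spectrum, "tcm_spectrum"))
  sum(spectrum$weights * spectrum$energies)
}

#' Spectrum-weighted linear attenuation
#'
#' The effective linear attenuation a polyenergetic beam sees in a
#' material: the fluence-weighted average of mu(E) over the spectrum.
#'
#' @param material A `tcm_material` (see [material()], [solution_material()]).
#' @param spectrum A `tcm_spectrum`.
#' @return Effective linear attenuation (1/cm).
#' @export
#' @examples
#' spectrum_weighted_attenuation(material("water"), make_spectrum(120))
spectrum_weighted_attenuation <- function(material, spectrum) {
  stopifnot(inherits(material, "tcm_material"),
            inherits(spectrum, "tcm_spectrum"))
  if (length(spectrum$energies) == 0) {
    abort("Empty spectrum.", class = "tcmbmd_domain_error")
  }
  sum(spectrum$weights * material$mu(spectrum$energies))
}
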