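#' Material attenuation model
#'
#' Mass attenuation coefficients over the diagnostic range (10-150 keV)
#' are generated from a two-basis parameterization of the elemental
#' composition: a photoelectric term proportional to `Z^4.6 * E^-3` per
#' gram and an incoherent-scatter term given by the Klein-Nishina cross
#' section per electron. The single free photoelectric constant is anchored
#' to aluminum (mu/rho = 1.128 cm^2/g at 30 keV, where photoabsorption
#' dominates); water then lands within 3% of its reference 0.2059 cm^2/g
#' at 60 keV. The two-compartment model cancels the absolute attenuation
#' scale, so a physically plausible energy dependence is all the phantom
#' simulation requires.
#'
#' @name attenuation
NULL

# Z and A for the elements used by the shipped materials
.elements <- list(
  H  = c(Z = 1,  A = 1.008),
  O  = c(Z = 8,  A = 15.999),
  P  = c(Z = 15, A = 30.974),
  K  = c(Z = 19, A = 39.098),
  Al = c(Z = 13, A = 26.982)
)

# Klein-Nishina total cross section per electron (cm^2)
.sigma_kn <- function(energy_kev) {
  k <- energy_kev / 510.99895
  re2 <- 7.94079e-26 # classical electron radius squared, cm^2
  2 * pi * re2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

.avogadro <- 6.02214076e23

# photoelectric constant anchored to aluminum at 30 keV (see ?attenuation)
.c_photoelectric <- local({
  al <- .elements$Al
  compton <- .avogadro * (al["Z"] / al["A"]) * .sigma_kn(30)
  unname((1.128 - compton) * al["A"] / al["Z"]^4.6 * 30^3)
})

#' Mass attenuation of a material (cm^2/g)
#'
#' @param composition Named numeric vector of elemental mass fractions
#'   (names among H, O, P, K, Al); fractions should sum to 1.
#' @param energy_kev Photon energies (keV), vectorized.
#' @return Mass attenuation coefficients (cm^2/g).
#' @export
#' @examples
#' mass_attenuation(c(H = 0.1119, O = 0.8881), c(60, 100)) # water
mass_attenuation <- function(composition, energy_kev) {
  check_number(energy_kev, "energy_kev", positive = TRUE)
  unknown <- setdiff(names(composition), names(.elements))
  if (length(unknown) > 0) {
    abort(sprintf("No attenuation data for element(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "tcmbmd_domain_error")
  }
  out <- 0
  for (el in names(composition)) {
    z <- .elements[[el]]["Z"]; a <- .elements[[el]]["A"]
    out <- out + composition[[el]] *
      (.c_photoelectric * z^4.6 / a * energy_kev^-3 +
         .avogadro * (z / a) * .sigma_kn(energy_kev))
  }
  unname(out)
}

# mass fractions of K2HPO4 (M = 174.176 g/mol)
.comp_k2hpo4 <- local({
  m <- 2 * 39.098 + 1.008 + 30.974 + 4 * 15.999
  c(K = 2 * 39.098 / m, H = 1.008 / m, P = 30.974 / m, O = 4 * 15.999 / m)
})
.comp_water <- c(H = 0.111894, O = 0.888106)
.rho_water <- 0.9982 # g/cm^3 at 20 C

#' Built-in materials
#'
#' Returns a material usable with [spectrum_weighted_attenuation()]: a list
#' with a `name`, a `mu(energy_kev)` function returning linear attenuation
#' (1/cm) at the material's density, and the `density` (g/cm^3).
#'
#' @param name One of `"water"`, `"aluminum"`.
#' @return A `tcm_material` list.
#' @export
material <- function(name = c("water", "aluminum")) {
  name <- match.arg(name)
  switch(name,
    water = new_material("water", function(e) {
      mass_attenuation(.comp_water, e) * .rho_water
    }, .rho_water),
    aluminum = new_material("aluminum", function(e) {
      mass_attenuation(c(Al = 1), e) * 2.699
    }, 2.699)
  )
}

new_material <- function(name, mu, density) {
  structure(list(name = name, mu = mu, density = density),
            class = "tcm_material")
}

#' Linear attenuation of an aqueous K2HPO4 solution
#'
#' Additive-salt model: the dissolved salt adds its mass attenuation on
#' top of water, `mu_sol(E) = mu_water(E) + c * (mu/rho)_K2HPO4(E)`. Water
#' displacement by the salt is ignored, which keeps the solution's
#' theoretical vBMD identical to its concentration; this is also the
#' convention under which calibration phantoms equate the two. The model is
#' exactly linear in concentration at every energy.
#'
#' @param concentration K2HPO4 concentration (g/cm^3), `>= 0`. Vectorized
#'   over either argument (not both).
#' @param energy_kev Photon energy (keV).
#' @return Linear attenuation (1/cm).
#' @export
#' @examples
#' solution_attenuation(0, 60)   # pure water
#' solution_attenuation(1, 60)
solution_attenuation <- function(concentration, energy_kev) {
  check_number(concentration, "concentration")
  if (any(concentration < 0)) {
    abort("`concentration` must be non-negative.",
          class = "tcmbmd_domain_error")
  }
  mass_attenuation(.comp_water, energy_kev) * .rho_water +
    concentration * mass_attenuation(.comp_k2hpo4, energy_kev)
}

#' K2HPO4 solution as a material
#'
#' @param concentration K2HPO4 concentration (g/cm^3).
#' @return A `tcm_material` for use with [spectrum_weighted_attenuation()].
#' @export
solution_material <- function(concentration) {
  check_number(concentration, "concentration")
  new_material(
    sprintf("K2HPO4 %.3f g/cm3", concentration),
    function(e) solution_attenuation(concentration, e),
    .rho_water + concentration
  )
}
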