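#' Plot measured vs theoretical phantom vBMD
#'
#' The phantom accuracy picture: measured two-compartment vBMD against
#' the theoretical value (the K2HPO4 concentration), with the identity
#' line; energy independence shows as different-kVp points landing on top
#' of each other.
#'
#' @param ... One or more `tcm_phantom_validation` tables (named
#'   arguments become legend labels).
#' @return A ggplot object.
#' @export
plot_phantom_validation <- function(...) {
  tables <- list(...)
  labels <- names(tables) %||% rep("", length(tables))
  labels[labels == ""] <- vapply(seq_along(tables), function(i) {
    attr(tables[[i]], "calibration")$kvp_label %||% sprintf("render %d", i)
  }, character(1))
  df <- purrr::map2_dfr(tables, labels, function(tab, lab) {
    tibble::tibble(concentration = tab$concentration, vbmd = tab$vbmd,
                   spectrum = lab)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration, y = .data$vbmd,
                                   colour = .data$spectrum,
                                   shape = .data$spectrum)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Theoretical vBMD (g/cm³)",
                  y = "Measured vBMD (g/cm³)") +
    ggplot2::theme_minimal()
}

#' Plot the HU-vs-concentration energy dependence
#'
#' The companion picture to [plot_phantom_validation()]: compartment mean
#' CT numbers *do* depend on tube voltage, which is why raw HU thresholds
#' do not transfer across scanners while two-compartment vBMD does.
#'
#' @inheritParams plot_phantom_validation
#' @return A ggplot object.
#' @export
plot_phantom_hu <- function(...) {
  tables <- list(...)
  labels <- names(tables) %||% rep("", length(tables))
  labels[labels == ""] <- vapply(seq_along(tables), function(i) {
    attr(tables[[i]], "calibration")$kvp_label %||% sprintf("render %d", i)
  }, character(1))
  df <- purrr::map2_dfr(tables, labels, function(tab, lab) {
    tibble::tibble(concentration = tab$concentration, mean_hu = tab$mean_hu,
                   spectrum = lab)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$concentration, y = .data$mean_hu,
                                   colour = .data$spectrum,
                                   shape = .data$spectrum)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::labs(x = "Theoretical vBMD (g/cm³)", y = "CT number (HU)") +
    ggplot2::theme_minimal()
}

#' Plot the age trend of mean lumbar vBMD by sex
#'
#' Scatter of per-subject mean vBMD against age with per-sex OLS lines
#' (the decline rates reported by [cohort_age_regression()]).
#'
#' @param cohort Cohort tibble.
#' @return A ggplot object.
#' @export
plot_age_trend <- function(cohort) {
  cohort$mean_vbmd <- vertebra_score(cohort, "average")
  ggplot2::ggplot(cohort, ggplot2::aes(x = .data$age, y = .data$mean_vbmd,
                                       colour = .data$sex)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "Age (years)", y = "Mean lumbar vBMD (g/cm³)") +
    ggplot2::theme_minimal()
}
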