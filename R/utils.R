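#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; clinical tables conventionally
#' round half away from zero (95.25 -> 95.3). Used for every percentage the
#' package reports.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded with halves away from zero.
#' @export
#' @examples
#' round_half_up(c(81.85, -81.85), 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# stopifnot-style scalar checks with readable errors
check_number <- function(x, name, finite = TRUE, positive = FALSE) {
  if (!is.numeric(x)) {
    abort(sprintf("`%s` must be numeric.", name), class = "tcmbmd_domain_error")
  }
  if (finite && any(!is.finite(x))) {
    abort(sprintf("`%s` must be finite.", name), class = "tcmbmd_domain_error")
  }
  if (positive && any(x <= 0)) {
    abort(sprintf("`%s` must be positive.", name), class = "tcmbmd_domain_error")
  }
  invisible(x)
}
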