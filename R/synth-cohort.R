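#' Parameters for the synthetic screening cohort
#'
#' Defaults emulate the structure of the clinical cohorts the screening
#' pipeline is designed for: three diagnostic groups with the published
#' group sizes, sex ratios and age distributions, group-level lumbar vBMD
#' centered on the published group means, an age-related decline of vBMD
#' (steeper in women), and a noisy linear link from vBMD to DXA aBMD from
#' which per-vertebra T-scores (and hence the DXA reference-standard
#' labels) are derived.
#'
#' Two structural choices matter for how the defaults behave:
#'
#' * The sex-specific age slope is applied *centered at the group's mean
#'   age* and attenuated by `age_slope_attenuation` inside groups, because
#'   group membership (a T-score cut) absorbs part of the marginal age
#'   trend. The attenuation default 0.85 is calibrated so that the pooled
#'   per-sex regression of mean vBMD on age returns the configured
#'   marginal slopes (-0.005 g/cm^3 per year for women, -0.0031 for men):
#'   the between-group age composition supplies the remainder.
#' * The vBMD-aBMD link noise has a routine subject-level component plus a
#'   rare, mostly positive "discordance" offset emulating aBMD
#'   overestimation by degenerative change and osteophytes; the mixture is
#'   calibrated so the pooled per-vertebra Pearson correlation of vBMD and
#'   aBMD falls in the moderate 0.60-0.80 band at the experimental cohort
#'   size.
#'
#' @param preset `"experimental"` (group sizes 57/25/23) or `"test"`
#'   (43/18/14).
#' @param ... Named overrides of any returned field.
#' @return A `tcm_cohort_params` list; fields are documented inline in the
#'   returned object's names.
#' @export
#' @examples
#' cohort_params("experimental")$n_per_group
cohort_params <- function(preset = c("experimental", "test"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset = preset,
    # group sizes, female fraction, age distribution (years): published
    # cohort structure, order normal / osteopenia / osteoporosis
    n_per_group = c(normal = 57, osteopenia = 25, osteoporosis = 23),
    female_fraction = c(23 / 57, 16 / 25, 22 / 23),
    age_mean = c(47.4, 55.9, 64.6),
    age_sd = c(11.3, 9.9, 9.1),
    age_range = c(20, 90),
    # lumbar vBMD per group (g/cm^3), shared by L1-L4; SD is the
    # within-group residual spread around the age trend
    vbmd_mean = c(0.175, 0.115, 0.062),
    vbmd_sd = c(0.03, 0.02, 0.015),
    vbmd_floor = 0.005,
    # fraction of within-group vBMD variance shared across a subject's
    # four vertebrae (subjects' vertebrae track each other)
    vbmd_subject_share = 0.6,
    # marginal vBMD decline per year of age, by sex, and its within-group
    # attenuation (see Details)
    age_slope = c(F = -0.005, M = -0.0031),
    age_slope_attenuation = 0.85,
    # aBMD link: abmd = intercept + slope * vbmd + noise (g/cm^2)
    abmd_intercept = 0.68,
    abmd_slope = 3.2,
    abmd_noise_sd = 0.05,
    abmd_vertebra_noise_sd = 0.02,
    discordance_prob = 0.18,
    discordance_range = c(0.32, 0.62),
    discordance_positive = 0.8,
    # per-vertebra young-adult aBMD reference (mean, SD) for T-scores
    tscore_ref_mean = c(1.184, 1.149, 1.099, 1.080),
    tscore_ref_sd = c(0.113, 0.101, 0.101, 0.107),
    seed = 1L
  )
  if (preset == "test") {
    base$n_per_group <- c(normal = 43, osteopenia = 18, osteoporosis = 14)
    base$female_fraction <- c(17 / 43, 12 / 18, 11 / 14)
    base$age_mean <- c(46.6, 52.8, 64.6)
    base$age_sd <- c(10.3, 10.1, 6.7)
  }
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(base))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown cohort parameter(s): %s",
                  paste(unknown, collapse = ", ")),
          class = "tcmbmd_domain_error")
  }
  base[names(overrides)] <- overrides
  validate_cohort_params(structure(base, class = "tcm_cohort_params"))
}

validate_cohort_params <- function(p) {
  if (any(p$n_per_group < 2)) {
    abort("Each group needs at least 2 subjects.",
          class = "tcmbmd_domain_error")
  }
  if (any(c(p$vbmd_sd, p$age_sd, p$abmd_noise_sd, p$tscore_ref_sd) <= 0)) {
    abort("All standard deviations must be positive.",
          class = "tcmbmd_domain_error")
  }
  if (any(p$female_fraction < 0 | p$female_fraction > 1)) {
    abort("`female_fraction` must lie in [0, 1].",
          class = "tcmbmd_domain_error")
  }
  p
}

#' Read / write cohort parameters as YAML
#'
#' @param path YAML file path.
#' @return `read_cohort_params()` returns a `tcm_cohort_params`.
#' @export
read_cohort_params <- function(path) {
  vals <- yaml::read_yaml(path)
  preset <- vals$preset %||% "experimental"
  vals$preset <- NULL
  # yaml drops names of the slope vector; restore the F/M convention
  if (!is.null(vals$age_slope)) {
    vals$age_slope <- setNames(as.numeric(vals$age_slope), c("F", "M"))
  }
  if (!is.null(vals$n_per_group)) {
    vals$n_per_group <- setNames(as.numeric(vals$n_per_group),
                                 c("normal", "osteopenia", "osteoporosis"))
  }
  do.call(cohort_params, c(list(preset = preset), vals))
}

#' @param params A `tcm_cohort_params`.
#' @rdname read_cohort_params
#' @export
write_cohort_params <- function(params, path) {
  stopifnot(inherits(params, "tcm_cohort_params"))
  yaml::write_yaml(unclass(params), path)
  invisible(path)
}

#' Generate a synthetic screening cohort
#'
#' Draws one cohort from [cohort_params()]: per subject a group, sex and
#' age; per vertebra a vBMD (group mean, attenuated sex-specific age
#' trend, a shared subject effect plus an independent vertebra effect,
#' floored at `vbmd_floor`); an aBMD through the noisy linear link; and a
#' T-score against the per-vertebra young-adult reference. The generative
#' `group` column is ground truth; the DXA-style reference standard
#' derived from the T-scores (see [add_dxa_group()]) disagrees with it for
#' a substantial minority of subjects, by design - this label noise mimics
#' the imperfect concordance of trabecular vBMD and projectional DXA.
#'
#' Deterministic for a fixed seed.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return A cohort tibble in the dialect of [read_cohort()]: `subject`,
#'   `sex`, `age`, `group`, `vbmd_l1..l4`, `abmd_l1..l4`,
#'   `tscore_l1..l4`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_params("experimental"), seed = 11)
#' dplyr::count(cohort, group)
generate_cohort <- function(params = cohort_params(), seed = NULL) {
  stopifnot(inherits(params, "tcm_cohort_params"))
  p <- params
  set.seed(seed %||% p$seed)
  ng <- p$n_per_group
  n <- sum(ng)
  gi <- rep(seq_along(.groups), ng)
  # deterministic female counts per group, shuffled within group
  sex <- unlist(lapply(seq_along(ng), function(g) {
    nf <- round(p$female_fraction[g] * ng[g])
    sample(c(rep("F", nf), rep("M", ng[g] - nf)))
  }))
  age <- pmin(p$age_range[2],
              pmax(p$age_range[1], rnorm(n, p$age_mean[gi], p$age_sd[gi])))
  trend <- p$age_slope_attenuation * p$age_slope[sex] * (age - p$age_mean[gi])
  share <- p$vbmd_subject_share
  subj_eff <- rnorm(n, 0, p$vbmd_sd[gi] * sqrt(share))
  vbmd <- vapply(1:4, function(j) {
    pmax(p$vbmd_floor,
         p$vbmd_mean[gi] + trend + subj_eff +
           rnorm(n, 0, p$vbmd_sd[gi] * sqrt(1 - share)))
  }, numeric(n))
  disc_sign <- ifelse(runif(n) < p$discordance_positive, 1, -1)
  link_noise <- rnorm(n, 0, p$abmd_noise_sd) +
    rbinom(n, 1, p$discordance_prob) * disc_sign *
      runif(n, p$discordance_range[1], p$discordance_range[2])
  abmd <- p$abmd_intercept + p$abmd_slope * vbmd + link_noise +
    matrix(rnorm(n * 4, 0, p$abmd_vertebra_noise_sd), n, 4)
  tscore <- sweep(sweep(abmd, 2, p$tscore_ref_mean, "-"),
                  2, p$tscore_ref_sd, "/")
  out <- tibble::tibble(
    subject = sprintf("S%03d", seq_len(n)),
    sex = sex,
    age = age,
    group = .groups[gi]
  )
  for (j in 1:4) out[[paste0("vbmd_l", j)]] <- vbmd[, j]
  for (j in 1:4) out[[paste0("abmd_l", j)]] <- abmd[, j]
  for (j in 1:4) out[[paste0("tscore_l", j)]] <- tscore[, j]
  out
}
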