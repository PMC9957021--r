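#' DXA T-score classification
#'
#' WHO-style lumbar classification using the lowest T-score of the
#' available vertebrae as the reference standard: `<= -2.5` osteoporosis,
#' `(-2.5, -1]` osteopenia, `> -1` normal. Taking the minimum over L1-L4
#' increases diagnostic sensitivity relative to a single-vertebra read.
#'
#' @param tscores Numeric vector of per-vertebra T-scores (NAs dropped).
#' @return One of `"osteoporosis"`, `"osteopenia"`, `"normal"`.
#' @export
#' @examples
#' classify_tscore(c(-0.2, 0.1, 0.4, 0.3))  # normal
#' classify_tscore(c(-1.0, 0, 0, 0))        # osteopenia (boundary)
#' classify_tscore(c(-2.5, 0, 0, 0))        # osteoporosis (boundary)
classify_tscore <- function(tscores) {
  tscores <- tscores[!is.na(tscores)]
  if (length(tscores) == 0) {
    abort("At least one T-score is required.", class = "tcmbmd_domain_error")
  }
  t_min <- min(tscores)
  if (t_min <= -2.5) "osteoporosis" else if (t_min <= -1) "osteopenia" else "normal"
}

.vertebrae <- c("L1", "L2", "L3", "L4")
.groups <- c("normal", "osteopenia", "osteoporosis")

#' Derive the DXA reference-standard group per subject
#'
#' Applies [classify_tscore()] rowwise to the `tscore_l1`..`tscore_l4`
#' columns of a cohort table.
#'
#' @param cohort Cohort tibble in the package's wide dialect (see
#'   [read_cohort()]).
#' @return The cohort with a `dxa_group` character column appended.
#' @export
add_dxa_group <- function(cohort) {
  ts <- as.matrix(cohort[, paste0("tscore_", tolower(.vertebrae))])
  cohort$dxa_group <- apply(ts, 1, classify_tscore)
  cohort
}

#' Read / write a cohort table
#'
#' CSV dialect: columns `subject`, `sex` (`F`/`M`), `age`, `group`, then
#' `vbmd_l1..l4` (g/cm^3), `abmd_l1..l4` (g/cm^2), `tscore_l1..l4`.
#'
#' @param path CSV file path.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns
#'   `path` invisibly.
#' @export
read_cohort <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    subject = readr::col_character(),
                    sex = readr::col_character(),
                    group = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' @param cohort Cohort tibble.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}

# TRUE where the subject is diseased for the given screening endpoint:
# the osteopenia endpoint pools osteopenia and osteoporosis as positives.
endpoint_positive <- function(group, endpoint = c("osteoporosis", "osteopenia")) {
  endpoint <- match.arg(endpoint)
  if (endpoint == "osteoporosis") group == "osteoporosis" else group != "normal"
}

# per-subject predictor for one vertebra or the mean over available ones
vertebra_score <- function(cohort, vertebra) {
  vb <- as.matrix(cohort[, paste0("vbmd_", tolower(.vertebrae))])
  if (vertebra == "average") {
    rowMeans(vb, na.rm = TRUE)
  } else {
    vb[, paste0("vbmd_", tolower(vertebra))]
  }
}

#' ROC of vBMD against the DXA reference standard
#'
#' @param cohort Cohort tibble; the reference standard is the `dxa_group`
#'   column if present, else derived via [add_dxa_group()].
#' @param endpoint `"osteoporosis"` (positives: osteoporosis subjects) or
#'   `"osteopenia"` (positives: osteopenia and osteoporosis pooled).
#' @param vertebra `"L1"`..`"L4"`, or `"average"` for the per-subject mean
#'   vBMD over available vertebrae.
#' @return A `tcm_roc`; see [roc_curve()].
#' @export
cohort_roc <- function(cohort, endpoint = c("osteoporosis", "osteopenia"),
                       vertebra = "average") {
  endpoint <- match.arg(endpoint)
  if (!"dxa_group" %in% names(cohort)) cohort <- add_dxa_group(cohort)
  d <- tibble::tibble(
    score = vertebra_score(cohort, vertebra),
    positive = endpoint_positive(cohort$dxa_group, endpoint)
  )
  roc_curve(d, .data$score, .data$positive)
}

#' Diagnostic thresholds and performance for a cohort
#'
#' The full screening table for one endpoint: for each of L1-L4 and the
#' per-subject average vBMD, the ROC AUC, the Youden-optimal threshold,
#' and sensitivity/specificity/accuracy at that threshold. Mirrors the
#' layout of a clinical threshold table (thresholds to three decimals,
#' percentages to one).
#'
#' @inheritParams cohort_roc
#' @return A tibble with columns `endpoint`, `vertebra`, `threshold`,
#'   `auc`, `sensitivity`, `specificity`, `accuracy`, `n_pos`, `n_neg`.
#' @export
cohort_performance <- function(cohort,
                               endpoint = c("osteoporosis", "osteopenia")) {
  endpoint <- match.arg(endpoint)
  if (!"dxa_group" %in% names(cohort)) cohort <- add_dxa_group(cohort)
  purrr::map_dfr(c(.vertebrae, "average"), function(v) {
    roc <- cohort_roc(cohort, endpoint, v)
    yj <- youden_threshold(roc)
    d <- tibble::tibble(
      score = vertebra_score(cohort, v),
      positive = endpoint_positive(cohort$dxa_group, endpoint)
    )
    perf <- diagnostic_performance(d, .data$score, .data$positive,
                                   yj$threshold)
    tibble::tibble(
      endpoint = endpoint,
      vertebra = v,
      threshold = round_half_up(yj$threshold, 3),
      auc = attr(roc, "auc"),
      sensitivity = perf$sensitivity,
      specificity = perf$specificity,
      accuracy = perf$accuracy,
      n_pos = attr(roc, "n_pos"),
      n_neg = attr(roc, "n_neg")
    )
  })
}

#' Evaluate fixed thresholds on a (test) cohort
#'
#' Applies previously derived thresholds to an independent cohort,
#' producing the verification counterpart of [cohort_performance()].
#'
#' @inheritParams cohort_roc
#' @param thresholds Tibble with columns `endpoint`, `vertebra`,
#'   `threshold` (e.g. the output of [cohort_performance()], or the
#'   shipped [reference_performance()] constants).
#' @return A tibble like [cohort_performance()]'s, without `auc`.
#' @export
apply_thresholds <- function(cohort, thresholds) {
  if (!"dxa_group" %in% names(cohort)) cohort <- add_dxa_group(cohort)
  purrr::map_dfr(seq_len(nrow(thresholds)), function(i) {
    row <- thresholds[i, ]
    d <- tibble::tibble(
      score = vertebra_score(cohort, row$vertebra),
      positive = endpoint_positive(cohort$dxa_group, row$endpoint)
    )
    perf <- diagnostic_performance(d, .data$score, .data$positive,
                                   row$threshold)
    tibble::tibble(
      endpoint = row$endpoint,
      vertebra = row$vertebra,
      threshold = row$threshold,
      sensitivity = perf$sensitivity,
      specificity = perf$specificity,
      accuracy = perf$accuracy,
      n_pos = sum(d$positive),
      n_neg = sum(!d$positive)
    )
  })
}

#' Pearson correlation with a two-sided test
#'
#' @param data A data frame.
#' @param x,y Columns (tidy-eval) to correlate.
#' @return A one-row tibble: `r`, `p_value`, `n`.
#' @export
pearson_r <- function(data, x, y) {
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  keep <- !is.na(xv) & !is.na(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 3) {
    abort("Pearson correlation needs at least 3 complete pairs.",
          class = "tcmbmd_domain_error")
  }
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Constant vector: correlation undefined.",
          class = "tcmbmd_domain_error")
  }
  ct <- cor.test(xv, yv, method = "pearson", alternative = "two.sided")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n = length(xv))
}

#' Per-vertebra correlation of vBMD and aBMD
#'
#' @param cohort Cohort tibble.
#' @return A tibble with one row per vertebra: `vertebra`, `r`,
#'   `p_value`, `n`.
#' @export
vbmd_abmd_correlation <- function(cohort) {
  purrr::map_dfr(.vertebrae, function(v) {
    lv <- tolower(v)
    out <- pearson_r(cohort, .data[[paste0("vbmd_", lv)]],
                     .data[[paste0("abmd_", lv)]])
    tibble::tibble(vertebra = v, out)
  })
}

#' Age regression of BMD, stratified by sex
#'
#' Ordinary least squares of a BMD value against age, fitted separately
#' per sex; the slope is the annual decline rate (units of the value per
#' year).
#'
#' @param data A data frame.
#' @param age,value,by Columns (tidy-eval): age in years, the BMD value,
#'   and the stratifying variable (typically sex).
#' @return A tibble with one row per stratum: `sex`, `slope`,
#'   `intercept`, `se_slope`, `r_squared`, `n`.
#' @export
age_regression <- function(data, age, value, by) {
  df <- tibble::tibble(
    age = dplyr::pull(data, {{ age }}),
    value = dplyr::pull(data, {{ value }}),
    by = dplyr::pull(data, {{ by }})
  )
  df <- df[stats::complete.cases(df), ]
  purrr::map_dfr(split(df, df$by), function(d) {
    if (nrow(d) < 3) {
      abort("Each stratum needs at least 3 points.",
            class = "tcmbmd_domain_error")
    }
    if (length(unique(d$age)) < 2) {
      abort("Degenerate design: a stratum has a single age value.",
            class = "tcmbmd_domain_error")
    }
    fit <- lm(value ~ age, data = d)
    # direct slope SE / R^2: summary.lm warns on exact-line fits
    res <- stats::residuals(fit)
    sigma2 <- sum(res^2) / (nrow(d) - 2)
    sxx <- sum((d$age - mean(d$age))^2)
    ss_tot <- sum((d$value - mean(d$value))^2)
    tibble::tibble(
      sex = d$by[1],
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      se_slope = sqrt(sigma2 / sxx),
      r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
      n = nrow(d)
    )
  })
}

#' Age regression of mean lumbar vBMD for a cohort
#'
#' Convenience wrapper: regresses the per-subject mean vBMD over L1-L4
#' against age, per sex.
#'
#' @param cohort Cohort tibble.
#' @return See [age_regression()].
#' @export
cohort_age_regression <- function(cohort) {
  cohort$mean_vbmd <- vertebra_score(cohort, "average")
  age_regression(cohort, .data$age, .data$mean_vbmd, .data$sex)
}

#' Pairwise Welch tests of vBMD between diagnostic groups
#'
#' Welch two-sample t-tests for the three group pairs, per vertebra. No
#' multiplicity correction is applied.
#'
#' @param cohort Cohort tibble with a `group` (or `dxa_group`) column.
#' @param vertebra `"L1"`..`"L4"` or `"average"`.
#' @param group_col Which grouping column to test; defaults to `group`.
#' @return A tibble: `vertebra`, `group1`, `group2`, `p_value`.
#' @export
pairwise_group_tests <- function(cohort, vertebra = "average",
                                 group_col = "group") {
  score <- vertebra_score(cohort, vertebra)
  grp <- cohort[[group_col]]
  if (is.null(grp)) {
    abort(sprintf("Column `%s` not found.", group_col),
          class = "tcmbmd_domain_error")
  }
  pairs <- utils::combn(.groups, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(p) {
    a <- score[grp == p[1]]; b <- score[grp == p[2]]
    if (length(a) < 2 || length(b) < 2) {
      abort(sprintf("Group `%s` or `%s` has fewer than 2 subjects.",
                    p[1], p[2]),
            class = "tcmbmd_domain_error")
    }
    tibble::tibble(
      vertebra = vertebra, group1 = p[1], group2 = p[2],
      p_value = t.test(a, b, var.equal = FALSE)$p.value
    )
  })
}

#' Reference clinical performance constants
#'
#' The diagnostic thresholds, AUCs, sensitivities, specificities and
#' accuracies reported for the 180-patient clinical cohorts that
#' motivated this package (105 experimental / 75 test subjects), shipped
#' as constants: the patient data are not redistributable, so these
#' numbers are reference values to compare against, not quantities the
#' package recomputes. The average osteoporosis threshold is 0.116 g/cm^3
#' and the average osteopenia threshold 0.126 g/cm^3.
#'
#' @return A tibble with columns `cohort`, `endpoint`, `vertebra`,
#'   `threshold`, `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `n_pos`, `n_neg` (threshold and AUC are `NA` for the test cohort,
#'   where the experimental thresholds were applied).
#' @export
reference_performance <- function() {
  path <- system.file("extdata", "reference_performance.csv",
                      package = "tcmbmd", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    cohort = readr::col_character(),
                    endpoint = readr::col_character(),
                    vertebra = readr::col_character(),
                    .default = readr::col_double()
                  ))
}

#' Self-consistency check of the reference performance tables
#'
#' Recomputes every accuracy cell of [reference_performance()] from its
#' printed sensitivity/specificity and the group sizes via
#' [accuracy_from_sens_spec()], and flags cells that cannot be produced
#' by any confusion matrix consistent with their own row. (A handful of
#' published osteopenia cells are known to be internally inconsistent;
#' the flag makes them visible rather than papering over them.)
#'
#' @param reference Performance table; defaults to the shipped constants.
#' @return The table with `accuracy_recomputed` and `consistent` columns.
#' @export
validate_tables <- function(reference = reference_performance()) {
  reference$accuracy_recomputed <- accuracy_from_sens_spec(
    reference$sensitivity, reference$specificity,
    reference$n_pos, reference$n_neg
  )
  reference$consistent <- reference$accuracy_recomputed == reference$accuracy
  reference
}
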