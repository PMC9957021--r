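#' ROC curve for a "low score is diseased" test
#'
#' ROC analysis with the polarity used throughout vBMD screening: a
#' subject tests positive when the score (vBMD) is *at or below* the
#' threshold. Candidate thresholds are the midpoints between consecutive
#' sorted unique scores, plus one sentinel below and one above all scores,
#' so every achievable confusion matrix appears exactly once. The AUC is
#' computed by the trapezoid rule over the resulting curve, which equals
#' the Mann-Whitney pairwise concordance probability (ties counting 1/2).
#'
#' @param data A data frame, one row per subject.
#' @param score Column (tidy-eval) holding the continuous test score.
#' @param positive Column (tidy-eval), logical, `TRUE` for diseased.
#' @return A `tcm_roc` tibble with one row per candidate threshold
#'   (`threshold`, `sensitivity`, `specificity`, fractions in `[0, 1]`),
#'   with the AUC and class counts in attributes; see [glance()].
#' @export
#' @examples
#' d <- tibble::tibble(vbmd = c(0.05, 0.08, 0.15, 0.20),
#'                     sick = c(TRUE, TRUE, FALSE, FALSE))
#' glance(roc_curve(d, vbmd, sick))$auc
roc_curve <- function(data, score, positive) {
  scores <- dplyr::pull(data, {{ score }})
  labels <- dplyr::pull(data, {{ positive }})
  if (!is.logical(labels)) {
    abort("`positive` must be a logical column (TRUE = diseased).",
          class = "tcmbmd_domain_error")
  }
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) {
    abort("ROC requires both a diseased and a non-diseased class.",
          class = "tcmbmd_single_class")
  }
  u <- sort(unique(scores))
  pad <- if (length(u) > 1) stats::median(diff(u)) / 2 else 0.5
  thresholds <- c(u[1] - pad,
                  if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
                  u[length(u)] + pad)
  sens <- vapply(thresholds, function(t) mean(scores[labels] <= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(scores[!labels] > t), numeric(1))
  # trapezoid over (FPR, TPR); thresholds ascend so both rates ascend
  fpr <- 1 - spec
  auc <- sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
  structure(
    tibble::tibble(threshold = thresholds,
                   sensitivity = sens,
                   specificity = spec),
    class = c("tcm_roc", class(tibble::tibble())),
    auc = auc, n_pos = n_pos, n_neg = n_neg
  )
}

#' @rdname roc_curve
#' @param x A `tcm_roc`.
#' @param ... Unused.
#' @exportS3Method generics::glance
glance.tcm_roc <- function(x, ...) {
  tibble::tibble(
    auc = attr(x, "auc"),
    n_pos = attr(x, "n_pos"),
    n_neg = attr(x, "n_neg")
  )
}

#' @rdname roc_curve
#' @exportS3Method generics::tidy
tidy.tcm_roc <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @rdname roc_curve
#' @param object A `tcm_roc`.
#' @exportS3Method ggplot2::autoplot
autoplot.tcm_roc <- function(object, ...) {
  df <- tibble::tibble(fpr = 1 - object$specificity,
                       tpr = object$sensitivity)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC (AUC = %.3f)", attr(object, "auc"))
    ) +
    ggplot2::theme_minimal()
}

#' Youden-index operating point
#'
#' Maximizes `J = sensitivity + specificity - 1` over the ROC's candidate
#' thresholds. Ties are broken toward higher sensitivity (screening favors
#' catching disease), then toward the lower threshold.
#'
#' @param roc A `tcm_roc` from [roc_curve()].
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "tcm_roc"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j == max(j))
  best <- best[roc$sensitivity[best] == max(roc$sensitivity[best])]
  best <- best[which.min(roc$threshold[best])]
  tibble::tibble(
    threshold = roc$threshold[best],
    sensitivity = roc$sensitivity[best],
    specificity = roc$specificity[best],
    youden_j = j[best]
  )
}

#' Diagnostic performance at a fixed threshold
#'
#' Confusion-matrix metrics for the screening polarity (positive when
#' `score <= threshold`), reported as percentages rounded to one decimal,
#' half away from zero, alongside the raw counts.
#'
#' @inheritParams roc_curve
#' @param threshold Decision threshold (finite).
#' @return A one-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy` (percent).
#' @export
diagnostic_performance <- function(data, score, positive, threshold) {
  check_number(threshold, "threshold")
  scores <- dplyr::pull(data, {{ score }})
  labels <- dplyr::pull(data, {{ positive }})
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (sum(labels) == 0 || sum(!labels) == 0) {
    abort("Both classes must be non-empty.", class = "tcmbmd_single_class")
  }
  test_pos <- scores <= threshold
  tp <- sum(test_pos & labels); fn <- sum(!test_pos & labels)
  tn <- sum(!test_pos & !labels); fp <- sum(test_pos & !labels)
  tibble::tibble(
    threshold = threshold,
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = round_half_up(100 * tp / (tp + fn), 1),
    specificity = round_half_up(100 * tn / (tn + fp), 1),
    accuracy = round_half_up(100 * (tp + tn) / (tp + tn + fp + fn), 1)
  )
}

#' Accuracy implied by printed sensitivity and specificity
#'
#' Published screening tables print sensitivity, specificity and accuracy
#' to one decimal together with the group sizes; the underlying confusion
#' matrix is integral, so the accuracy cell can be reconstructed exactly:
#' `TP = round(sens * n_pos / 100)`, `TN = round(spec * n_neg / 100)`,
#' `accuracy = 100 * (TP + TN) / (n_pos + n_neg)`, rounded to one decimal.
#' Used as a self-consistency check on reported performance tables.
#'
#' @param sensitivity,specificity Percentages as printed.
#' @param n_pos,n_neg Diseased / non-diseased group sizes.
#' @return Accuracy percentage, rounded to one decimal.
#' @export
#' @examples
#' accuracy_from_sens_spec(95.7, 78.0, 23, 82) # 81.9
accuracy_from_sens_spec <- function(sensitivity, specificity, n_pos, n_neg) {
  check_number(c(sensitivity, specificity), "sensitivity/specificity")
  if (any(n_pos <= 0) || any(n_neg <= 0)) {
    abort("`n_pos` and `n_neg` must be positive.",
          class = "tcmbmd_domain_error")
  }
  tp <- round_half_up(sensitivity * n_pos / 100)
  tn <- round_half_up(specificity * n_neg / 100)
  round_half_up(100 * (tp + tn) / (n_pos + n_neg), 1)
}
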