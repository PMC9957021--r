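# Independent oracles used across the suite. These deliberately do not
# share code with the package implementations they check.

# Mann-Whitney pairwise concordance for a "low score is diseased" test:
# P(score_pos < score_neg) + 0.5 * P(tie), enumerated over all pairs.
mw_auc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  total <- 0
  for (p in pos) {
    total <- total + sum(p < neg) + 0.5 * sum(p == neg)
  }
  total / (length(pos) * length(neg))
}

# Exhaustive Youden search: J evaluated at every point where the decision
# rule (positive when score <= t) can change, i.e. each unique score plus
# a point below all scores. Returns the maximal J and the sens/spec at it.
brute_youden <- function(scores, positive) {
  cand <- c(min(scores) - 1, sort(unique(scores)))
  stats <- vapply(cand, function(t) {
    sens <- mean(scores[positive] <= t)
    spec <- mean(scores[!positive] > t)
    c(j = sens + spec - 1, sens = sens, spec = spec)
  }, numeric(3))
  i <- which.max(stats["j", ])
  list(j = unname(stats["j", i]), sensitivity = unname(stats["sens", i]),
       specificity = unname(stats["spec", i]))
}

# random ROC instance on a coarse grid so ties occur; scores rounded to
# measurement precision so no two distinct values sit a machine epsilon
# apart (vBMD is never resolved beyond ~1 mg/cm^3)
random_roc_instance <- function(seed) {
  set.seed(seed)
  n_pos <- sample(2:25, 1)
  n_neg <- sample(2:25, 1)
  grid <- seq(0.02, 0.25, by = 0.01)
  score <- c(sample(grid, n_pos, replace = TRUE) - 0.02 * rbinom(n_pos, 1, 0.5),
             sample(grid, n_neg, replace = TRUE))
  tibble::tibble(
    score = round(score, 3),
    positive = rep(c(TRUE, FALSE), c(n_pos, n_neg))
  )
}

# uniform-HU synthetic volume with an optional elliptical insert
make_test_volume <- function(dims = c(32, 32, 12), background = 0,
                             insert_hu = NULL, insert = NULL,
                             spacing = c(1, 1, 1)) {
  data <- array(background, dim = dims)
  if (!is.null(insert_hu)) {
    x <- seq_len(dims[1]) - 1
    y <- seq_len(dims[2]) - 1
    mask <- outer(((x - insert$cx) / insert$a)^2,
                  ((y - insert$cy) / insert$b)^2, "+") <= 1
    for (z in insert$z) data[, , z + 1][mask] <- insert_hu
  }
  ct_volume(data, spacing = spacing)
}
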