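test_that("presets reproduce the published cohort structure", {
  p_exp <- cohort_params("experimental")
  expect_equal(unname(p_exp$n_per_group), c(57, 25, 23))
  expect_equal(sum(p_exp$n_per_group), 105)
  p_test <- cohort_params("test")
  expect_equal(unname(p_test$n_per_group), c(43, 18, 14))
  expect_equal(sum(p_test$n_per_group), 75)

  cohort <- generate_cohort(p_exp, seed = 1)
  expect_equal(as.integer(table(cohort$group)[c("normal", "osteopenia",
                                                "osteoporosis")]),
               c(57L, 25L, 23L))
  # deterministic female counts per group (23:34, 16:9, 22:1)
  sex_tab <- table(cohort$group, cohort$sex)
  expect_equal(unname(sex_tab[c("normal", "osteopenia", "osteoporosis"), "F"]),
               c(23, 16, 22))
  expect_true(all(cohort$age >= 20 & cohort$age <= 90))
  expect_true(all(as.matrix(cohort[, paste0("vbmd_l", 1:4)]) >= 0.005))
})

test_that("generation is deterministic per seed, down to the CSV bytes", {
  a <- generate_cohort(cohort_params(), seed = 17)
  b <- generate_cohort(cohort_params(), seed = 17)
  expect_identical(a, b)
  pa <- withr::local_tempfile(fileext = ".csv")
  pb <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, pa); write_cohort(b, pb)
  expect_identical(readBin(pa, "raw", file.size(pa)),
                   readBin(pb, "raw", file.size(pb)))
  expect_false(identical(a, generate_cohort(cohort_params(), seed = 18)))
})

test_that("parameter overrides are validated", {
  expect_error(cohort_params(bogus_field = 1), class = "tcmbmd_domain_error")
  expect_error(cohort_params(vbmd_sd = c(0, 0.02, 0.015)),
               class = "tcmbmd_domain_error")
  expect_error(cohort_params(n_per_group = c(normal = 1, osteopenia = 5,
                                             osteoporosis = 5)),
               class = "tcmbmd_domain_error")
})

test_that("parameters round-trip through YAML", {
  p <- cohort_params("test", abmd_noise_sd = 0.07, seed = 5L)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_params(p, path)
  back <- read_cohort_params(path)
  expect_equal(back$abmd_noise_sd, 0.07)
  expect_equal(unname(back$n_per_group), c(43, 18, 14))
  expect_equal(back$age_slope, c(F = -0.005, M = -0.0031))
})

test_that("a noiseless aBMD link gives perfect vBMD-aBMD correlation", {
  p <- cohort_params(abmd_noise_sd = 1e-12, abmd_vertebra_noise_sd = 1e-12,
                     discordance_prob = 0)
  cohort <- generate_cohort(p, seed = 3)
  out <- vbmd_abmd_correlation(cohort)
  expect_true(all(out$r > 1 - 1e-9))
})

test_that("default link noise lands the correlations in the moderate band", {
  # the calibrated target: per-vertebra Pearson r within [0.60, 0.80] at
  # the experimental cohort size for (nearly) every seed; deterministic
  # over this fixed seed set
  in_band <- vapply(1:20, function(seed) {
    r <- vbmd_abmd_correlation(generate_cohort(cohort_params(), seed = seed))$r
    all(r >= 0.60 & r <= 0.80)
  }, logical(1))
  expect_gte(mean(in_band), 0.85)
})

test_that("pooled per-sex age regression recovers the configured slopes", {
  p500 <- cohort_params(n_per_group = c(normal = 271, osteopenia = 119,
                                        osteoporosis = 110))
  fit <- cohort_age_regression(generate_cohort(p500, seed = 12))
  for (s in c("F", "M")) {
    row <- fit[fit$sex == s, ]
    expect_lt(abs(row$slope - cohort_params()$age_slope[[s]]),
              3 * row$se_slope)
  }
})

test_that("Youden thresholds separate the osteoporosis and osteopenia groups", {
  p <- cohort_params()
  between <- vapply(1:30, function(seed) {
    cohort <- add_dxa_group(generate_cohort(p, seed = seed))
    th <- youden_threshold(cohort_roc(cohort, "osteoporosis", "average"))$threshold
    th > p$vbmd_mean[3] && th < p$vbmd_mean[2]
  }, logical(1))
  expect_gte(mean(between), 0.95)
})

test_that("T-score labels agree with the generative groups far above chance", {
  # intentional label noise: the DXA-style reference standard is derived
  # from aBMD, which carries group information only through the noisy
  # vBMD link, so concordance is designed to sit well below 1 (see the
  # methods vignette for why ~0.6 is the ceiling for this model family)
  conc <- vapply(1:10, function(seed) {
    cohort <- add_dxa_group(generate_cohort(cohort_params(), seed = seed))
    mean(cohort$dxa_group == cohort$group)
  }, numeric(1))
  expect_true(all(conc > 0.45))
  expect_gt(mean(conc), 0.55)
  # the extreme groups keep their own label as the modal assignment;
  # osteopenia, squeezed between both boundaries, gets no such guarantee
  cohort <- add_dxa_group(generate_cohort(cohort_params(), seed = 1))
  tab <- table(cohort$group, cohort$dxa_group)
  for (g in c("normal", "osteoporosis")) {
    expect_equal(names(which.max(tab[g, ])), g)
  }
})
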