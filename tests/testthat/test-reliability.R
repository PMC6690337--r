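test_that("Cohen's kappa matches hand computation and an independent implementation", {
  # 2x2 fixture: 40 agree-A, 10 + 10 disagreements, 40 agree-B
  r1 <- c(rep("A", 40), rep("A", 10), rep("B", 10), rep("B", 40))
  r2 <- c(rep("A", 40), rep("B", 10), rep("A", 10), rep("B", 40))
  k <- cohen_kappa(r1, r2)
  expect_equal(k$p_observed, 0.8)
  expect_equal(k$p_expected, 0.5)
  expect_equal(k$value, 0.6)
  expect_identical(k$label, "moderate agreement")

  expect_equal(cohen_kappa(r1, r1)$value, 1)
  # symmetric in raters, invariant to permuting items
  expect_equal(cohen_kappa(r2, r1)$value, k$value)
  set.seed(3)
  perm <- sample(length(r1))
  expect_equal(cohen_kappa(r1[perm], r2[perm])$value, k$value)
  # kappa never exceeds raw agreement
  expect_lte(k$value, k$p_observed)

  # independent cross-check on random labels
  set.seed(12)
  a <- sample(1:4, 300, replace = TRUE)
  b <- ifelse(stats::rbinom(300, 1, 0.7) == 1, a, sample(1:4, 300, replace = TRUE))
  expect_equal(cohen_kappa(a, b)$value,
               e1071::classAgreement(table(a, b))$kappa, tolerance = 1e-10)

  expect_error(cohen_kappa(rep("A", 10), rep("A", 10)), "2 categories")
  expect_error(cohen_kappa(c("A", "B"), c("A", "B", "B")), "paired")
})

test_that("agreement bands reproduce the published qualitative labels", {
  lk <- tonebattery:::landis_koch_label
  expect_identical(lk(0.39), "fair agreement")
  expect_identical(lk(0.33), "fair agreement")
  expect_identical(lk(0.67), "substantial agreement")
  expect_identical(lk(0.53), "moderate agreement")
  cc <- tonebattery:::cicchetti_label
  expect_identical(cc(0.22), "poor")
  expect_identical(cc(0.37), "poor")
  expect_identical(cc(0.45), "fair")
  expect_identical(cc(0.80), "excellent")
})

test_that("average-measures two-way mixed ICC matches the mean-square decomposition", {
  m <- cbind(c(2, 4, 6, 8), c(3, 4, 7, 7))
  r <- icc_average(m)
  # independent oracle: two-way anova mean squares via stats::aov
  d <- data.frame(y = as.vector(m),
                  item = factor(rep(1:4, 2)), rater = factor(rep(1:2, each = 4)))
  ms <- summary(stats::aov(y ~ item + rater, d))[[1]][, "Mean Sq"]
  icc_oracle <- (ms[1] - ms[3]) / ms[1]
  expect_equal(r$value, icc_oracle, tolerance = 1e-12)
  expect_equal(r$ms_items, ms[1], tolerance = 1e-12)

  expect_equal(icc_average(cbind(1:6, 1:6))$value, 1)
  # independent noise on one column strictly lowers reliability
  set.seed(6)
  base <- stats::rnorm(40, 5, 2)
  clean <- icc_average(cbind(base, base))$value
  noisy <- icc_average(cbind(base, base + stats::rnorm(40)))$value
  expect_lt(noisy, clean)
  expect_error(icc_average(matrix(3, 5, 2)), "variance")
  expect_error(icc_average(matrix(1:2, 1, 2)), "at least 2")
})

test_that("unusable-trial filtering reproduces the removal-rate arithmetic", {
  expect_equal(removal_percent(359, 10620), 3.38)
  expect_equal(removal_percent(0, 500), 0)

  set.seed(14)
  r <- simulate_ratings(1000, rater = list(agreement = 0.9, unusable_rate = 0,
                                           rating_sd = 1), seed = 20)
  # plant exactly 50 zero-coded trials for rater 2
  planted <- sample(unique(r$trial_id), 50)
  r$tone_label[r$rater_id == 2 & r$trial_id %in% planted] <- 0L
  f <- filter_unusable(r)
  expect_equal(f$stats$removed, 50)
  expect_equal(f$stats$percent, 5.00)
  expect_equal(length(unique(f$records$trial_id)), 950)
  # recomputing the percentage from the filtered table agrees
  expect_equal(removal_percent(f$stats$total - length(unique(f$records$trial_id)),
                               f$stats$total), f$stats$percent)
  # restricting usability to rater 1 keeps the planted trials
  f1 <- filter_unusable(r, by_rater = 1)
  expect_equal(f1$stats$removed, 0)
  # excluded subjects are removed wholesale
  subj <- unique(r$subject_id)[1]
  fx <- filter_unusable(r, exclude_subjects = subj)
  expect_false(subj %in% fx$records$subject_id)
  # empty input
  e <- filter_unusable(r[0, ])
  expect_equal(e$stats$percent, 0)
})

test_that("accuracy derivation matches targets and canonicalises pinyin segmentally", {
  rec <- tibble::tibble(
    trial_id = 1:4, subject_id = "S1", task = "naming", session = "post",
    rater_id = 2L,
    tone_label = c(4L, 2L, 1L, 3L),
    rating = 5L,
    transcription = c("mao", "Māo ", "mao1", "mau"),
    target_tone = c(4L, 3L, 1L, 3L),
    target_transcription = c("mao", "mao", "mao", "mao"))
  tone <- derive_accuracy(rec, "tone")
  expect_equal(tone$correct, c(1L, 0L, 1L, 1L))
  pin <- derive_accuracy(rec, "pinyin")
  # diacritics, case, whitespace and tone digits are stripped; a single
  # segmental error still counts as wrong
  expect_equal(pin$correct, c(1L, 1L, 1L, 0L))

  rec$target_tone[2] <- NA
  expect_warning(derive_accuracy(rec, "tone"), "skipped")
})
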