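test_that("the default design lays out the full battery with exact cell counts", {
  des <- generate_design(design_config())
  expect_equal(sum(des$task == "training"), 60 * 6 * 288)
  odd <- des[des$task == "oddity", ]
  per_cell <- table(odd$subject_id, odd$session)
  expect_true(all(per_cell == 72))
  one <- odd[odd$subject_id == odd$subject_id[1] & odd$session == "pre", ]
  expect_equal(unname(table(one$trial_type)), rep(24L, 3), ignore_attr = TRUE)
  expect_equal(unname(table(one$item_novelty)), rep(36L, 2), ignore_attr = TRUE)
  pid <- des[des$task == "picture_id", ]
  expect_true(all(pid$session == "post"))
  expect_equal(sum(pid$voice_novelty == "untrained"), 60 * 36)
  expect_equal(sum(des$task == "pitch_contour"), 60 * 2 * 96)
  expect_equal(sum(des$task == "continuum"), 60 * 120)
  # annotations present exactly when the task defines them
  expect_true(all(is.na(des$trial_type[des$task != "oddity"])))
  expect_true(all(!is.na(des$step[des$task == "continuum"])))
})

test_that("design scales with configuration and invalid configs name the violated count", {
  cfg <- design_config(n_per_condition = 2, trials_per_training_session = 24,
                       oddity_trials = 12, picture_id_trials = 12,
                       repetition_words = 12, naming_pictures = 6,
                       aptitude_trials = 24, continuum_repetitions = 10)
  des <- generate_design(cfg)
  expect_equal(length(unique(des$subject_id)), 6)
  expect_equal(unname(table(unique(des[, c("subject_id", "condition")])$condition)),
               rep(2L, 3), ignore_attr = TRUE)
  expect_error(design_config(n_per_condition = 0), "n_per_condition")
  expect_error(design_config(oddity_trials = 70), "oddity_trials")
  expect_error(design_config(trials_per_training_session = -5),
               "trials_per_training_session")
})

test_that("outcome simulation is deterministic and respects the logistic model", {
  cfg <- tiny_config(seed = 5)
  des <- generate_design(cfg)
  des2 <- generate_design(cfg)
  expect_identical(des, des2)

  null_params <- generative_params(
    fixed_effects = c(intercept = 0),
    random_sd = c(intercept = 0))
  d1 <- simulate_responses(des, null_params, seed = 2)
  d2 <- simulate_responses(des, null_params, seed = 2)
  expect_identical(d1, d2)

  # fair-coin limit (pitch-contour rows excluded: their intercept is latent
  # aptitude by design)
  flat <- d1$correct[!d1$task %in% c("pitch_contour", "continuum")]
  n <- length(flat)
  expect_lt(abs(mean(flat) - 0.5), 3 * sqrt(0.25 / n))

  # intercept 1.0 -> accuracy plogis(1) = 0.731
  one <- simulate_responses(des, generative_params(
    fixed_effects = c(intercept = 1), random_sd = c(intercept = 0)), seed = 3)
  acc <- one$correct[!one$task %in% c("pitch_contour", "continuum")]
  expect_lt(abs(mean(acc) - stats::plogis(1)),
            3 * sqrt(stats::plogis(1) * (1 - stats::plogis(1)) / length(acc)))
})

test_that("subject random intercepts overdisperse accuracy relative to the binomial", {
  cfg <- design_config(n_per_condition = 20, trials_per_training_session = 96,
                       oddity_trials = 6, picture_id_trials = 2,
                       repetition_words = 2, naming_pictures = 1,
                       aptitude_trials = 2, continuum_repetitions = 2, seed = 1)
  des <- generate_design(cfg)
  tr <- function(params, seed) {
    d <- simulate_responses(des, params, seed = seed)
    d <- d[d$task == "training", ]
    tapply(d$correct, d$subject_id, mean)
  }
  m <- 6 * 96  # training trials per subject
  means_re <- tr(generative_params(fixed_effects = c(intercept = 0),
                                   random_sd = c(intercept = 2)), 7)
  p_bar <- mean(means_re)
  var_binom <- p_bar * (1 - p_bar) / m
  expect_gt(stats::var(means_re), 3 * var_binom)

  # unknown coefficient names are listed in the error
  expect_error(simulate_responses(des, generative_params(
    fixed_effects = c(intercept = 0, wibble = 1))), "wibble")
})

test_that("continuum categorisation follows the psychometric curve", {
  # infinitely steep curve at midpoint 3.5: steps 1-3 all tone 2, 4-6 all tone 3
  step_fun <- simulate_continuum(
    data.frame(subject_id = "S1", b1 = 0, midpoint = 3.5),
    repetitions = 20, seed = 1)
  expect_true(all(step_fun$chose_tone3[step_fun$step >= 4] == 1))
  expect_true(all(step_fun$chose_tone3[step_fun$step <= 3] == 0))

  # flat responder: every step near 50%
  flat <- simulate_continuum(
    data.frame(subject_id = "S1", b1 = 1, midpoint = 3.5),
    repetitions = 600, seed = 2)
  by_step <- tapply(flat$chose_tone3, flat$step, mean)
  expect_true(all(abs(by_step - 0.5) < 3 * sqrt(0.25 / 600)))

  expect_error(simulate_continuum(
    data.frame(subject_id = "S1", b1 = 0.5, midpoint = 3.5), steps = 9), "1-6")
  expect_error(simulate_continuum(
    data.frame(subject_id = "S1", b1 = -1, midpoint = 3.5)), "non-negative")
})

test_that("dual-rater codings share a latent truth, flag unusable trials at the stated rate, and replay byte-identically", {
  r <- simulate_ratings(1000,
                        rater = list(agreement = 1, unusable_rate = 0.05,
                                     rating_sd = 1), seed = 9)
  expect_equal(nrow(r), 2000)
  # per-trial latent truth is shared: with agreement 1, usable pairs agree
  r1 <- r[r$rater_id == 1, ]; r2 <- r[r$rater_id == 2, ]
  usable <- r1$tone_label != 0 & r2$tone_label != 0
  expect_true(all(r1$tone_label[usable] == r2$tone_label[usable]))
  # ~5% of codings are zero, within binomial error
  zero_rate <- mean(r$tone_label == 0)
  expect_lt(abs(zero_rate - 0.05), 3 * sqrt(0.05 * 0.95 / 2000))

  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  utils::write.csv(simulate_ratings(200, seed = 4), f1, row.names = FALSE)
  utils::write.csv(simulate_ratings(200, seed = 4), f2, row.names = FALSE)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))

  expect_error(simulate_ratings(10, rater = list(agreement = 1.2,
                                                 unusable_rate = 0,
                                                 rating_sd = 1)), "\\[0, 1\\]")
})

test_that("trial tables round-trip through CSV and configs load from YAML/JSON", {
  cfg <- tiny_config(seed = 3)
  des <- generate_design(cfg)
  dat <- simulate_responses(des, generative_params(), seed = 6)

  long <- tempfile(fileext = ".csv")
  write_trials(dat, long)
  back <- read_trials(long)
  expect_equal(nrow(back), nrow(dat))
  expect_equal(sort(unique(back$task)), sort(unique(dat$task)))
  expect_equal(mean(back$correct, na.rm = TRUE), mean(dat$correct, na.rm = TRUE))

  split_dir <- tempfile()
  paths <- write_trials(dat, split_dir, split_by_task = TRUE)
  expect_equal(length(paths), length(unique(dat$task)))
  back2 <- read_trials(split_dir)
  expect_equal(nrow(back2), nrow(dat))
  unlink(c(long, split_dir), recursive = TRUE)

  yml <- tempfile(fileext = ".yaml")
  writeLines(c("design:", "  n_per_condition: 2",
               "  trials_per_training_session: 24",
               "  oddity_trials: 12", "  picture_id_trials: 12",
               "  repetition_words: 12", "  naming_pictures: 6",
               "  aptitude_trials: 24", "  continuum_repetitions: 10",
               "params:",
               "  aptitude_mean: 0.6"), yml)
  cf <- config_from_file(yml)
  expect_s3_class(cf$design, "design_config")
  expect_equal(cf$design$n_per_condition, 2)
  expect_equal(cf$params$aptitude_mean, 0.6)
  unlink(yml)
})
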