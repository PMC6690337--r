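#' Design configuration for the tone-training battery
#'
#' Describes the planned experiment: three training conditions (`LV` single
#' speaker, `HV` four speakers intermixed, `HVB` four speakers blocked), six
#' training sessions of two-alternative forced-choice word-learning trials,
#' pre/post perception and production tests, and the aptitude tasks. The
#' defaults are the study design the analysis presets assume: 20 subjects per
#' condition, 288 training trials per session, 72 oddity trials split
#' trained/untrained and neutral/easy/hard, 72 post-only picture
#' identification trials split by voice novelty, 72 repetition words, 36
#' naming pictures, a 96-trial pitch-contour test, and a 6-step tonal
#' continuum with 20 repetitions per step.
#'
#' @param n_per_condition Subjects per training condition.
#' @param conditions Condition labels.
#' @param training_sessions Number of training sessions.
#' @param trials_per_training_session Two-alternative trials per session.
#' @param oddity_trials Three-interval-oddity trials per test session; must be
#'   divisible by 6 (2 item-novelty cells x 3 trial types, balanced).
#' @param picture_id_trials Picture-identification trials (post-only); must be
#'   even (trained/untrained voice halves).
#' @param repetition_words Word-repetition items per test session; must be
#'   even (trained/untrained halves).
#' @param naming_pictures Picture-naming items (post-only).
#' @param aptitude_trials Pitch-contour test trials per session.
#' @param continuum_steps Steps of the tonal continuum (step 1 = Tone 2
#'   endpoint, last step = Tone 3 endpoint); between 2 and 6.
#' @param continuum_repetitions Repetitions per step over the two blocks; must
#'   be even.
#' @param seed Integer seed controlling within-session trial-order shuffling
#'   in [generate_design()].
#' @return A validated list of class `"design_config"`.
#' @export
design_config <- function(n_per_condition = 20,
                          conditions = c("LV", "HV", "HVB"),
                          training_sessions = 6,
                          trials_per_training_session = 288,
                          oddity_trials = 72,
                          picture_id_trials = 72,
                          repetition_words = 72,
                          naming_pictures = 36,
                          aptitude_trials = 96,
                          continuum_steps = 6,
                          continuum_repetitions = 20,
                          seed = 1L) {
  counts <- c(n_per_condition = n_per_condition,
              training_sessions = training_sessions,
              trials_per_training_session = trials_per_training_session,
              oddity_trials = oddity_trials,
              picture_id_trials = picture_id_trials,
              repetition_words = repetition_words,
              naming_pictures = naming_pictures,
              aptitude_trials = aptitude_trials,
              continuum_steps = continuum_steps,
              continuum_repetitions = continuum_repetitions)
  bad <- names(counts)[!is.finite(counts) | counts <= 0 | counts != round(counts)]
  if (length(bad)) {
    stop("design counts must be positive integers; violated: ",
         paste(bad, collapse = ", "))
  }
  if (length(conditions) < 2 || anyDuplicated(conditions)) {
    stop("`conditions` must be at least two distinct labels")
  }
  if (oddity_trials %% 6 != 0) {
    stop("`oddity_trials` must be divisible by 6 (balanced novelty x trial-type cells)")
  }
  if (picture_id_trials %% 2 != 0) {
    stop("`picture_id_trials` must be even (balanced voice-novelty halves)")
  }
  if (repetition_words %% 2 != 0) {
    stop("`repetition_words` must be even (balanced item-novelty halves)")
  }
  if (continuum_steps < 2 || continuum_steps > 6) {
    stop("`continuum_steps` must be between 2 and 6")
  }
  if (continuum_repetitions %% 2 != 0) {
    stop("`continuum_repetitions` must be even (two blocks)")
  }
  structure(c(as.list(counts), list(conditions = conditions, seed = as.integer(seed))),
            class = "design_config")
}

#' Generative parameters for simulating battery outcomes
#'
#' Fixed effects are named log-odds coefficients over a vocabulary of centred
#' design columns: `intercept`, `condition_HV`, `condition_HVB` (centred
#' dummies vs `LV`), `pooled` (centred LV vs HV+HVB contrast), `session`
#' (centred numeric training session), `test_session` (pre -1/2, post +1/2),
#' `item_novelty` and `voice_novelty` (untrained +1/2, trained -1/2),
#' `trial_type_easy` and `trial_type_hard` (centred dummies vs neutral), and
#' `aptitude` (centred, x10-scaled latent aptitude). Interactions are written
#' with `:` (e.g. `"test_session:pooled"`). Columns that a task does not
#' define are zero for its rows, so a coefficient set may be shared across
#' tasks.
#'
#' `fixed_effects` is either one named numeric vector applied to every task,
#' or a named list with one vector per task (`training`, `oddity`,
#' `picture_id`, `repetition`, `naming`, `pitch_contour`). For the
#' pitch-contour task the intercept is the subject's latent aptitude on the
#' log-odds scale (the test *is* the aptitude measure), so an `aptitude`
#' coefficient is not allowed there.
#'
#' The default effects encode the qualitative structure the battery's tests
#' assume: performance improves over training sessions and from pre- to
#' post-test, the single-speaker condition leads training performance, oddity
#' trial types order easy > neutral > hard, and aptitude is a positive
#' predictor everywhere -- with all condition-by-session and
#' condition-by-aptitude interactions at zero (the no-variability-benefit
#' world).
#'
#' @param fixed_effects Named numeric vector, or per-task named list of such
#'   vectors (log-odds).
#' @param random_sd Named non-negative SDs of per-subject random effects over
#'   `intercept`, `session`, `test_session`, `item_novelty`, `voice_novelty`.
#' @param random_corr Correlation matrix for the random effects (default
#'   identity), order matching `random_sd`.
#' @param aptitude_mean,aptitude_sd Mean and SD of the latent true aptitude on
#'   the proportion-correct scale (truncated to `[0.05, 0.95]`).
#' @return A validated list of class `"generative_params"`.
#' @export
generative_params <- function(fixed_effects = NULL,
                              random_sd = c(intercept = 0.8, session = 0.1,
                                            test_session = 0.3,
                                            item_novelty = 0.2,
                                            voice_novelty = 0.2),
                              random_corr = NULL,
                              aptitude_mean = 0.55,
                              aptitude_sd = 0.15) {
  if (is.null(fixed_effects)) fixed_effects <- default_fixed_effects()
  if (any(random_sd < 0)) stop("`random_sd` entries must be non-negative")
  bad <- setdiff(names(random_sd),
                 c("intercept", "session", "test_session", "item_novelty",
                   "voice_novelty"))
  if (length(bad)) stop("unknown random-effect term(s): ", paste(bad, collapse = ", "))
  k <- length(random_sd)
  if (is.null(random_corr)) random_corr <- diag(k)
  if (!isTRUE(all.equal(dim(random_corr), c(k, k))) ||
      !isTRUE(all.equal(diag(random_corr), rep(1, k))) ||
      any(eigen(random_corr, symmetric = TRUE, only.values = TRUE)$values < -1e-8)) {
    stop("`random_corr` must be a positive semi-definite correlation matrix ",
         "matching `random_sd`")
  }
  if (aptitude_sd < 0 || aptitude_mean <= 0 || aptitude_mean >= 1) {
    stop("latent aptitude must have mean in (0, 1) and non-negative SD")
  }
  structure(list(fixed_effects = fixed_effects, random_sd = random_sd,
                 random_corr = random_corr, aptitude_mean = aptitude_mean,
                 aptitude_sd = aptitude_sd),
            class = "generative_params")
}

default_fixed_effects <- function() {
  list(
    training = c(intercept = 1.0, session = 0.5,
                 condition_HV = -0.79, condition_HVB = -0.83,
                 "session:condition_HV" = -0.19,
                 "session:condition_HVB" = -0.35,
                 aptitude = 0.13),
    oddity = c(intercept = 0.5, test_session = 0.31,
               item_novelty = 0.31, trial_type_easy = 0.40,
               trial_type_hard = -0.14, aptitude = 0.07),
    picture_id = c(intercept = 1.0, voice_novelty = -1.07,
                   condition_HV = -0.3, condition_HVB = -0.1,
                   "voice_novelty:condition_HV" = 0.6,
                   "voice_novelty:condition_HVB" = 0.4,
                   aptitude = 0.15),
    repetition = c(intercept = 1.1, test_session = 0.40,
                   item_novelty = -0.02, aptitude = 0.07),
    naming = c(intercept = -0.3, condition_HV = -0.2, condition_HVB = -0.1,
               aptitude = 0.08),
    pitch_contour = c(test_session = 0.21)
  )
}

subject_roster <- function(config) {
  n <- config$n_per_condition * length(config$conditions)
  tibble::tibble(
    subject_id = sprintf("S%03d", seq_len(n)),
    condition = rep(config$conditions, each = config$n_per_condition)
  )
}

#' Generate the trial-level design skeleton (no outcomes)
#'
#' Lays out one row per planned trial for every task in the battery, with the
#' full design annotation (condition, session, item and voice novelty, oddity
#' trial type, continuum step) but no responses. Rows are created in a fixed
#' canonical order and trial presentation order is then shuffled within each
#' subject x task x session cell, driven by `config$seed`, so the output is
#' deterministic.
#'
#' @param config A [design_config()].
#' @return A tibble of trial skeletons with columns `subject_id`, `condition`,
#'   `task`, `session` (`"1"`..`"6"` for training, `"pre"`/`"post"` for
#'   pre/post tasks, `"post"` for post-only tasks), `trial_index`
#'   (presentation order within the cell), `item_id`, `item_novelty`,
#'   `voice_novelty`, `trial_type`, `step` (`NA` where a task does not define
#'   the annotation).
#' @export
generate_design <- function(config = design_config()) {
  stopifnot(inherits(config, "design_config"))
  subs <- subject_roster(config)
  blank <- function(n) rep(NA_character_, n)

  task_rows <- function(task, sessions, per_session) {
    k <- nrow(per_session)
    dplyr::bind_rows(lapply(sessions, function(ss) {
      dplyr::bind_rows(lapply(seq_len(nrow(subs)), function(i) {
        dplyr::mutate(per_session,
                      subject_id = subs$subject_id[i],
                      condition = subs$condition[i],
                      task = task, session = ss)
      }))
    }))
  }

  tr <- tibble::tibble(
    item_id = ((seq_len(config$trials_per_training_session) - 1L) %%
                 max(config$trials_per_training_session %/% 8L, 1L)) + 1L,
    item_novelty = "trained", voice_novelty = NA_character_,
    trial_type = NA_character_, step = NA_integer_)
  training <- task_rows("training", as.character(seq_len(config$training_sessions)), tr)

  ko <- config$oddity_trials
  od <- tibble::tibble(
    item_id = seq_len(ko),
    item_novelty = rep(c("trained", "untrained"), each = ko / 2),
    voice_novelty = NA_character_,
    trial_type = rep(rep(c("neutral", "easy", "hard"), each = ko / 6), times = 2),
    step = NA_integer_)
  oddity <- task_rows("oddity", c("pre", "post"), od)

  kp <- config$picture_id_trials
  pid <- tibble::tibble(
    item_id = rep(seq_len(kp / 2), 2),
    item_novelty = NA_character_,
    voice_novelty = rep(c("trained", "untrained"), each = kp / 2),
    trial_type = NA_character_, step = NA_integer_)
  picture_id <- task_rows("picture_id", "post", pid)

  kr <- config$repetition_words
  rp <- tibble::tibble(
    item_id = seq_len(kr),
    item_novelty = rep(c("trained", "untrained"), each = kr / 2),
    voice_novelty = NA_character_, trial_type = NA_character_,
    step = NA_integer_)
  repetition <- task_rows("repetition", c("pre", "post"), rp)

  nm <- tibble::tibble(
    item_id = seq_len(config$naming_pictures),
    item_novelty = "trained", voice_novelty = NA_character_,
    trial_type = NA_character_, step = NA_integer_)
  naming <- task_rows("naming", "post", nm)

  pc <- tibble::tibble(
    item_id = seq_len(config$aptitude_trials),
    item_novelty = NA_character_, voice_novelty = NA_character_,
    trial_type = NA_character_, step = NA_integer_)
  pitch <- task_rows("pitch_contour", c("pre", "post"), pc)

  ct <- tibble::tibble(
    item_id = rep(seq_len(config$continuum_steps), times = config$continuum_repetitions),
    item_novelty = NA_character_, voice_novelty = NA_character_,
    trial_type = NA_character_,
    step = rep(seq_len(config$continuum_steps), times = config$continuum_repetitions))
  continuum <- task_rows("continuum", "pre", ct)

  design <- dplyr::bind_rows(training, oddity, picture_id, repetition, naming,
                             pitch, continuum)
  design <- design[, c("subject_id", "condition", "task", "session", "item_id",
                       "item_novelty", "voice_novelty", "trial_type", "step")]
  # canonical order, then a seed-driven shuffle of presentation order within
  # each subject x task x session cell
  design <- design[order(design$task, design$subject_id, design$session,
                         design$item_id), ]
  set.seed(config$seed)
  cell <- interaction(design$subject_id, design$task, design$session, drop = TRUE)
  design$trial_index <- stats::ave(seq_len(nrow(design)), cell,
                                   FUN = function(ix) sample(length(ix)))
  tibble::as_tibble(design)
}

generator_vocabulary <- c("intercept", "condition_HV", "condition_HVB",
                          "pooled", "session", "test_session", "item_novelty",
                          "voice_novelty", "trial_type_easy", "trial_type_hard",
                          "aptitude")

# Centred base columns of the generator's linear predictor; annotations a
# task does not define contribute zero for its rows.
generator_columns <- function(design, aptitude_centred) {
  n <- nrow(design)
  ctr_dummy <- function(v) { d <- as.numeric(v); d - mean(d) }
  cond <- design$condition
  list(
    intercept = rep(1, n),
    condition_HV = ctr_dummy(cond == "HV"),
    condition_HVB = ctr_dummy(cond == "HVB"),
    pooled = ctr_dummy(cond != "LV"),
    session = ifelse(design$task == "training",
                     suppressWarnings(as.numeric(design$session)), NA) |>
      (\(s) ifelse(is.na(s), 0, s - mean(s, na.rm = TRUE)))(),
    test_session = dplyr::case_when(design$session == "pre" ~ -0.5,
                                    design$session == "post" ~ 0.5,
                                    TRUE ~ 0),
    item_novelty = dplyr::case_when(design$item_novelty == "untrained" ~ 0.5,
                                    design$item_novelty == "trained" ~ -0.5,
                                    TRUE ~ 0),
    voice_novelty = dplyr::case_when(design$voice_novelty == "untrained" ~ 0.5,
                                     design$voice_novelty == "trained" ~ -0.5,
                                     TRUE ~ 0),
    trial_type_easy = ifelse(is.na(design$trial_type), 0,
                             as.numeric(design$trial_type == "easy") - 1 / 3),
    trial_type_hard = ifelse(is.na(design$trial_type), 0,
                             as.numeric(design$trial_type == "hard") - 1 / 3),
    aptitude = aptitude_centred
  )
}

#' Simulate binary outcomes for the battery's trial design
#'
#' Draws `correct ~ Bernoulli(plogis(eta))` where `eta` is the task's fixed
#' linear predictor plus per-subject random effects, mirroring the logistic
#' mixed models the analysis presets fit. A latent true aptitude (a
#' proportion) is drawn per subject; it sets the intercept of the
#' pitch-contour test on the log-odds scale and, x10-scaled and centred,
#' enters the other tasks through their `aptitude` coefficient. Rows of the
#' `continuum` task are not given outcomes here -- categorisation choices
#' follow a psychometric curve and are produced by [simulate_continuum()].
#'
#' @param design Trial skeletons from [generate_design()].
#' @param params A [generative_params()].
#' @param seed Integer seed; identical `(design, params, seed)` give
#'   identical output.
#' @return The design with columns `correct` (0/1, `NA` for continuum rows)
#'   and `aptitude_true` (the subject's latent proportion) appended.
#' @export
simulate_responses <- function(design, params = generative_params(), seed = 1L) {
  stopifnot(is.data.frame(design), inherits(params, "generative_params"))
  fe <- params$fixed_effects
  tasks <- setdiff(unique(design$task), "continuum")
  if (!is.list(fe)) fe <- stats::setNames(rep(list(fe), length(tasks)), tasks)
  for (task in names(fe)) check_terms(names(fe[[task]]), task)

  set.seed(as.integer(seed))
  subs <- unique(design$subject_id)
  apt_true <- pmin(pmax(stats::rnorm(length(subs), params$aptitude_mean,
                                     params$aptitude_sd), 0.05), 0.95)
  names(apt_true) <- subs
  apt_scaled <- 10 * apt_true
  apt_c <- apt_scaled - mean(apt_scaled)

  sd <- params$random_sd
  Sigma <- diag(sd, length(sd)) %*% params$random_corr %*% diag(sd, length(sd))
  ev <- eigen(Sigma, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), length(sd))
  b <- matrix(stats::rnorm(length(subs) * length(sd)), length(subs)) %*% t(L)
  dimnames(b) <- list(subs, names(sd))

  cols <- generator_columns(design, apt_c[design$subject_id])
  sub_i <- match(design$subject_id, subs)
  eta <- rep(NA_real_, nrow(design))
  for (task in tasks) {
    rows <- which(design$task == task)
    coefs <- fe[[task]]
    if (is.null(coefs)) stop("no fixed effects supplied for task `", task, "`")
    if (task == "pitch_contour" && "aptitude" %in% names(coefs)) {
      stop("`aptitude` coefficient is not allowed for the pitch_contour task; ",
           "its intercept is the latent aptitude itself")
    }
    e <- if (task == "pitch_contour") stats::qlogis(apt_true)[sub_i[rows]] else 0
    for (nm in names(coefs)) {
      e <- e + coefs[[nm]] * term_column(nm, cols, rows)
    }
    for (nm in colnames(b)) {
      col <- if (nm == "intercept") rep(1, length(rows)) else term_column(nm, cols, rows)
      e <- e + b[sub_i[rows], nm] * col
    }
    eta[rows] <- e
  }
  if (any(!is.finite(eta[design$task != "continuum"]))) {
    stop("linear predictor is not finite for some trials")
  }
  out <- design
  out$correct <- NA_integer_
  sim_rows <- which(design$task != "continuum")
  out$correct[sim_rows] <- stats::rbinom(length(sim_rows), 1, stats::plogis(eta[sim_rows]))
  out$aptitude_true <- apt_true[design$subject_id]
  tibble::as_tibble(out)
}

check_terms <- function(terms, task) {
  parts <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  unknown <- setdiff(parts, generator_vocabulary)
  if (length(unknown)) {
    stop("unknown generator term(s) for task `", task, "`: ",
         paste(unknown, collapse = ", "),
         "; recognised base terms: ", paste(generator_vocabulary, collapse = ", "))
  }
}

term_column <- function(term, cols, rows) {
  parts <- strsplit(term, ":", fixed = TRUE)[[1]]
  out <- rep(1, length(rows))
  for (p in parts) out <- out * cols[[p]][rows]
  out
}

#' Simulate tonal-continuum categorisation responses
#'
#' Generates two-alternative (Tone 2 vs Tone 3) choices over the synthesised
#' continuum following each subject's psychometric curve
#' `P(Tone 3 | step t) = 1 / (1 + b1^(t - midpoint))`, the response curve
#' implied by the logistic growth parameterisation used for slope scoring
#' (see [fit_categorization_slope()]). `b1 < 1` gives a curve rising from the
#' Tone 2 endpoint to the Tone 3 endpoint (the smaller `b1`, the steeper and
#' more categorical); `b1 = 1` is a flat 50% responder; `b1 = 0` is the
#' infinitely steep step-function limit.
#'
#' @param subjects Data frame with columns `subject_id`, `b1` (>= 0) and
#'   `midpoint` (continuum position of the 50% point).
#' @param steps Number of continuum steps (2 to 6; step values outside 1-6
#'   are rejected).
#' @param repetitions Repetitions per step across the two blocks (even).
#' @param seed Integer seed.
#' @return A tibble with one row per trial: `subject_id`, `session`, `block`,
#'   `step`, `trial_index`, `chose_tone3` (0/1) and `choice`
#'   (`"tone2"`/`"tone3"`).
#' @export
simulate_continuum <- function(subjects, steps = 6, repetitions = 20, seed = 1L) {
  stopifnot(is.data.frame(subjects),
            all(c("subject_id", "b1", "midpoint") %in% names(subjects)))
  if (steps < 2 || steps > 6) stop("continuum steps outside 1-6 are rejected")
  if (repetitions %% 2 != 0) stop("`repetitions` must be even (two blocks)")
  if (any(subjects$b1 < 0)) stop("psychometric `b1` must be non-negative")
  set.seed(as.integer(seed))
  grid <- expand.grid(block = 1:2, rep = seq_len(repetitions / 2),
                      step = seq_len(steps))
  out <- dplyr::bind_rows(lapply(seq_len(nrow(subjects)), function(i) {
    b1 <- subjects$b1[i]; m <- subjects$midpoint[i]
    p <- if (b1 == 0) {
      as.numeric(grid$step > m) + 0.5 * (grid$step == m)
    } else {
      1 / (1 + b1^(grid$step - m))
    }
    tibble::tibble(subject_id = subjects$subject_id[i], session = "pre",
                   block = grid$block, step = grid$step,
                   chose_tone3 = stats::rbinom(nrow(grid), 1, p))
  }))
  out$choice <- ifelse(out$chose_tone3 == 1, "tone3", "tone2")
  out$trial_index <- stats::ave(seq_len(nrow(out)), out$subject_id,
                                FUN = seq_along)
  out[, c("subject_id", "session", "block", "step", "trial_index",
          "chose_tone3", "choice")]
}

#' Simulate dual-rater production codings
#'
#' Emulates the production-coding pipeline's input: for each production trial
#' a latent produced tone and pinyin string are drawn (correct with the
#' stated production accuracies), then two raters independently code the
#' shared latent truth. Each rater reproduces the latent tone with
#' probability `agreement` (otherwise a uniformly drawn other tone), marks
#' the trial unusable (tone label 0) with probability `unusable_rate`, gives
#' a 1-7 nativelikeness rating (noisy around a quality anchored to tone
#' correctness), and transcribes the latent pinyin.
#'
#' @param trials Either an integer number of trials (a generic roster is
#'   built: subjects of 36 trials each, task `"repetition"`, session
#'   `"post"`) or a data frame with columns `trial_id`, `subject_id`, `task`,
#'   `session`, `target_tone`, `target_transcription`. An optional
#'   `produced_correct` column (0/1) fixes whether the latent production has
#'   the right tone instead of drawing it from `production$tone_accuracy`,
#'   which ties the codings to outcomes simulated elsewhere.
#' @param production List with `tone_accuracy` and `pinyin_accuracy`:
#'   probabilities that the latent production matches the target.
#' @param rater List with `agreement` (probability a rater reproduces the
#'   latent tone), `unusable_rate`, and `rating_sd`.
#' @param seed Integer seed.
#' @return A tibble with two rows (raters 1 and 2) per trial: `trial_id`,
#'   `subject_id`, `task`, `session`, `rater_id`, `tone_label` (0-4, 0 =
#'   unusable), `rating` (1-7), `transcription`, `target_tone`,
#'   `target_transcription`.
#' @export
simulate_ratings <- function(trials,
                             production = list(tone_accuracy = 0.7,
                                               pinyin_accuracy = 0.6),
                             rater = list(agreement = 0.9,
                                          unusable_rate = 0.03,
                                          rating_sd = 1),
                             seed = 1L) {
  probs <- c(production$tone_accuracy, production$pinyin_accuracy,
             rater$agreement, rater$unusable_rate)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("accuracy, agreement and unusable-rate probabilities must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  syllables <- c("ma", "mao", "di", "hua", "shu", "bei", "wan", "tang",
                 "lu", "qian", "niao", "deng")
  if (is.numeric(trials) && length(trials) == 1) {
    n <- as.integer(trials)
    trials <- tibble::tibble(
      trial_id = seq_len(n),
      subject_id = sprintf("S%03d", ((seq_len(n) - 1L) %/% 36L) + 1L),
      task = "repetition", session = "post",
      target_tone = sample(1:4, n, replace = TRUE),
      target_transcription = sample(syllables, n, replace = TRUE))
  }
  stopifnot(all(c("trial_id", "subject_id", "task", "session", "target_tone",
                  "target_transcription") %in% names(trials)))
  n <- nrow(trials)
  # shared latent production
  tone_ok <- if ("produced_correct" %in% names(trials)) {
    trials$produced_correct == 1
  } else {
    stats::rbinom(n, 1, production$tone_accuracy) == 1
  }
  other <- vapply(trials$target_tone,
                  function(t) sample(setdiff(1:4, t), 1), numeric(1))
  latent_tone <- ifelse(tone_ok, trials$target_tone, other)
  pinyin_ok <- stats::rbinom(n, 1, production$pinyin_accuracy) == 1
  latent_pinyin <- ifelse(pinyin_ok, trials$target_transcription,
                          paste0(trials$target_transcription, "r"))
  quality <- ifelse(tone_ok, 5, 3)
  rate_one <- function(rater_id) {
    agree <- stats::rbinom(n, 1, rater$agreement) == 1
    miscode <- vapply(latent_tone,
                      function(t) sample(setdiff(1:4, t), 1), numeric(1))
    label <- ifelse(agree, latent_tone, miscode)
    unusable <- stats::rbinom(n, 1, rater$unusable_rate) == 1
    label[unusable] <- 0L
    rating <- pmin(pmax(round(quality + stats::rnorm(n, 0, rater$rating_sd)), 1), 7)
    tibble::tibble(trial_id = trials$trial_id,
                   subject_id = trials$subject_id,
                   task = trials$task, session = trials$session,
                   rater_id = rater_id,
                   tone_label = as.integer(label),
                   rating = as.integer(rating),
                   transcription = latent_pinyin,
                   target_tone = trials$target_tone,
                   target_transcription = trials$target_transcription)
  }
  out <- dplyr::bind_rows(rate_one(1L), rate_one(2L))
  dplyr::arrange(out, .data$trial_id, .data$rater_id)
}

#' Write and read battery trial tables as CSV
#'
#' Trial tables are exchanged as UTF-8 CSV with a header row, either as one
#' long file with a `task` column (default) or split into one file per task.
#' Missing annotations are written as empty fields.
#'
#' @param data Trial table (from [generate_design()] or
#'   [simulate_responses()], or user data in the same schema).
#' @param path Output file (long format) or, with `split_by_task = TRUE`, a
#'   directory receiving `trials_<task>.csv` files.
#' @param split_by_task Write one file per task instead of one long file.
#' @return Invisibly, the path(s) written.
#' @export
write_trials <- function(data, path, split_by_task = FALSE) {
  stopifnot(is.data.frame(data))
  if (!split_by_task) {
    utils::write.csv(data, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(split(data, data$task), function(d) {
    p <- file.path(path, paste0("trials_", d$task[1], ".csv"))
    utils::write.csv(d, p, row.names = FALSE, na = "", fileEncoding = "UTF-8")
    p
  }, character(1))
  invisible(unname(paths))
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  files <- if (dir.exists(path)) {
    list.files(path, pattern = "^trials_.*\\.csv$", full.names = TRUE)
  } else {
    path
  }
  out <- dplyr::bind_rows(lapply(files, function(p) {
    d <- utils::read.csv(p, na.strings = "", fileEncoding = "UTF-8",
                         stringsAsFactors = FALSE)
    # session mixes numeric training sessions with pre/post labels; keep it
    # character so per-task files bind cleanly
    if ("session" %in% names(d)) d$session <- as.character(d$session)
    d
  }))
  tibble::as_tibble(out)
}

#' Build design and generative configuration from a YAML or JSON document
#'
#' The document mirrors the argument names of [design_config()] and
#' [generative_params()] under top-level keys `design` and `params` (either
#' may be omitted to take the defaults). Per-task fixed effects are given as
#' named mappings of coefficient name to log-odds value.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `design` (a `design_config`) and `params`
#'   (a `generative_params`).
#' @export
config_from_file <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  design <- do.call(design_config, doc$design %||% list())
  pl <- doc$params %||% list()
  if (!is.null(pl$fixed_effects)) {
    pl$fixed_effects <- lapply(pl$fixed_effects, unlist)
    if (length(pl$fixed_effects) == 1 && is.null(names(pl$fixed_effects))) {
      pl$fixed_effects <- pl$fixed_effects[[1]]
    }
  }
  if (!is.null(pl$random_sd)) pl$random_sd <- unlist(pl$random_sd)
  if (!is.null(pl$random_corr)) pl$random_corr <- as.matrix(pl$random_corr)
  params <- do.call(generative_params, pl)
  list(design = design, params = params)
}
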