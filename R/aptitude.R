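#' Pitch-contour aptitude scores
#'
#' Scores each subject's accuracy on the pitch-contour perception test at the
#' stated session (pre-test by default: the measure is itself affected by
#' training, so post-test scores are never used as aptitude). The proportion
#' correct is scaled by 10 -- one aptitude unit then corresponds to a 10
#' percentage-point difference in test performance -- and centred against the
#' scored sample's mean, matching how the score enters the analysis models as
#' a continuous predictor.
#'
#' @param trials Trial table containing at least `subject_id`, `task`,
#'   `session` and `correct`; rows with `task == "pitch_contour"` and the
#'   requested session are used.
#' @param session Session to score (default `"pre"`).
#' @return A tibble with one row per scored subject: `subject_id`,
#'   `n_trials`, `proportion`, `scaled` (`proportion * 10`), `centred`
#'   (`scaled` minus the sample mean). Subjects with no trials at the session
#'   are dropped with a warning.
#' @export
pitch_contour_aptitude <- function(trials, session = "pre") {
  stopifnot(all(c("subject_id", "task", "session", "correct") %in% names(trials)))
  sub <- trials[trials$task == "pitch_contour" & trials$session == session &
                  !is.na(trials$correct), ]
  if (!nrow(sub)) stop("no pitch-contour trials at session `", session, "`")
  all_subs <- unique(trials$subject_id)
  scored <- dplyr::summarise(
    dplyr::group_by(sub, .data$subject_id),
    n_trials = dplyr::n(),
    proportion = mean(.data$correct),
    .groups = "drop")
  missing <- setdiff(all_subs, scored$subject_id)
  if (length(missing)) {
    warning("subject(s) with no scorable pitch-contour trials excluded: ",
            paste(missing, collapse = ", "))
  }
  scored$scaled <- scored$proportion * 10
  scored$centred <- scored$scaled - mean(scored$scaled)
  scored
}

#' Per-subject categorisation slope from continuum responses
#'
#' Fits the logistic growth curve `Y = 1 / (1/u + b0 * b1^t)` with `u = 1` to
#' each subject's per-step proportion of Tone 3 choices `Y` against continuum
#' step `t`, via its log-linearised form: ordinary least squares of
#' `log(1/Y - 1)` on `t` gives `log(b1)` as the slope and `log(b0)` as the
#' intercept. Per-step proportions of exactly 0 or 1 receive a continuity
#' correction of `1/(2 * n_step)` before the log transform. Under this
#' parameterisation `b1 < 1` is a categorical perceiver (the smaller, the
#' steeper the psychometric curve), `b1 = 1` is a flat responder, and
#' `b1 > 1` a reversed curve; subjects with `b1` above the exclusion
#' threshold (default 1.2) are flagged for removal.
#'
#' @param responses Continuum response table with columns `subject_id`,
#'   `step` and `chose_tone3` (see [simulate_continuum()]).
#' @param threshold Exclusion threshold on `b1` (default 1.2).
#' @return A tibble with one row per subject: `subject_id`, `n_steps`, `b0`,
#'   `b1`, `flat` (`TRUE` when every per-step proportion is identical, in
#'   which case `b1 = 1`), and `excluded` (`b1 > threshold`).
#' @export
fit_categorization_slope <- function(responses, threshold = 1.2) {
  stopifnot(all(c("subject_id", "step", "chose_tone3") %in% names(responses)))
  if (any(responses$step < 1 | responses$step > 6)) {
    stop("continuum steps outside 1-6 are rejected")
  }
  by_step <- dplyr::summarise(
    dplyr::group_by(responses, .data$subject_id, .data$step),
    n = dplyr::n(), p = mean(.data$chose_tone3), .groups = "drop")
  fits <- lapply(split(by_step, by_step$subject_id), function(d) {
    if (nrow(d) < 2) {
      stop("subject `", d$subject_id[1],
           "` has fewer than 2 distinct continuum steps")
    }
    p <- d$p
    p <- ifelse(p == 0, 1 / (2 * d$n), ifelse(p == 1, 1 - 1 / (2 * d$n), p))
    yl <- log(1 / p - 1)
    flat <- isTRUE(all.equal(stats::var(yl), 0)) || stats::var(yl) < 1e-12
    if (flat) {
      b1 <- 1
      b0 <- exp(mean(yl))
    } else {
      cf <- stats::coef(stats::lm(yl ~ d$step))
      b0 <- exp(unname(cf[1]))
      b1 <- exp(unname(cf[2]))
    }
    tibble::tibble(subject_id = d$subject_id[1], n_steps = nrow(d),
                   b0 = b0, b1 = b1, flat = flat)
  })
  out <- dplyr::bind_rows(fits)
  out$excluded <- out$b1 > threshold
  out
}

#' Apply the categorisation-slope exclusion threshold to a roster
#'
#' @param fits Slope table from [fit_categorization_slope()].
#' @param threshold Exclusion threshold on `b1` (default 1.2); subjects with
#'   `b1 > threshold` are removed.
#' @return A list with `kept` and `excluded` (row subsets of `fits` with
#'   `excluded` recomputed at this threshold), `n_excluded`, `n_total`, and
#'   `threshold`.
#' @export
apply_slope_exclusions <- function(fits, threshold = 1.2) {
  stopifnot(all(c("subject_id", "b1") %in% names(fits)))
  excl <- fits$b1 > threshold
  fits$excluded <- excl
  list(kept = fits[!excl, ], excluded = fits[excl, ],
       n_excluded = sum(excl), n_total = nrow(fits), threshold = threshold)
}
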