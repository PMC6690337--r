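#' Remove unusable production trials and account for the removal rate
#'
#' A rater codes tone label 0 when a production trial had no sound or an
#' unrecognisable tone; such trials are removed before analysis, as are all
#' trials from explicitly excluded subjects (e.g. lost to recording
#' problems). By default a trial is dropped when *either* rater coded 0; set
#' `by_rater` to restrict the check to one rater's codings.
#'
#' @param records Dual-rater rating table (see [simulate_ratings()] for the
#'   schema); must carry `trial_id`, `rater_id`, `tone_label`, `subject_id`.
#' @param exclude_subjects Character vector of subject IDs to remove
#'   entirely.
#' @param by_rater `NULL` (default: either rater's 0 removes the trial) or a
#'   rater ID whose codings alone determine usability.
#' @return A list with `records` (the usable rows) and `stats`, a list with
#'   `removed` (trials removed), `total` (trials before filtering), and
#'   `percent` (`removed / total * 100`, rounded to 2 decimals).
#' @examples
#' removal_percent(359, 10620)   # 3.38
#' @export
filter_unusable <- function(records, exclude_subjects = character(),
                            by_rater = NULL) {
  needed <- c("trial_id", "subject_id", "rater_id", "tone_label")
  stopifnot(all(needed %in% names(records)))
  if (!nrow(records)) {
    return(list(records = records,
                stats = list(removed = 0L, total = 0L, percent = 0)))
  }
  total <- length(unique(records$trial_id))
  check <- if (is.null(by_rater)) records else records[records$rater_id %in% by_rater, ]
  zero_trials <- unique(check$trial_id[check$tone_label == 0])
  subj_trials <- unique(records$trial_id[records$subject_id %in% exclude_subjects])
  drop <- union(zero_trials, subj_trials)
  keep <- !(records$trial_id %in% drop)
  list(records = records[keep, ],
       stats = list(removed = length(drop), total = total,
                    percent = removal_percent(length(drop), total)))
}

#' Removal-rate arithmetic
#'
#' @param removed Number of removed trials.
#' @param total Number of trials before removal.
#' @return Percentage removed, rounded to 2 decimals.
#' @export
removal_percent <- function(removed, total) {
  if (total == 0) return(0)
  round(removed / total * 100, 2)
}

#' Derive binary accuracy outcomes from production codings
#'
#' Tone accuracy: 1 iff the rater's tone label equals the target tone.
#' Pinyin accuracy: 1 iff the transcription exactly matches the target after
#' canonicalisation (lower-casing and stripping whitespace, tone digits and
#' diacritics -- the measure is segmental only).
#'
#' @param records Usable rating records (after [filter_unusable()]).
#' @param measure `"tone"` or `"pinyin"`.
#' @param rater Rater whose codings define the outcome (default 2, the naive
#'   rater).
#' @return A tibble with one row per trial: `trial_id`, `subject_id`, `task`,
#'   `session`, and `correct` (0/1). Records with a missing target are
#'   skipped with a warning.
#' @export
derive_accuracy <- function(records, measure = c("tone", "pinyin"), rater = 2) {
  measure <- match.arg(measure)
  rec <- records[records$rater_id == rater, ]
  target_col <- if (measure == "tone") "target_tone" else "target_transcription"
  miss <- is.na(rec[[target_col]])
  if (any(miss)) {
    warning(sum(miss), " record(s) with missing ", measure, " target skipped")
    rec <- rec[!miss, ]
  }
  correct <- if (measure == "tone") {
    as.integer(rec$tone_label == rec$target_tone)
  } else {
    as.integer(canonical_pinyin(rec$transcription) ==
                 canonical_pinyin(rec$target_transcription))
  }
  tibble::tibble(trial_id = rec$trial_id, subject_id = rec$subject_id,
                 task = rec$task, session = rec$session, correct = correct)
}

canonical_pinyin <- function(x) {
  x <- tolower(x)
  x <- gsub("[[:space:][:digit:]]", "", x)
  # strip tone diacritics by transliterating to plain ASCII vowels
  x <- chartr("āáǎàēéěèīíǐìōóǒòūúǔùǖǘǚǜü",
              "aaaaeeeeiiiioooouuuuuuuuu", x)
  x
}

landis_koch_label <- function(kappa) {
  kappa <- round(kappa, 10)  # keep band edges stable under float error
  if (kappa <= 0) "poor"
  else if (kappa <= 0.20) "slight agreement"
  else if (kappa <= 0.40) "fair agreement"
  else if (kappa <= 0.60) "moderate agreement"
  else if (kappa <= 0.80) "substantial agreement"
  else "almost perfect agreement"
}

cicchetti_label <- function(icc) {
  icc <- round(icc, 10)
  if (icc < 0.40) "poor"
  else if (icc < 0.60) "fair"
  else if (icc < 0.75) "good"
  else "excellent"
}

#' Cohen's kappa for two raters
#'
#' Unweighted chance-corrected agreement
#' `kappa = (p_o - p_e) / (1 - p_e)`, where `p_o` is the observed agreement
#' and `p_e` the agreement expected from the raters' marginal label
#' frequencies. The qualitative Landis-Koch band is attached (<= 0 poor,
#' 0.20 slight, 0.40 fair, 0.60 moderate, 0.80 substantial, above that
#' almost perfect).
#'
#' @param rater1,rater2 Equal-length paired label vectors.
#' @return A list of class `"reliability_result"`: `statistic = "kappa"`,
#'   `value`, `label`, `n_items`, `p_observed`, `p_expected`.
#' @export
cohen_kappa <- function(rater1, rater2) {
  if (length(rater1) != length(rater2)) stop("label vectors must be paired")
  ok <- !is.na(rater1) & !is.na(rater2)
  r1 <- as.character(rater1[ok]); r2 <- as.character(rater2[ok])
  n <- length(r1)
  if (n == 0) stop("no complete rating pairs")
  cats <- sort(unique(c(r1, r2)))
  if (length(cats) < 2) stop("fewer than 2 categories observed across raters")
  p_o <- mean(r1 == r2)
  p_e <- sum((table(factor(r1, cats)) / n) * (table(factor(r2, cats)) / n))
  if (isTRUE(all.equal(p_e, 1))) {
    stop("expected agreement is 1 (both raters effectively constant); ",
         "kappa is undefined")
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  structure(list(statistic = "kappa", value = kappa,
                 label = landis_koch_label(kappa), n_items = n,
                 p_observed = p_o, p_expected = unname(p_e)),
            class = "reliability_result")
}

#' Average-measures two-way mixed intraclass correlation
#'
#' Consistency ICC for the average of `k` fixed raters over random items
#' (ICC(3, k) in the Shrout-Fleiss scheme), computed from the two-way mean
#' squares: `ICC = (MS_items - MS_error) / MS_items`. Rows with any missing
#' rating are dropped listwise. The qualitative Cicchetti band is attached
#' (< 0.40 poor, 0.40-0.59 fair, 0.60-0.74 good, >= 0.75 excellent).
#'
#' @param ratings Numeric matrix or data frame, items in rows, raters in
#'   columns (>= 2 of each).
#' @return A list of class `"reliability_result"`: `statistic = "icc"`,
#'   `value`, `label`, `n_items`, `n_raters`, `ms_items`, `ms_error`.
#' @export
icc_average <- function(ratings) {
  m <- as.matrix(ratings)
  storage.mode(m) <- "double"
  m <- m[stats::complete.cases(m), , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stop("need at least 2 items and 2 raters")
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  ss_items <- k * sum((row_m - grand)^2)
  ss_raters <- n * sum((col_m - grand)^2)
  ss_error <- ss_total - ss_items - ss_raters
  ms_items <- ss_items / (n - 1)
  ms_error <- ss_error / ((n - 1) * (k - 1))
  if (ms_items <= 0) stop("no between-item variance; ICC is undefined")
  icc <- (ms_items - ms_error) / ms_items
  structure(list(statistic = "icc", value = icc,
                 label = cicchetti_label(icc), n_items = n, n_raters = k,
                 ms_items = ms_items, ms_error = ms_error),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("%s = %.3f ('%s'), n = %d\n",
              toupper(x$statistic), x$value, x$label, x$n_items))
  invisible(x)
}
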