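#' Bayes factor for a point null against a half-normal alternative
#'
#' Computes the Bayes factor comparing H0 (the effect is exactly zero) against
#' an informed H1 in which the effect, on the log-odds scale, follows a
#' half-normal distribution with mode 0 and scale `x`, supported only on the
#' predicted (positive) direction. The data enter through the coefficient
#' estimate `beta` and its standard error `se` from a logistic (mixed) model;
#' the sampling distribution of `beta` is taken as Normal(theta, se^2), which
#' is the standard large-sample summary-statistic approach to informed Bayes
#' factors.
#'
#' `B > 1` favours H1, `B < 1` favours the null. An estimate opposite to the
#' predicted direction (negative `beta`) drives `B` towards the null because
#' the half-normal prior places no mass there.
#'
#' @param beta Coefficient estimate (log-odds). May be negative; the sign is
#'   interpreted relative to the predicted direction.
#' @param se Standard error of `beta`; must be positive.
#' @param x Scale (SD) of the half-normal H1 model, in log-odds units; must be
#'   positive. May also be a [halfnormal_h1] object, in which case its scale
#'   is used.
#' @param method `"closed_form"` (default) uses the conjugate-normal closed
#'   form; `"integration"` evaluates the marginal likelihood by adaptive
#'   quadrature. The two agree to well below 1e-6.
#' @return The Bayes factor, a positive scalar (vectorised over the inputs).
#' @examples
#' bf_halfnormal(0.13, 0.228, 1.71)   # ~0.22, substantial evidence for H0
#' bf_halfnormal(0, 1, 1)             # 1/sqrt(2)
#' @export
bf_halfnormal <- function(beta, se, x, method = c("closed_form", "integration")) {
  method <- match.arg(method)
  if (inherits(x, "halfnormal_h1")) x <- x$x
  if (any(!is.finite(beta))) stop("`beta` must be finite")
  if (any(!is.finite(se)) || any(se <= 0)) stop("`se` must be positive")
  if (any(!is.finite(x)) || any(x <= 0)) stop("half-normal scale `x` must be positive")
  if (method == "closed_form") {
    s2 <- se^2 + x^2
    # posterior of theta given beta under the (full) normal prior N(0, x^2)
    post_var <- se^2 * x^2 / s2
    post_mean <- beta * x^2 / s2
    # marginal likelihood under the half-normal = 2 * normal marginal * mass
    # of the posterior on the positive half-line
    m1 <- 2 * stats::dnorm(beta, 0, sqrt(s2)) * stats::pnorm(post_mean / sqrt(post_var))
    m0 <- stats::dnorm(beta, 0, se)
    m1 / m0
  } else {
    n <- max(length(beta), length(se), length(x))
    beta <- rep_len(beta, n); se <- rep_len(se, n); x <- rep_len(x, n)
    vapply(seq_len(n), function(i) {
      # the integrand's mass lies within the likelihood's support; a finite
      # upper limit keeps the quadrature accurate when beta is far below 0
      upper <- max(beta[i], 0) + 15 * se[i]
      m1 <- stats::integrate(
        function(theta) stats::dnorm(beta[i], theta, se[i]) * 2 * stats::dnorm(theta, 0, x[i]),
        lower = 0, upper = upper, rel.tol = 1e-12, abs.tol = 0,
        subdivisions = 1000L
      )$value
      m1 / stats::dnorm(beta[i], 0, se[i])
    }, numeric(1))
  }
}

#' Qualitative conclusion category for a Bayes factor
#'
#' Applies the conventional substantial-evidence thresholds: `B < 1/3` is
#' substantial evidence for the null, `B > 3` substantial evidence for H1,
#' anything in between (including the boundaries themselves) is ambiguous --
#' the data do not sensitively distinguish the hypotheses.
#'
#' @param B Bayes factor(s), positive.
#' @return Character vector in
#'   `c("substantial_null", "ambiguous", "substantial_H1")`.
#' @export
conclusion_category <- function(B) {
  if (any(!is.finite(B)) || any(B <= 0)) stop("`B` must be a positive Bayes factor")
  ifelse(B < 1 / 3, "substantial_null", ifelse(B > 3, "substantial_H1", "ambiguous"))
}

#' Robustness region of a Bayes-factor conclusion over the prior scale
#'
#' Reports the maximal contiguous range of half-normal scales `x` that lead to
#' the same qualitative conclusion as the scale actually used. The region is
#' located by evaluating the Bayes factor over a grid of scales at `resolution`
#' (default 0.01, matching 2-decimal reporting). Because `B -> 1` as
#' `x -> 0+`, an ambiguous region whose run reaches the smallest grid point is
#' reported as starting at 0. When the conclusion is substantial evidence for
#' the null, the upper endpoint is always infinity: making the alternative
#' more diffuse only strengthens the case for the null.
#'
#' @inheritParams bf_halfnormal
#' @param x_used The scale at which the reported Bayes factor was computed.
#' @param resolution Grid step for the scale search (default 0.01).
#' @param x_max Upper end of the search grid (default 50 log-odds units).
#' @return A list of class `"robustness_region"` with elements `lo`, `hi`
#'   (numeric, `hi` possibly `Inf`), `category` (the reference conclusion),
#'   `x_used`, and `B_used`. If no grid scale reproduces the reference
#'   category, `lo` and `hi` are `NA` and `empty` is `TRUE`.
#' @export
robustness_region <- function(beta, se, x_used, resolution = 0.01, x_max = 50) {
  if (inherits(x_used, "halfnormal_h1")) x_used <- x_used$x
  stopifnot(is.finite(beta), se > 0, x_used > 0, resolution > 0, x_max > x_used)
  B_used <- bf_halfnormal(beta, se, x_used)
  ref <- conclusion_category(B_used)
  grid <- seq(resolution, x_max, by = resolution)
  cats <- conclusion_category(bf_halfnormal(beta, se, grid))
  hit <- which(cats == ref)
  out <- list(lo = NA_real_, hi = NA_real_, category = ref,
              x_used = x_used, B_used = B_used, empty = TRUE)
  class(out) <- "robustness_region"
  if (!length(hit)) return(out)
  i0 <- which.min(abs(grid - x_used))
  if (cats[i0] != ref) i0 <- hit[which.min(abs(grid[hit] - x_used))]
  runs <- split(hit, cumsum(c(1L, diff(hit) != 1L)))
  run <- runs[[which(vapply(runs, function(r) i0 %in% r, logical(1)))]]
  lo <- grid[run[1]]
  hi <- grid[run[length(run)]]
  # B -> 1 as x -> 0+, so an ambiguous run touching the grid origin extends to 0
  if (run[1] == 1L && ref == "ambiguous") lo <- 0
  if (run[length(run)] == length(grid)) hi <- Inf
  if (ref == "substantial_null") hi <- Inf
  out$lo <- round(lo, 2)
  out$hi <- if (is.finite(hi)) round(hi, 2) else hi
  out$empty <- FALSE
  out
}

#' @export
print.robustness_region <- function(x, ...) {
  if (x$empty) {
    cat(sprintf("Robustness region: empty (no scale reproduces '%s')\n", x$category))
  } else {
    cat(sprintf("Robustness region [%s]: %.2f : %s (x used = %.3g, B = %.3f)\n",
                x$category, x$lo, if (is.finite(x$hi)) sprintf("%.2f", x$hi) else "Inf",
                x$x_used, x$B_used))
  }
  invisible(x)
}

new_halfnormal_h1 <- function(x, derivation_case, inputs) {
  stopifnot(is.finite(x), x > 0)
  structure(list(x = x, derivation_case = derivation_case, inputs = inputs),
            class = "halfnormal_h1")
}

#' @export
print.halfnormal_h1 <- function(x, ...) {
  cat(sprintf("Half-normal H1 model: scale x = %.4g (%s)\n", x$x, x$derivation_case))
  invisible(x)
}

#' Prior scale for a predicted main effect of training condition
#'
#' For contrasts where H1 predicts a main-effect advantage of the pooled
#' high-variability conditions, the maximal plausible group difference arises
#' when the low-variability group sits at task baseline and the other group
#' above the grand mean by as much as the grand mean exceeds baseline, i.e. a
#' difference of `2 * (p_bar - b)` in log-odds. Treating that maximum as
#' roughly two prior SDs gives the half-normal scale `x = p_bar - b`.
#'
#' @param p_bar_logodds Grand-mean performance in log-odds (the centred-model
#'   intercept).
#' @param baseline_logodds Minimal/chance performance for the task in
#'   log-odds; see [chance_logodds()].
#' @return A `halfnormal_h1` object with `derivation_case = "main_effect"`.
#' @export
scale_main_effect <- function(p_bar_logodds, baseline_logodds) {
  x <- p_bar_logodds - baseline_logodds
  if (!is.finite(x) || x <= 0) {
    stop("grand mean must exceed the baseline on the log-odds scale; got x = ",
         format(x))
  }
  new_halfnormal_h1(x, "main_effect",
                    list(p_bar = p_bar_logodds, b = baseline_logodds))
}

#' Chance/minimal performance in log-odds for the battery's task formats
#'
#' @param task_kind One of `"two_afc"` (two-alternative forced choice, chance
#'   1/2), `"four_way_tone"` (four-way tone identification, chance 1/4),
#'   `"pinyin_minimal"` (open transcription with no chance level; minimal
#'   performance taken as one correct response out of 72, i.e. 1/72),
#'   `"three_oddity"` (three-interval oddity, chance 1/3).
#' @return The logit of the chance proportion, a non-positive scalar.
#' @export
chance_logodds <- function(task_kind = c("two_afc", "four_way_tone",
                                         "pinyin_minimal", "three_oddity")) {
  task_kind <- match.arg(task_kind)
  p <- switch(task_kind,
              two_afc = 1 / 2,
              four_way_tone = 1 / 4,
              pinyin_minimal = 1 / 72,
              three_oddity = 1 / 3)
  stats::qlogis(p)
}

#' Prior scale for a session-by-condition interaction
#'
#' The maximal interaction arises when the low-variability group shows no
#' pre-to-post improvement and the pooled high-variability group improves by
#' twice the average, i.e. a difference of `2 * t_bar`; half of that maximum
#' gives the scale `x = t_bar`.
#'
#' @param t_bar Mean pre-to-post improvement across conditions (the
#'   test-session main effect, log-odds); must be positive.
#' @return A `halfnormal_h1` object with
#'   `derivation_case = "session_interaction"`.
#' @export
scale_session_interaction <- function(t_bar) {
  if (!is.finite(t_bar) || t_bar <= 0) {
    stop("mean session effect `t_bar` must be positive; got ", format(t_bar))
  }
  new_halfnormal_h1(t_bar, "session_interaction", list(t_bar = t_bar))
}

#' Prior scale for an aptitude-by-condition interaction
#'
#' The maximal two-way interaction arises when aptitude has no effect in the
#' low-variability group and twice the average effect in the other, giving a
#' maximum of `2 * a_bar` and hence scale `x = a_bar`.
#'
#' @param a_bar Mean effect of aptitude across conditions (log-odds per
#'   aptitude unit); must be positive.
#' @return A `halfnormal_h1` object with
#'   `derivation_case = "aptitude_interaction"`.
#' @export
scale_aptitude_interaction <- function(a_bar) {
  if (!is.finite(a_bar) || a_bar <= 0) {
    stop("mean aptitude effect `a_bar` must be positive; got ", format(a_bar))
  }
  new_halfnormal_h1(a_bar, "aptitude_interaction", list(a_bar = a_bar))
}

#' Prior scale for the three-way aptitude x session x condition interaction
#'
#' Based on half the gap between the maximal possible aptitude effect on the
#' task (`maxa`, from the scale of the measure, see [max_aptitude_effect()])
#' and the baseline aptitude effect actually observed at pre-test (`ba`):
#' `x = (maxa - ba) / 2`.
#'
#' @param maxa Maximal aptitude effect per aptitude unit (log-odds).
#' @param ba Baseline (pre-test) aptitude effect (log-odds); must satisfy
#'   `maxa > ba >= 0`.
#' @return A `halfnormal_h1` object with `derivation_case = "threeway"`.
#' @export
scale_threeway <- function(maxa, ba) {
  if (!is.finite(maxa) || !is.finite(ba) || ba < 0 || maxa <= ba) {
    stop("need maximal aptitude effect > baseline aptitude effect >= 0; got maxa = ",
         format(maxa), ", ba = ", format(ba))
  }
  new_halfnormal_h1((maxa - ba) / 2, "threeway", list(maxa = maxa, ba = ba))
}

#' Maximal effect of aptitude per aptitude unit
#'
#' Assumes participants with maximal aptitude perform at ceiling and those
#' with minimal aptitude at chance, and divides that log-odds range by the
#' length of the aptitude predictor to obtain a per-unit slope.
#'
#' @param ceiling_logodds Ceiling performance in log-odds (e.g. 71/72 correct
#'   is `qlogis(71/72)` = 4.263).
#' @param chance_logodds Chance performance in log-odds (negative).
#' @param aptitude_range Length of the aptitude predictor (observed
#'   `max - min` of the scaled score by default in the battery).
#' @return Maximal aptitude effect per unit, a positive scalar.
#' @export
max_aptitude_effect <- function(ceiling_logodds, chance_logodds, aptitude_range) {
  if (!is.finite(aptitude_range) || aptitude_range <= 0) {
    stop("`aptitude_range` must be positive")
  }
  if (ceiling_logodds <= chance_logodds) {
    stop("ceiling must exceed chance on the log-odds scale")
  }
  (ceiling_logodds - chance_logodds) / aptitude_range
}

#' Smallest sample size at which the evidence would reach a criterion
#'
#' Projects the Bayes factor to larger samples under the standard assumption
#' that the coefficient estimate stays fixed while its standard error shrinks
#' as `SE(n) = se * sqrt(n0 / n)`. Returns the smallest integer `n` at which
#' the half-normal-prior Bayes factor drops to or below `criterion`
#' (substantial evidence for the null by default).
#'
#' @inheritParams bf_halfnormal
#' @param n0 Sample size at which `se` was observed.
#' @param criterion Evidence threshold (default 1/3).
#' @param n_max Largest sample size scanned (default 100000).
#' @return A list with `n` (smallest attaining sample size, or `NA`),
#'   `attainable` (logical), `B_at_n`, and `criterion`. When `beta` is too far
#'   from zero in the predicted direction, shrinking the SE strengthens H1
#'   instead and the criterion is never reached; this is reported with
#'   `attainable = FALSE` and the Bayes factor at `n_max`.
#' @export
required_sample_size <- function(beta, se, x, n0, criterion = 1 / 3,
                                 n_max = 1e5) {
  if (inherits(x, "halfnormal_h1")) x <- x$x
  stopifnot(is.finite(beta), se > 0, x > 0, n0 > 0, criterion > 0)
  n_grid <- seq.int(ceiling(n0), n_max)
  B <- bf_halfnormal(beta, se * sqrt(n0 / n_grid), x)
  idx <- which(B <= criterion)
  if (!length(idx)) {
    return(list(n = NA_integer_, attainable = FALSE,
                B_at_n = B[length(B)], criterion = criterion,
                n_scanned = n_max))
  }
  n_star <- n_grid[idx[1]]
  list(n = as.integer(n_star), attainable = TRUE,
       B_at_n = B[idx[1]], criterion = criterion)
}
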