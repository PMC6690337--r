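#' Fit a logistic (mixed) model with an automatic random-effects fallback
#'
#' Fits a logistic mixed-effects model by maximum likelihood (via
#' \pkg{lme4}'s `glmer` with the BOBYQA optimiser) and, on non-convergence,
#' walks down a deterministic fallback ladder: the full random-effects
#' structure as specified, then the same structure with correlations between
#' random effects removed (every `(terms | g)` becomes `(terms || g)`), then
#' random intercepts only. The level actually used is recorded so that model
#' simplifications are explicit rather than ad hoc. A formula with no random
#' effects is fitted as an ordinary logistic regression with `glm`.
#'
#' For a model whose only random effect is a scalar per-group intercept, the
#' likelihood is integrated with adaptive Gauss-Hermite quadrature
#' (`nAGQ = 9` by default); multivariate random effects use the Laplace
#' approximation (`nAGQ = 1`), which is the standard practice for these
#' designs.
#'
#' @param formula Model formula in `lme4` syntax, e.g.
#'   `correct ~ session_c * condition_HV + (1 + session_c | subject_id)`.
#'   The outcome must be binary (0/1 or logical).
#' @param data Data frame of trial records (typically augmented by
#'   [build_contrasts()]).
#' @param nAGQ `"auto"` (default: 9-node adaptive Gauss-Hermite when the
#'   random part is a single scalar intercept, Laplace otherwise) or an
#'   integer passed to `glmer`.
#' @param separation_cap Absolute log-odds beyond which a coefficient is
#'   flagged as a possible separation artefact (default 10).
#' @return An object of class `"glmm_fit"`: a list with `coefficients`
#'   (tibble: `term`, `estimate`, `se`, `z`, `p`, `separation_flag`),
#'   `fallback_level` (`"full"`, `"no_correlations"`, `"intercept_only"`, or
#'   `"fixed_only"` for a `glm` fit), `converged`, `singular`, `logLik`,
#'   `ranef_vcov` (list of random-effect covariance matrices), `nAGQ`,
#'   `formula` (the formula actually fitted), and `model` (the underlying
#'   fit).
#' @export
fit_glmm <- function(formula, data, nAGQ = "auto", separation_cap = 10) {
  stopifnot(inherits(formula, "formula"), is.data.frame(data))
  resp <- all.vars(formula)[1]
  y <- data[[resp]]
  if (is.null(y)) stop("outcome column `", resp, "` not found")
  if (!all(stats::na.omit(unique(as.numeric(y))) %in% c(0, 1))) {
    stop("outcome `", resp, "` must be binary (0/1)")
  }
  bars <- lme4::findbars(formula)
  if (is.null(bars)) {
    fit <- stats::glm(formula, family = stats::binomial(), data = data)
    if (any(is.na(stats::coef(fit)))) {
      aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
      stop("rank-deficient design; aliased term(s): ",
           paste(aliased, collapse = ", "))
    }
    return(new_glmm_fit(fit, formula, "fixed_only", converged = fit$converged,
                        singular = FALSE, nAGQ = NA_integer_,
                        separation_cap = separation_cap))
  }

  ladder <- fallback_ladder(formula)
  last_fit <- NULL
  for (level in names(ladder)) {
    f <- ladder[[level]]
    n_agq <- resolve_nagq(nAGQ, f)
    fit <- try_glmer(f, data, n_agq)
    last_fit <- fit
    if (fit$converged) {
      return(new_glmm_fit(fit$model, f, level, converged = TRUE,
                          singular = fit$singular, nAGQ = n_agq,
                          separation_cap = separation_cap))
    }
  }
  if (is.null(last_fit$model)) {
    stop("model could not be fitted at any fallback level: ", last_fit$message)
  }
  warning("model did not converge at any fallback level; returning the ",
          "intercept-only fit with converged = FALSE")
  new_glmm_fit(last_fit$model, ladder[[length(ladder)]],
               names(ladder)[length(ladder)], converged = FALSE,
               singular = last_fit$singular, nAGQ = resolve_nagq(nAGQ, ladder[[length(ladder)]]),
               separation_cap = separation_cap)
}

# The deterministic simplification ladder: full structure, correlations
# removed, intercepts only. Steps that do not change the formula are dropped.
fallback_ladder <- function(formula) {
  bars <- lme4::findbars(formula)
  fixed <- lme4::nobars(formula)
  fixed_str <- paste(deparse(fixed), collapse = " ")
  bar_str <- function(b, sep) {
    sprintf("(%s %s %s)", deparse(b[[2]]), sep, deparse(b[[3]]))
  }
  full <- formula
  nocorr_terms <- vapply(bars, function(b) {
    multi <- length(attr(stats::terms(stats::reformulate(deparse(b[[2]]))), "term.labels")) > 0 &&
      deparse(b[[2]]) != "1"
    bar_str(b, if (multi) "||" else "|")
  }, character(1))
  nocorr <- stats::as.formula(
    paste(fixed_str, "+", paste(nocorr_terms, collapse = " + ")),
    env = environment(formula))
  groups <- unique(vapply(bars, function(b) deparse(b[[3]]), character(1)))
  int_only <- stats::as.formula(
    paste(fixed_str, "+", paste(sprintf("(1 | %s)", groups), collapse = " + ")),
    env = environment(formula))
  ladder <- list(full = full, no_correlations = nocorr, intercept_only = int_only)
  keep <- !duplicated(vapply(ladder, function(f) paste(deparse(f), collapse = ""),
                             character(1)))
  ladder[keep]
}

resolve_nagq <- function(nAGQ, formula) {
  if (identical(nAGQ, "auto")) {
    bars <- lme4::findbars(formula)
    scalar <- length(bars) == 1 && deparse(bars[[1]][[2]]) == "1"
    if (scalar) 9L else 1L
  } else {
    as.integer(nAGQ)
  }
}

try_glmer <- function(formula, data, nAGQ) {
  warned <- character()
  model <- withCallingHandlers(
    tryCatch(
      lme4::glmer(formula, data = data, family = stats::binomial(),
                  nAGQ = nAGQ,
                  control = lme4::glmerControl(optimizer = "bobyqa")),
      error = function(e) e
    ),
    warning = function(w) {
      warned <<- c(warned, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (inherits(model, "error")) {
    return(list(model = NULL, converged = FALSE, singular = FALSE,
                message = conditionMessage(model)))
  }
  msgs <- model@optinfo$conv$lme4$messages
  # a boundary (singular) fit is a converged fit with a variance estimated
  # at zero, not an optimisation failure; it is tracked separately
  msgs <- msgs[!grepl("singular", msgs, ignore.case = TRUE)]
  conv_warn <- grepl("converge|convergence", warned, ignore.case = TRUE) &
    !grepl("singular", warned, ignore.case = TRUE)
  converged <- model@optinfo$conv$opt == 0 && length(msgs) == 0 &&
    !any(conv_warn)
  list(model = model, converged = converged,
       singular = lme4::isSingular(model), message = "")
}

new_glmm_fit <- function(model, formula, fallback_level, converged, singular,
                         nAGQ, separation_cap) {
  if (inherits(model, "glm")) {
    cm <- summary(model)$coefficients
    ll <- as.numeric(stats::logLik(model))
    rvc <- list()
  } else {
    cm <- summary(model)$coefficients
    ll <- as.numeric(stats::logLik(model))
    rvc <- lapply(lme4::VarCorr(model), function(m) {
      attr(m, "stddev") <- NULL; attr(m, "correlation") <- NULL
      m[, , drop = FALSE]
    })
  }
  est <- cm[, 1]
  se <- cm[, 2]
  z <- est / se
  coefs <- tibble::tibble(
    term = rownames(cm),
    estimate = unname(est),
    se = unname(se),
    z = unname(z),
    p = unname(2 * stats::pnorm(-abs(z))),
    separation_flag = unname(abs(est) > separation_cap)
  )
  if (any(coefs$separation_flag)) {
    warning("possible separation: |estimate| > ", separation_cap,
            " for term(s): ",
            paste(coefs$term[coefs$separation_flag], collapse = ", "))
  }
  structure(list(coefficients = coefs, fallback_level = fallback_level,
                 converged = converged, singular = singular, logLik = ll,
                 ranef_vcov = rvc, nAGQ = nAGQ, formula = formula,
                 model = model),
            class = "glmm_fit")
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Logistic mixed model fit (", x$fallback_level,
      if (!x$converged) ", NOT converged" else "",
      if (x$singular) ", singular" else "", ")\n", sep = "")
  cat("  ", paste(deparse(x$formula), collapse = " "), "\n", sep = "")
  cat(sprintf("  logLik = %.3f\n", x$logLik))
  print(x$coefficients, n = Inf)
  invisible(x)
}

#' Wald coefficient report for a fitted model
#'
#' Returns the coefficient table with Wald `z = estimate / se` and two-sided
#' normal-approximation p-values, sorted by term name (intercept first).
#'
#' @param fit A `"glmm_fit"` from [fit_glmm()].
#' @return A tibble with columns `term`, `estimate`, `se`, `z`, `p`.
#' @export
wald_table <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  tab <- fit$coefficients[, c("term", "estimate", "se", "z", "p")]
  is_int <- tab$term == "(Intercept)"
  dplyr::bind_rows(tab[is_int, ], tab[!is_int, ][order(tab$term[!is_int]), ])
}

#' Extract one coefficient (estimate and SE) from a fit
#'
#' Convenience accessor used when feeding model coefficients into the
#' Bayes-factor machinery.
#'
#' @param fit A `"glmm_fit"`.
#' @param term Coefficient name as it appears in the model summary.
#' @return A list with `estimate`, `se`, `z`, `p`.
#' @export
coef_of <- function(fit, term) {
  stopifnot(inherits(fit, "glmm_fit"))
  row <- fit$coefficients[fit$coefficients$term == term, ]
  if (nrow(row) != 1) {
    stop("term `", term, "` not found in fit; available: ",
         paste(fit$coefficients$term, collapse = ", "))
  }
  as.list(row[, c("estimate", "se", "z", "p")])
}
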