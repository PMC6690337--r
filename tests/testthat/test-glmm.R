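test_that("a fixed-effects-only fit reproduces closed-form and IRLS estimates", {
  d <- data.frame(correct = rep(c(1, 1, 1, 0), 25))
  fit <- fit_glmm(correct ~ 1, d)
  expect_identical(fit$fallback_level, "fixed_only")
  expect_equal(fit$coefficients$estimate, stats::qlogis(0.75), tolerance = 1e-8)

  set.seed(21)
  n <- 400
  d2 <- data.frame(x1 = stats::rnorm(n), x2 = stats::rbinom(n, 1, 0.5) - 0.5)
  d2$correct <- stats::rbinom(n, 1, stats::plogis(0.3 + 0.8 * d2$x1 - 0.5 * d2$x2))
  fit2 <- fit_glmm(correct ~ x1 + x2, d2)
  oracle <- irls_logistic(cbind(1, d2$x1, d2$x2), d2$correct)
  expect_equal(fit2$coefficients$estimate, oracle, tolerance = 1e-4,
               ignore_attr = TRUE)
})

test_that("the fallback ladder is constructed and walked deterministically", {
  lad <- tonebattery:::fallback_ladder(
    correct ~ a * b + (1 + a + b | subject_id))
  expect_identical(names(lad), c("full", "no_correlations", "intercept_only"))
  expect_match(paste(deparse(lad$no_correlations), collapse = ""),
               "\\|\\|", all = FALSE)
  expect_match(paste(deparse(lad$intercept_only), collapse = ""),
               "\\(1 \\| subject_id\\)")
  # an intercept-only spec collapses to a single rung
  lad2 <- tonebattery:::fallback_ladder(correct ~ a + (1 | g))
  expect_identical(names(lad2), "full")

  set.seed(33)
  d <- data.frame(subject_id = rep(sprintf("S%02d", 1:12), each = 20))
  d$a <- stats::rnorm(nrow(d))
  d$correct <- stats::rbinom(nrow(d), 1, stats::plogis(0.4 + 0.3 * d$a))
  f1 <- fit_glmm(correct ~ a + (1 | subject_id), d)
  f2 <- fit_glmm(correct ~ a + (1 | subject_id), d)
  expect_identical(f1$fallback_level, f2$fallback_level)
  expect_equal(f1$coefficients, f2$coefficients)
})

test_that("Wald statistics are internally consistent and sorted", {
  set.seed(5)
  d <- data.frame(subject_id = rep(sprintf("S%02d", 1:10), each = 30))
  d$z1 <- stats::rnorm(nrow(d))
  d$correct <- stats::rbinom(nrow(d), 1, stats::plogis(0.2 + 0.4 * d$z1))
  fit <- fit_glmm(correct ~ z1 + (1 | subject_id), d)
  tab <- wald_table(fit)
  expect_identical(tab$term[1], "(Intercept)")
  expect_equal(tab$z, tab$estimate / tab$se)
  expect_equal(tab$p, 2 * stats::pnorm(-abs(tab$z)))
  co <- coef_of(fit, "z1")
  expect_equal(co$z, co$estimate / co$se)
  expect_error(coef_of(fit, "nonexistent"), "not found")
})

test_that("binary-outcome and rank checks reject bad inputs, separation is flagged", {
  d <- data.frame(correct = c(0, 1, 2, 1))
  expect_error(fit_glmm(correct ~ 1, d), "binary")
  d2 <- data.frame(correct = rep(c(0, 1), 20), x = 1)
  d2$x2 <- d2$x  # aliased
  expect_error(fit_glmm(correct ~ x + x2, d2), "rank|aliased")
  # perfectly separated predictor
  d3 <- data.frame(correct = rep(c(0, 1), each = 20),
                   x = rep(c(-1, 1), each = 20))
  w <- testthat::capture_warnings(fit <- fit_glmm(correct ~ x, d3))
  expect_true(any(grepl("separation", w)))
  expect_true(any(fit$coefficients$separation_flag))
})
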