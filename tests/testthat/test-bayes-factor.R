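test_that("closed form agrees with independent numerical integration", {
  set.seed(11)
  beta <- stats::runif(40, -2, 2)
  se <- stats::runif(40, 0.05, 1)
  x <- stats::runif(40, 0.05, 5)
  b_closed <- bf_halfnormal(beta, se, x)
  b_num <- bf_halfnormal(beta, se, x, method = "integration")
  expect_true(all(abs(b_closed - b_num) < 1e-6))
  # exact marginal-likelihood ratio at beta = 0, se = 1, x = 1
  expect_equal(bf_halfnormal(0, 1, 1), 1 / sqrt(2), tolerance = 1e-10)
})

test_that("a vanishing prior scale collapses H1 onto H0 and diffuseness penalises the null effect", {
  expect_equal(bf_halfnormal(0.4, 0.2, 1e-8), 1, tolerance = 1e-3)
  expect_equal(bf_halfnormal(-1.3, 0.6, 1e-8), 1, tolerance = 1e-3)
  # at beta = 0, B strictly decreases in the scale
  grid <- seq(0.05, 6, by = 0.05)
  B <- bf_halfnormal(0, 0.4, grid)
  expect_true(all(diff(B) < 0))
})

test_that("conclusion categories use the substantial-evidence thresholds with boundaries ambiguous", {
  expect_identical(conclusion_category(0.219), "substantial_null")
  expect_identical(conclusion_category(0.5), "ambiguous")
  expect_identical(conclusion_category(4.0), "substantial_H1")
  expect_identical(conclusion_category(1 / 3), "ambiguous")
  expect_identical(conclusion_category(3), "ambiguous")
  expect_error(conclusion_category(-1), "positive")
})

test_that("prior-scale derivation rules implement the stated arithmetic and reject degenerate inputs", {
  expect_equal(scale_main_effect(1.0986, 0)$x, 1.0986)
  expect_equal(scale_main_effect(-0.213, -4.263)$x, 4.05)
  expect_error(scale_main_effect(0, 0), "exceed")
  expect_error(scale_main_effect(-1, 0), "exceed")

  expect_equal(scale_session_interaction(0.31)$x, 0.31)
  expect_identical(scale_session_interaction(0.395)$derivation_case,
                   "session_interaction")
  expect_error(scale_session_interaction(0), "positive")

  expect_equal(scale_aptitude_interaction(0.171)$x, 0.171)
  expect_equal(scale_aptitude_interaction(0.129)$x, 0.129)
  expect_error(scale_aptitude_interaction(-0.1), "positive")

  expect_equal(scale_threeway(1.0, 0.2)$x, 0.4)
  expect_error(scale_threeway(0.5, 0.5), "baseline")
  # back-solved so that (maxa - ba) / 2 reproduces a printed scale
  expect_equal(scale_threeway(0.89, 0.2)$x, 0.345)

  expect_equal(max_aptitude_effect(4.263, -1.099, 5.0), 1.0724)
  expect_error(max_aptitude_effect(4.263, 4.263, 5.0), "exceed")
  expect_error(max_aptitude_effect(4.263, -1.099, 0), "positive")
})

test_that("chance and ceiling log-odds match the task formats", {
  expect_equal(chance_logodds("two_afc"), 0)
  expect_equal(chance_logodds("four_way_tone"), stats::qlogis(1 / 4))
  expect_equal(chance_logodds("pinyin_minimal"), stats::qlogis(1 / 72))
  expect_equal(chance_logodds("three_oddity"), stats::qlogis(1 / 3))
  expect_error(chance_logodds("roulette"))
})

test_that("robustness regions bracket the conclusion and respect the null-evidence convention", {
  rr <- robustness_region(0.13, 0.228, 1.71)
  expect_identical(rr$category, "substantial_null")
  expect_equal(rr$lo, 1.11, tolerance = 0.05)
  expect_identical(rr$hi, Inf)

  rr6 <- robustness_region(0.006, 0.127, 0.171)
  expect_identical(rr6$category, "ambiguous")
  expect_equal(rr6$lo, 0)
  expect_equal(rr6$hi, 0.354, tolerance = 0.05)

  # the category holds strictly inside and flips just outside the endpoints
  inside <- conclusion_category(bf_halfnormal(0.13, 0.228, rr$lo + 0.01))
  outside <- conclusion_category(bf_halfnormal(0.13, 0.228, rr$lo - 0.02))
  expect_identical(inside, "substantial_null")
  expect_false(identical(outside, "substantial_null"))
  in6 <- conclusion_category(bf_halfnormal(0.006, 0.127, rr6$hi - 0.01))
  out6 <- conclusion_category(bf_halfnormal(0.006, 0.127, rr6$hi + 0.02))
  expect_identical(in6, "ambiguous")
  expect_false(identical(out6, "ambiguous"))

  # substantial-null references always extend to infinite scales
  for (b in c(-0.4, -0.05, 0.1)) {
    r <- robustness_region(b, 0.15, 2)
    if (r$category == "substantial_null") expect_identical(r$hi, Inf)
  }
})

test_that("sample-size projection matches an exhaustive-scan oracle and the stated bound", {
  res <- required_sample_size(0.006, 0.127, 0.171, n0 = 60)
  expect_true(res$attainable)
  expect_gt(res$n, 300)

  # brute-force oracle over n = 60..5000
  ns <- 60:5000
  B <- vapply(ns, function(n) bf_halfnormal(0.006, 0.127 * sqrt(60 / n), 0.171),
              numeric(1))
  expect_identical(res$n, ns[which(B <= 1 / 3)[1]])

  # already-satisfied inputs return the current sample size
  expect_identical(required_sample_size(0.0, 0.05, 1.0, n0 = 40)$n, 40L)

  # a clear effect in the predicted direction never reaches null evidence
  res2 <- required_sample_size(1.0, 0.1, 1.0, n0 = 60, n_max = 2000)
  expect_false(res2$attainable)
  expect_true(is.na(res2$n))
})
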