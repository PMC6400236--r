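test_that("top_n selects maxima with multiset semantics", {
  expect_identical(top_n(c(1, 5, 3, 2), 2), c(5, 3))
  expect_identical(top_n(c(4, 4, 4), 2), c(4, 4))
  expect_error(top_n(c(1, 2, 3, 4), 5), "1 <= n")
  expect_error(top_n(c(1, 2), 0), "1 <= n")
})

test_that("flip maps maxima to strictly positive minima and back", {
  expect_equal(flip(c(5, 3), 0.5), c(0.5, 2.5))
  expect_equal(flip(7, 1), 1)
  expect_error(flip(numeric(0), 1), "empty")
  expect_error(flip(c(1, 2), 0), "positive")
  # involution up to the anchor: double flipping restores the multiset
  # shape exactly, shifted by the constant (delta - min)
  m <- c(9.5, 7, 6.2, 3)
  ff <- flip(flip(m, 0.25), 0.25)
  expect_equal(diff(sort(ff)), diff(sort(m)), tolerance = 1e-12)
  expect_equal(ff - m, rep(0.25 - min(m), length(m)), tolerance = 1e-12)
  expect_true(all(flip(m, 0.25) >= 0.25))
})

test_that("fit_tail composes top_n, flip and the Weibull MLE deterministically", {
  set.seed(61)
  x <- rnorm(2e4, 100, 10)
  tm <- fit_tail(x, 250, offset_delta = 0.1, condition = "olfaction")
  expect_s3_class(tm, "evt_tail")
  expect_gt(tm$weibull$shape, 0)
  expect_gt(tm$weibull$scale, 0)
  expect_identical(tm$anchor, max(x))
  expect_identical(fit_tail(x, 250, offset_delta = 0.1,
                            condition = "olfaction"), tm)
  # fitted likelihood attains the brute-force grid optimum on the
  # flipped maxima
  fl <- flip(top_n(x, 250), 0.1)
  grid <- weibull_grid_best(fl, c(0.3, 4), c(0.5, 8))
  expect_gte(attr(tm$weibull, "loglik"), grid$loglik)
  expect_error(fit_tail(c(7, 7, 7, 1), 3), "degenerate")
  expect_error(fit_tail(x, 2), ">= 3")
})

test_that("response probabilities form a proper CDF on the response axis", {
  set.seed(62)
  tm <- fit_tail(rnorm(5000, 100, 10), 100)
  top <- tm$anchor + tm$offset_delta
  expect_equal(response_probability(tm, top), 1)
  expect_equal(response_probability(tm, top + 50), 1)
  expect_lt(response_probability(tm, -1e6), 1e-12)
  grid <- seq(tm$anchor - 60, tm$anchor + 5, length.out = 1000)
  pr <- response_probability(tm, grid)
  expect_true(all(diff(pr) >= 0))
  expect_true(all(pr >= 0 & pr <= 1))
})

test_that("response probability matches a Monte-Carlo draw from the fitted tail", {
  set.seed(63)
  tm <- fit_tail(rnorm(5000, 100, 10), 100)
  x_mid <- tm$anchor - 2 # inside the fitted tail
  set.seed(64)
  w <- rweibull(1e6, tm$weibull$shape, tm$weibull$scale)
  mc <- 1 - mean(w < tm$anchor + tm$offset_delta - x_mid)
  expect_lt(abs(response_probability(tm, x_mid) - mc), 0.01)
})

test_that("sensitivity shift is zero for identical or saturated models", {
  set.seed(65)
  x <- rnorm(1000, 100, 10)
  a <- fit_tail(x, 50)
  b <- fit_tail(x, 50)
  expect_equal(sensitivity_shift(a, b, 75), 0)
  set.seed(66)
  y <- rnorm(1000, 40, 5)
  cc <- fit_tail(y, 50)
  expect_equal(sensitivity_shift(a, cc, 1e6), 0) # both saturate to 1
})

test_that("the olfaction tail model is more sensitive at threshold on canonical data", {
  shifts <- vapply(1:10, function(s) {
    d <- canonical_data(8200 + s)
    min(vapply(c(3L, 8L), function(n) {
      sensitivity_shift(fit_tail(d$olfaction$values, n),
                        fit_tail(d$control$values, n), 75)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(shifts > 0))
})

test_that("smaller n gives at least the sensitivity of larger n on the fixture", {
  # an empirical regression on the canonical fixture, not a theorem: the
  # ordering is asserted for the olfaction tuning curves and for the
  # olfaction-minus-control shift (the control curves alone can order
  # either way; see the methods vignette)
  d <- canonical_data(101)
  p_olf <- vapply(c(3L, 8L), function(n)
    response_probability(fit_tail(d$olfaction$values, n), 75), numeric(1))
  expect_gte(p_olf[1], p_olf[2])
  shifts <- vapply(c(3L, 8L), function(n)
    sensitivity_shift(fit_tail(d$olfaction$values, n),
                      fit_tail(d$control$values, n), 75), numeric(1))
  expect_gte(shifts[1], shifts[2])
})

test_that("flipped block maxima of bounded data pass a Weibull GOF test", {
  # data bounded above at 100: block maxima approach the reverse-Weibull
  # extreme-value law, so flipped maxima are Weibull-distributed
  pass <- vapply(1:20, function(s) {
    set.seed(8300 + s)
    x <- runif(1e5, 0, 100)
    maxima <- apply(matrix(x, nrow = 100), 2, max)
    fl <- flip(maxima, 1e-3 * diff(range(maxima)))
    wb <- fit_weibull_mle(fl)
    suppressWarnings(
      ks.test(fl, "pweibull", wb$shape, wb$scale)$p.value) >= 0.01
  }, logical(1))
  expect_gte(mean(pass), 0.9)
})

test_that("evt_tail methods expose coefficients, predictions and simulations", {
  set.seed(67)
  tm <- fit_tail(rnorm(2000, 80, 12), 100, condition = "control")
  expect_named(coef(tm), c("shape", "scale", "anchor", "offset_delta"))
  expect_equal(predict(tm, newdata = c(60, 80)),
               response_probability(tm, c(60, 80)))
  expect_length(predict(tm), 100L)
  s1 <- simulate(tm, nsim = 500, seed = 9)
  s2 <- simulate(tm, nsim = 500, seed = 9)
  expect_identical(s1, s2)
  expect_lte(max(s1), tm$anchor + tm$offset_delta)
  expect_output(print(tm), "Weibull tail model")
  curve <- tail_cdf_curve(tm, 0, 120, 64L)
  expect_true(all(diff(curve$probability) >= 0))
  pdf(NULL)
  expect_no_error(plot(tm, threshold_T = 75))
  dev.off()
})
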