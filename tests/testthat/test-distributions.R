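test_that("Weibull density and CDF match closed forms and base R", {
  p11 <- weibull_params(1, 1)
  expect_equal(weibull_pdf(-1, p11), 0)
  expect_equal(weibull_pdf(1, p11), exp(-1), tolerance = 1e-12)
  expect_equal(weibull_pdf(2, weibull_params(2, 2)), exp(-1),
               tolerance = 1e-12)
  expect_equal(weibull_cdf(0, p11), 0)
  for (k in c(0.5, 1, 2.5))
    expect_equal(weibull_cdf(3, weibull_params(k, 3)), 1 - exp(-1),
                 tolerance = 1e-12)
  # base R as an independent oracle on a grid
  g <- seq(0.05, 12, length.out = 60)
  p <- weibull_params(1.7, 2.2)
  expect_equal(weibull_pdf(g, p), dweibull(g, 1.7, 2.2), tolerance = 1e-12)
  expect_equal(weibull_cdf(g, p), pweibull(g, 1.7, 2.2), tolerance = 1e-12)
  expect_error(weibull_params(0, 1), "positive")
  expect_error(weibull_params(1, -2), "positive")
})

test_that("Weibull CDF agrees with quadrature of the pdf", {
  p <- weibull_params(2, 1.5)
  q <- integrate(function(x) weibull_pdf(x, p), 0, 15, rel.tol = 1e-13)
  expect_equal(weibull_cdf(15, p), q$value, tolerance = 1e-12)
})

test_that("GPD density matches closed forms, the exponential limit and quadrature", {
  expect_equal(gpd_pdf(0, gpd_params(0.5, 2)), 0.5, tolerance = 1e-12)
  expect_equal(gpd_pdf(5, gpd_params(0.3, 2, tau = 5)), 0.5,
               tolerance = 1e-12)
  expect_equal(gpd_pdf(1, gpd_params(1e-12, 1)), exp(-1), tolerance = 1e-6)
  p <- gpd_params(0.5, 2)
  q <- integrate(function(x) gpd_pdf(x, p), 0, 1e4, rel.tol = 1e-10)
  expect_equal(q$value, gpd_cdf(1e4, p), tolerance = 1e-6)
  # negative shape: support bounded above at tau - sigma/k
  pn <- gpd_params(-0.5, 10)
  expect_equal(gpd_pdf(25, pn), 0)
  expect_equal(gpd_cdf(25, pn), 1)
  expect_equal(gpd_cdf(-1, pn), 0)
  qq <- integrate(function(x) gpd_pdf(x, pn), 0, 20, rel.tol = 1e-10)
  expect_equal(qq$value, 1, tolerance = 1e-6)
  expect_error(gpd_params(0.1, 0), "positive")
})

test_that("pdfs integrate to one and CDFs differentiate back to pdfs", {
  cases <- list(
    list(pdf = function(x) weibull_pdf(x, weibull_params(0.8, 3)),
         cdf = function(x) weibull_cdf(x, weibull_params(0.8, 3)),
         interior = c(1, 3, 7), upper = 200),
    list(pdf = function(x) gpd_pdf(x, gpd_params(0.2, 5)),
         cdf = function(x) gpd_cdf(x, gpd_params(0.2, 5)),
         interior = c(2, 5, 15), upper = 1e5))
  for (cs in cases) {
    expect_equal(integrate(cs$pdf, 0, cs$upper, rel.tol = 1e-9)$value, 1,
                 tolerance = 1e-6)
    h <- 1e-6
    for (x0 in cs$interior)
      expect_equal((cs$cdf(x0 + h) - cs$cdf(x0 - h)) / (2 * h), cs$pdf(x0),
                   tolerance = 1e-4)
    grid <- seq(0, 50, length.out = 200)
    cv <- cs$cdf(grid)
    expect_true(all(diff(cv) >= 0))
    expect_true(all(cv >= 0 & cv <= 1))
  }
})

test_that("GPD quantile function inverts the CDF", {
  for (k in c(-0.4, 1e-12, 0.3)) {
    p <- gpd_params(k, 7, tau = 2)
    u <- c(0.01, 0.2, 0.5, 0.9, 0.999)
    expect_equal(gpd_cdf(gpd_quantile(u, p), p), u, tolerance = 1e-10)
  }
})

test_that("Gaussian moment estimators are the unbiased closed forms", {
  g <- fit_gaussian(c(1, 2, 3))
  expect_equal(g$mu, 2)
  expect_equal(g$sigma2, 1)
  expect_error(fit_gaussian(c(5, 5, 5)), "variance")
  expect_error(fit_gaussian(3), "at least 2")
  set.seed(41)
  big <- fit_gaussian(rnorm(1e4, 100, 15))
  expect_lt(abs(big$mu - 100), 4 * 15 / sqrt(1e4))
})

test_that("Weibull MLE recovers parameters and attains the grid optimum", {
  set.seed(7)
  x <- rweibull(1e4, 1.5, 3)
  fit <- fit_weibull_mle(x)
  expect_lt(abs(fit$shape - 1.5) / 1.5, 0.05)
  expect_lt(abs(fit$scale - 3) / 3, 0.05)
  expect_true(attr(fit, "converged"))
  # exponential draws are Weibull with unit shape
  set.seed(8)
  e <- rexp(1e4, 1)
  expect_lt(abs(fit_weibull_mle(e)$shape - 1), 0.05)
  expect_error(fit_weibull_mle(c(0, 1, 2)), "strictly positive")
  expect_error(fit_weibull_mle(c(2, 2, 2)), "degenerate")
  # optimizer beats a 200x200 brute-force grid on a small instance
  set.seed(9)
  xs <- rweibull(200, 1.5, 3)
  fs <- fit_weibull_mle(xs)
  grid <- weibull_grid_best(xs, c(0.5, 3), c(1, 6))
  expect_gte(attr(fs, "loglik"), grid$loglik)
  # independent MLE oracle
  ref <- suppressWarnings(fitdistrplus::fitdist(xs, "weibull"))
  expect_equal(attr(fs, "loglik"), as.numeric(ref$loglik), tolerance = 1e-6)
})

test_that("GPD MLE recovers parameters and attains the grid optimum", {
  set.seed(11)
  x <- rgpd_ref(1e4, 0.3, 10)
  fit <- fit_gpd_mle(x)
  expect_lt(abs(fit$shape - 0.3), 0.05)
  expect_lt(abs(fit$scale - 10) / 10, 0.05)
  # exponential draws are the GPD shape -> 0 limit
  set.seed(12)
  e <- rexp(1e4, 1 / 5)
  expect_lt(abs(fit_gpd_mle(e)$shape), 0.05)
  expect_error(fit_gpd_mle(c(-1, 1, 2), tau = 0), ">= tau")
  set.seed(13)
  xs <- rgpd_ref(300, 0.3, 10)
  fs <- fit_gpd_mle(xs)
  grid <- gpd_grid_best(xs, c(-0.2, 0.9), c(4, 20))
  expect_gte(attr(fs, "loglik"), grid$loglik)
})

test_that("MLE estimation error shrinks as the sample grows", {
  sizes <- c(100, 1000, 10000)
  for (fam in c("weibull", "gpd")) {
    med_err <- vapply(sizes, function(n) {
      errs <- vapply(1:20, function(s) {
        set.seed(1000 + s)
        if (fam == "weibull")
          abs(fit_weibull_mle(rweibull(n, 1.5, 3))$shape - 1.5)
        else abs(fit_gpd_mle(rgpd_ref(n, 0.3, 10))$shape - 0.3)
      }, numeric(1))
      median(errs)
    }, numeric(1))
    expect_true(all(diff(med_err) < 0))
  }
})

test_that("log-likelihood sums log densities with strict support checks", {
  expect_equal(log_likelihood("weibull", weibull_params(1, 1), 1), -1,
               tolerance = 1e-12)
  expect_equal(log_likelihood("gaussian", gaussian_params(0, 1),
                              numeric(0)), 0)
  set.seed(21)
  x <- rnorm(100, 3, 2)
  expect_equal(log_likelihood("gaussian", gaussian_params(3, 4), x),
               sum(dnorm(x, 3, 2, log = TRUE)), tolerance = 1e-10)
  expect_error(log_likelihood("weibull", weibull_params(1, 1), c(1, -1)),
               "support")
  expect_error(log_likelihood("generalized pareto", gpd_params(0.2, 1, 5),
                              c(6, 4)), "support")
  expect_error(log_likelihood("generalized pareto", gpd_params(-0.5, 10),
                              c(5, 30)), "support")
})
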