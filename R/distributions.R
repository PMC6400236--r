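# Density/CDF evaluation and maximum-likelihood fitting for the three
# families the tail analysis manipulates directly: Gaussian, two-parameter
# Weibull, Generalized Pareto (GPD).

#' Parameter containers for the core distribution families
#'
#' Constructors validate their invariants and return lightweight classed
#' lists. `gaussian_params` holds the mean `mu` (spikes/s) and variance
#' `sigma2`; `weibull_params` the dimensionless shape `k > 0` and scale
#' `lambda > 0` (units of the fitted axis); `gpd_params` the shape `k`,
#' scale `sigma > 0` (spikes/s) and threshold `tau` (spikes/s). GPD support
#' is `x >= tau`, additionally bounded above by `tau - sigma/k` when
#' `k < 0`.
#'
#' @param mu,sigma2 Gaussian mean and variance (`sigma2 > 0`).
#' @param shape,scale Weibull/GPD shape and scale.
#' @param tau GPD threshold (default 0, matching non-negative spike rates).
#' @return an object of class `"gaussian_params"`, `"weibull_params"` or
#'   `"gpd_params"`.
#' @name dist-params
NULL

#' @rdname dist-params
#' @export
gaussian_params <- function(mu, sigma2) {
  if (!is_scalar_num(mu) || !is_scalar_num(sigma2) || sigma2 <= 0)
    stop_domain("gaussian_params: 'mu' must be finite and 'sigma2' > 0")
  structure(list(mu = mu, sigma2 = sigma2), class = "gaussian_params")
}

#' @rdname dist-params
#' @export
weibull_params <- function(shape, scale) {
  if (!is_scalar_num(shape) || !is_scalar_num(scale) || shape <= 0 ||
      scale <= 0)
    stop_domain("weibull_params: 'shape' and 'scale' must be positive")
  structure(list(shape = shape, scale = scale), class = "weibull_params")
}

#' @rdname dist-params
#' @export
gpd_params <- function(shape, scale, tau = 0) {
  if (!is_scalar_num(shape) || !is_scalar_num(scale) || !is_scalar_num(tau) ||
      scale <= 0)
    stop_domain("gpd_params: 'scale' must be positive and parameters finite")
  structure(list(shape = shape, scale = scale, tau = tau),
            class = "gpd_params")
}

#' @export
print.gaussian_params <- function(x, ...) {
  cat(sprintf("Gaussian(mu = %.6g, sigma2 = %.6g)\n", x$mu, x$sigma2))
  invisible(x)
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull(shape k = %.6g, scale lambda = %.6g)\n",
              x$shape, x$scale))
  invisible(x)
}

#' @export
print.gpd_params <- function(x, ...) {
  cat(sprintf("GPD(shape k = %.6g, scale sigma = %.6g, threshold tau = %.6g)\n",
              x$shape, x$scale, x$tau))
  invisible(x)
}

#' Two-parameter Weibull density and distribution function
#'
#' The density is `(k/lambda) (x/lambda)^(k-1) exp(-(x/lambda)^k)` for
#' `x >= 0` and 0 below; the CDF is `1 - exp(-(x/lambda)^k)`. The support
#' is the standard lower-bounded-at-zero one: spike rates cannot be
#' negative, which is exactly why the Weibull is the extreme-value family
#' used here (on the flipped axis, see [fit_tail()]).
#'
#' @param x numeric vector of evaluation points.
#' @param params a [weibull_params()] object.
#' @return numeric vector of densities (non-negative) or probabilities in
#'   `[0, 1]`.
#' @export
#' @examples
#' weibull_pdf(1, weibull_params(1, 1)) # exp(-1)
#' weibull_cdf(2, weibull_params(3, 2)) # 1 - exp(-1)
weibull_pdf <- function(x, params) {
  params <- as_weibull_params(params)
  k <- params$shape; lam <- params$scale
  out <- numeric(length(x))
  pos <- is.finite(x) & x > 0
  out[pos] <- (k / lam) * (x[pos] / lam)^(k - 1) * exp(-(x[pos] / lam)^k)
  # x == 0: density is 0 for k > 1, 1/lambda for k == 1, +Inf for k < 1;
  # report the k >= 1 values and cap the k < 1 singularity at Inf.
  zero <- is.finite(x) & x == 0
  out[zero] <- if (k > 1) 0 else if (k == 1) 1 / lam else Inf
  out
}

#' @rdname weibull_pdf
#' @export
weibull_cdf <- function(x, params) {
  params <- as_weibull_params(params)
  out <- numeric(length(x))
  pos <- is.finite(x) & x > 0
  out[pos] <- 1 - exp(-(x[pos] / params$scale)^params$shape)
  out[x == Inf] <- 1
  out
}

as_weibull_params <- function(p) {
  if (inherits(p, "weibull_params")) return(p)
  if (is.list(p) && all(c("shape", "scale") %in% names(p)))
    return(weibull_params(p$shape, p$scale))
  stop_domain("expected a 'weibull_params' object")
}

as_gpd_params <- function(p) {
  if (inherits(p, "gpd_params")) return(p)
  if (is.list(p) && all(c("shape", "scale") %in% names(p)))
    return(gpd_params(p$shape, p$scale, p$tau %||% 0))
  stop_domain("expected a 'gpd_params' object")
}

as_gaussian_params <- function(p) {
  if (inherits(p, "gaussian_params")) return(p)
  if (is.list(p) && all(c("mu", "sigma2") %in% names(p)))
    return(gaussian_params(p$mu, p$sigma2))
  stop_domain("expected a 'gaussian_params' object")
}

# shape values closer to zero than this are evaluated with the exponential
# limiting form, for numerical stability of (1 + k z)^(-1 - 1/k)
GPD_SHAPE_EPS <- 1e-9

#' Generalized Pareto density, distribution and quantile functions
#'
#' Density `(1/sigma) (1 + k (x - tau)/sigma)^(-1 - 1/k)` on the support,
#' 0 outside; for `|k| < 1e-9` the exponential limiting form
#' `(1/sigma) exp(-(x - tau)/sigma)` is used. `gpd_cdf` and `gpd_quantile`
#' are the matching closed forms; `gpd_rand` draws by inverse-CDF sampling.
#'
#' @param x numeric vector of evaluation points.
#' @param p probabilities in `[0, 1]` (for `gpd_quantile`).
#' @param n number of draws (for `gpd_rand`).
#' @param params a [gpd_params()] object.
#' @return densities, probabilities, quantiles or draws respectively.
#' @export
#' @examples
#' gpd_pdf(0, gpd_params(0.5, 2)) # 1/sigma = 0.5
gpd_pdf <- function(x, params) {
  params <- as_gpd_params(params)
  k <- params$shape; s <- params$scale; tau <- params$tau
  z <- (x - tau) / s
  out <- numeric(length(x))
  if (abs(k) < GPD_SHAPE_EPS) {
    ok <- is.finite(z) & z >= 0
    out[ok] <- exp(-z[ok]) / s
  } else {
    ok <- is.finite(z) & z >= 0 & (1 + k * z) > 0
    out[ok] <- (1 + k * z[ok])^(-1 - 1 / k) / s
  }
  out
}

#' @rdname gpd_pdf
#' @export
gpd_cdf <- function(x, params) {
  params <- as_gpd_params(params)
  k <- params$shape; s <- params$scale
  z <- (x - params$tau) / s
  z[z < 0] <- 0
  if (abs(k) < GPD_SHAPE_EPS) return(1 - exp(-z))
  zz <- 1 + k * z
  out <- 1 - pmax(zz, 0)^(-1 / k)
  if (k < 0) out[z >= -1 / k] <- 1
  out
}

#' @rdname gpd_pdf
#' @export
gpd_quantile <- function(p, params) {
  params <- as_gpd_params(params)
  if (any(p < 0 | p > 1)) stop_domain("gpd_quantile: p must lie in [0, 1]")
  k <- params$shape; s <- params$scale
  if (abs(k) < GPD_SHAPE_EPS) q <- -log(1 - p)
  else q <- ((1 - p)^(-k) - 1) / k
  params$tau + s * q
}

#' @rdname gpd_pdf
#' @export
gpd_rand <- function(n, params) {
  gpd_quantile(runif(n), params)
}

#' Unbiased Gaussian moment estimators
#'
#' The mean is the sample mean and the variance the sum of squared
#' deviations divided by `n - 1` (the unbiased estimator), which is how
#' the with-olfaction spike-rate data are summarised before any tail
#' modeling.
#'
#' @param samples numeric vector, `n >= 2`, not all values identical.
#' @return a [gaussian_params()] object.
#' @export
#' @examples
#' fit_gaussian(c(1, 2, 3)) # mu = 2, sigma2 = 1
fit_gaussian <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 2L)
    stop_domain("fit_gaussian: need at least 2 observations")
  if (!all(is.finite(samples)))
    stop_domain("fit_gaussian: samples must be finite")
  s2 <- var(samples)
  if (s2 == 0)
    stop_domain("fit_gaussian: zero variance (all values identical)")
  gaussian_params(mean(samples), s2)
}

#' Maximum-likelihood fit of the two-parameter Weibull
#'
#' Solved by profile likelihood: for fixed shape `k` the scale MLE is
#' `lambda(k) = (mean(x^k))^(1/k)`, and the profile score in `k`,
#' `1/k + mean(log x) - sum(x^k log x)/sum(x^k)`, is driven to zero by
#' safeguarded Newton iterations (tolerance 1e-10, at most 200 steps,
#' bisection fallback inside a maintained bracket). Deterministic for a
#' fixed input. Samples are internally rescaled by their mean for
#' numerical stability; the shape is scale-invariant.
#'
#' @param samples numeric vector, `n >= 3`, all strictly positive, not all
#'   identical.
#' @return a [weibull_params()] object with attributes `loglik`,
#'   `converged` and `iterations`.
#' @export
fit_weibull_mle <- function(samples) {
  if (!is.numeric(samples) || length(samples) < 3L)
    stop_domain("fit_weibull_mle: need at least 3 observations")
  if (!all(is.finite(samples)) || any(samples <= 0))
    stop_domain("fit_weibull_mle: all samples must be strictly positive")
  if (diff(range(samples)) == 0)
    stop_domain("fit_weibull_mle: degenerate input (all values identical)")
  sc <- mean(samples)
  x <- samples / sc
  lx <- log(x)
  mlx <- mean(lx)
  score <- function(k) {
    xk <- x^k
    s0 <- sum(xk); s1 <- sum(xk * lx); s2 <- sum(xk * lx * lx)
    g <- 1 / k + mlx - s1 / s0
    dg <- -1 / k^2 - (s2 * s0 - s1 * s1) / s0^2
    c(g, dg)
  }
  # score is decreasing in k; bracket a sign change
  lo <- 1e-8; hi <- 1
  while (score(hi)[1] > 0 && hi < 1e6) hi <- hi * 2
  if (score(hi)[1] > 0)
    stop_domain("fit_weibull_mle: failed to bracket the profile score")
  k <- min(max(1.2825 / max(sd(lx), 1e-12), lo * 2), hi) # Gumbel-slope start
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(200L)) {
    sv <- score(k)
    if (sv[1] > 0) lo <- k else hi <- k
    step <- sv[1] / sv[2]
    k_new <- k - step
    if (!is.finite(k_new) || k_new <= lo || k_new >= hi)
      k_new <- (lo + hi) / 2 # safeguarded bisection
    if (abs(k_new - k) < 1e-10 * max(1, k) && abs(sv[1]) < 1e-8) {
      k <- k_new; converged <- TRUE; break
    }
    k <- k_new
  }
  if (!converged && abs(score(k)[1]) < 1e-6) converged <- TRUE
  if (!converged)
    stop_domain("fit_weibull_mle: profile Newton failed to converge")
  lam <- mean(x^k)^(1 / k) * sc
  out <- weibull_params(k, lam)
  attr(out, "loglik") <- log_likelihood("weibull", out, samples)
  attr(out, "converged") <- converged
  attr(out, "iterations") <- iter
  out
}

gpd_negloglik <- function(theta, y) {
  k <- theta[1]; s <- exp(theta[2])
  z <- 1 + k * y / s
  if (any(z <= 0)) return(1e10)
  n <- length(y)
  if (abs(k) < GPD_SHAPE_EPS) n * log(s) + sum(y) / s
  else n * log(s) + (1 + 1 / k) * sum(log(z))
}

#' Maximum-likelihood fit of the two-parameter Generalized Pareto
#'
#' The threshold `tau` is held fixed (default 0, the lower bound of
#' non-negative spike rates) and `(k, sigma)` maximize the GPD likelihood
#' of the exceedances `samples - tau`. Optimization is Nelder-Mead on
#' `(k, log sigma)` from a moment-based start plus two fixed fallback
#' starts, keeping the best optimum; deterministic for a fixed input.
#'
#' @param samples numeric vector with all values `>= tau`, `n >= 3`.
#' @param tau fixed threshold parameter.
#' @return a [gpd_params()] object with attributes `loglik` and
#'   `converged`.
#' @export
fit_gpd_mle <- function(samples, tau = 0) {
  if (!is.numeric(samples) || length(samples) < 3L)
    stop_domain("fit_gpd_mle: need at least 3 observations")
  if (!is_scalar_num(tau)) stop_domain("fit_gpd_mle: 'tau' must be finite")
  if (!all(is.finite(samples)) || any(samples < tau))
    stop_domain("fit_gpd_mle: all samples must be >= tau")
  y <- samples - tau
  if (diff(range(y)) == 0)
    stop_domain("fit_gpd_mle: degenerate input (all values identical)")
  m <- mean(y); v <- var(y)
  k0 <- 0.5 * (1 - m^2 / v)
  s0 <- max(m * (1 - k0), 1e-8)
  starts <- list(c(k0, log(s0)), c(0.1, log(max(m, 1e-8))),
                 c(-0.1, log(max(m, 1e-8))))
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      optim(st, gpd_negloglik, y = y, method = "Nelder-Mead",
            control = list(maxit = 1000, reltol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || best$value >= 1e10)
    stop_domain("fit_gpd_mle: optimization failed to converge")
  out <- gpd_params(best$par[1], exp(best$par[2]), tau)
  attr(out, "loglik") <- -best$value
  attr(out, "converged") <- best$convergence == 0
  out
}

#' Log-likelihood of a sample under a fitted family
#'
#' Sums log densities for the families handled directly by the tail
#' analysis. An empty sample has log-likelihood 0 (empty sum); samples
#' outside the family's support are an error rather than a silent `-Inf`.
#'
#' @param family one of `"gaussian"`, `"weibull"`, `"generalized pareto"`.
#' @param params the matching parameter object.
#' @param samples numeric vector (possibly empty).
#' @return the log-likelihood in nats.
#' @export
log_likelihood <- function(family, params, samples) {
  family <- match.arg(family, c("gaussian", "weibull", "generalized pareto"))
  if (length(samples) == 0L) return(0)
  if (!all(is.finite(samples)))
    stop_domain("log_likelihood: samples must be finite")
  switch(family,
    gaussian = {
      p <- as_gaussian_params(params)
      sum(dnorm(samples, p$mu, sqrt(p$sigma2), log = TRUE))
    },
    weibull = {
      p <- as_weibull_params(params)
      if (any(samples <= 0))
        stop_domain("log_likelihood: Weibull support violation (x <= 0)")
      sum(dweibull(samples, p$shape, p$scale, log = TRUE))
    },
    `generalized pareto` = {
      p <- as_gpd_params(params)
      if (any(samples < p$tau))
        stop_domain("log_likelihood: GPD support violation (x < tau)")
      if (p$shape < 0 && any(samples > p$tau - p$scale / p$shape))
        stop_domain("log_likelihood: GPD support violation (x above upper bound)")
      d <- gpd_pdf(samples, p)
      if (any(d <= 0))
        stop_domain("log_likelihood: GPD support violation")
      sum(log(d))
    })
}

# ---- distribution specs: a (family, params) pair usable by the samplers ----

#' Bundle a family name with its parameters for generative sampling
#'
#' The samplers and the pipeline pass distributions around as a
#' `dist_spec`: a family tag plus a parameter object. Supported families
#' are the three the analysis samples from: `"gaussian"`, `"weibull"` and
#' `"generalized pareto"`.
#'
#' @param family family tag.
#' @param params matching parameter object.
#' @return an object of class `"dist_spec"`.
#' @export
dist_spec <- function(family, params) {
  family <- match.arg(family, c("gaussian", "weibull", "generalized pareto"))
  params <- switch(family,
    gaussian = as_gaussian_params(params),
    weibull = as_weibull_params(params),
    `generalized pareto` = as_gpd_params(params))
  structure(list(family = family, params = params), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("distribution spec:", x$family, "\n")
  print(x$params)
  invisible(x)
}

dist_pdf <- function(spec, x) {
  switch(spec$family,
    gaussian = dnorm(x, spec$params$mu, sqrt(spec$params$sigma2)),
    weibull = weibull_pdf(x, spec$params),
    `generalized pareto` = gpd_pdf(x, spec$params))
}

dist_cdf <- function(spec, x) {
  switch(spec$family,
    gaussian = pnorm(x, spec$params$mu, sqrt(spec$params$sigma2)),
    weibull = weibull_cdf(x, spec$params),
    `generalized pareto` = gpd_cdf(x, spec$params))
}

dist_quantile <- function(spec, p) {
  switch(spec$family,
    gaussian = qnorm(p, spec$params$mu, sqrt(spec$params$sigma2)),
    weibull = qweibull(p, spec$params$shape, spec$params$scale),
    `generalized pareto` = gpd_quantile(p, spec$params))
}

dist_rand <- function(spec, n) {
  switch(spec$family,
    gaussian = rnorm(n, spec$params$mu, sqrt(spec$params$sigma2)),
    weibull = rweibull(n, spec$params$shape, spec$params$scale),
    `generalized pareto` = gpd_rand(n, spec$params))
}

dist_log_pdf_fn <- function(spec, nonneg = FALSE) {
  # scalar log-density closure for the MCMC inner loop
  fn <- switch(spec$family,
    gaussian = {
      mu <- spec$params$mu; s <- sqrt(spec$params$sigma2)
      function(x) dnorm(x, mu, s, log = TRUE)
    },
    weibull = {
      k <- spec$params$shape; lam <- spec$params$scale
      function(x) if (x <= 0) -Inf else
        log(k / lam) + (k - 1) * log(x / lam) - (x / lam)^k
    },
    `generalized pareto` = {
      k <- spec$params$shape; s <- spec$params$scale; tau <- spec$params$tau
      if (abs(k) < GPD_SHAPE_EPS)
        function(x) if (x < tau) -Inf else -log(s) - (x - tau) / s
      else
        function(x) {
          z <- 1 + k * (x - tau) / s
          if (x < tau || z <= 0) -Inf else -log(s) + (-1 - 1 / k) * log(z)
        }
    })
  if (!nonneg) return(fn)
  function(x) if (x < 0) -Inf else fn(x)
}
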