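# The candidate-family catalog behind BIC model selection. Sixteen named
# continuous families plus the Gaussian. Families whose density lives in
# base R are fitted through fitdistrplus; the remaining densities and fits
# are implemented here (no installed package provides them). The Weibull
# and Generalized Pareto entries reuse the package's own MLE fitters.

# log densities for families without a base-R implementation -----------------

dgumbel_min_log <- function(x, mu, s) {
  z <- (x - mu) / s
  z - exp(z) - log(s)
}

dgev_log <- function(x, loc, scale, shape) {
  z <- (x - loc) / scale
  if (abs(shape) < 1e-9) return(-z - exp(-z) - log(scale))
  t <- 1 + shape * z
  out <- rep(-Inf, length(x))
  ok <- t > 0
  out[ok] <- -log(scale) + (-1 - 1 / shape) * log(t[ok]) - t[ok]^(-1 / shape)
  out
}

dinvgauss_log <- function(x, mu, lambda) {
  0.5 * (log(lambda) - log(2 * pi) - 3 * log(x)) -
    lambda * (x - mu)^2 / (2 * mu^2 * x)
}

dbisa_log <- function(x, scale, shape) {
  t1 <- sqrt(x / scale); t2 <- sqrt(scale / x)
  log(t1 + t2) - log(2 * shape * x) + dnorm((t1 - t2) / shape, log = TRUE)
}

dnakagami_log <- function(x, m, omega) {
  log(2) + m * log(m) - lgamma(m) - m * log(omega) +
    (2 * m - 1) * log(x) - m * x^2 / omega
}

drician_log <- function(x, nu, sigma) {
  s2 <- sigma^2
  z <- x * nu / s2
  log(x) - log(s2) - (x^2 + nu^2) / (2 * s2) +
    log(besselI(z, 0, expon.scaled = TRUE)) + z
}

dtls_log <- function(x, loc, scale, df) {
  dt((x - loc) / scale, df, log = TRUE) - log(scale)
}

drayleigh_log <- function(x, sigma) {
  log(x) - 2 * log(sigma) - x^2 / (2 * sigma^2)
}

# generic penalized Nelder-Mead MLE on a transformed parameter vector
mle_optim <- function(x, nll, start, maxit = 2000) {
  o <- optim(start, nll, method = "Nelder-Mead",
             control = list(maxit = maxit, reltol = 1e-10))
  if (o$value >= 1e9) stop_domain("MLE optimization failed (support/overflow)")
  o
}

fit_via_fitdist <- function(x, distr, start = NULL) {
  args <- list(data = x, distr = distr, method = "mle")
  if (!is.null(start)) args$start <- start
  f <- suppressWarnings(do.call(fitdistrplus::fitdist, args))
  list(params = as.list(f$estimate), loglik = as.numeric(f$loglik))
}

# catalog table ---------------------------------------------------------------

# Each entry: n_params; feasible(x) returning TRUE or a reason string;
# fit(x) returning list(params, loglik).
catalog_table <- function() {
  pos <- function(x) if (all(x > 0)) TRUE else
    "support (0, Inf) excludes non-positive observations"
  nonneg <- function(x) if (all(x >= 0)) TRUE else
    "support [0, Inf) excludes negative observations"
  anyx <- function(x) TRUE
  list(
    "beta" = list(
      n_params = 2L,
      feasible = function(x) if (all(x > 0 & x < 1)) TRUE else
        "support (0, 1) excludes observations outside the unit interval",
      fit = function(x) {
        m <- mean(x); v <- var(x)
        c0 <- max(m * (1 - m) / v - 1, 0.1)
        fit_via_fitdist(x, "beta",
                        start = list(shape1 = m * c0, shape2 = (1 - m) * c0))
      }),
    "birnbaum-saunders" = list(
      n_params = 2L, feasible = pos,
      fit = function(x) {
        s <- mean(x); r <- 1 / mean(1 / x)
        g0 <- max(sqrt(2 * (sqrt(s / r) - 1)), 0.05)
        b0 <- sqrt(s * r)
        nll <- function(th)
          -sum(dbisa_log(x, exp(th[1]), exp(th[2])))
        o <- mle_optim(x, nll, c(log(b0), log(g0)))
        list(params = list(scale = exp(o$par[1]), shape = exp(o$par[2])),
             loglik = -o$value)
      }),
    "exponential" = list(
      n_params = 1L, feasible = nonneg,
      fit = function(x) {
        rate <- 1 / mean(x)
        list(params = list(rate = rate),
             loglik = sum(dexp(x, rate, log = TRUE)))
      }),
    "extreme value" = list( # Gumbel, minimum convention
      n_params = 2L, feasible = anyx,
      fit = function(x) {
        s0 <- max(sqrt(6 * var(x)) / pi, 1e-8)
        mu0 <- mean(x) + 0.5772156649 * s0
        nll <- function(th) -sum(dgumbel_min_log(x, th[1], exp(th[2])))
        o <- mle_optim(x, nll, c(mu0, log(s0)))
        list(params = list(location = o$par[1], scale = exp(o$par[2])),
             loglik = -o$value)
      }),
    "gamma" = list(
      n_params = 2L, feasible = pos,
      fit = function(x) {
        m <- mean(x); v <- var(x)
        fit_via_fitdist(x, "gamma",
                        start = list(shape = m^2 / v, rate = m / v))
      }),
    "generalized extreme value" = list(
      n_params = 3L, feasible = anyx,
      fit = function(x) {
        s0 <- max(sqrt(6 * var(x)) / pi, 1e-8)
        mu0 <- mean(x) - 0.5772156649 * s0
        nll <- function(th) {
          ld <- dgev_log(x, th[1], exp(th[2]), th[3])
          if (any(!is.finite(ld))) return(1e10)
          -sum(ld)
        }
        o <- mle_optim(x, nll, c(mu0, log(s0), 0.1))
        list(params = list(location = o$par[1], scale = exp(o$par[2]),
                           shape = o$par[3]),
             loglik = -o$value)
      }),
    "generalized pareto" = list(
      n_params = 2L, feasible = nonneg,
      fit = function(x) {
        p <- fit_gpd_mle(x, tau = 0)
        list(params = list(shape = p$shape, scale = p$scale, tau = 0),
             loglik = attr(p, "loglik"))
      }),
    "inverse gaussian" = list(
      n_params = 2L, feasible = pos,
      fit = function(x) {
        mu <- mean(x)
        lambda <- length(x) / sum(1 / x - 1 / mu)
        list(params = list(mean = mu, shape = lambda),
             loglik = sum(dinvgauss_log(x, mu, lambda)))
      }),
    "logistic" = list(
      n_params = 2L, feasible = anyx,
      fit = function(x)
        fit_via_fitdist(x, "logis",
                        start = list(location = median(x),
                                     scale = max(sqrt(3 * var(x)) / pi, 1e-8)))),
    "log-logistic" = list(
      n_params = 2L, feasible = pos,
      fit = function(x) {
        # logistic MLE on the log scale; jacobian sum(log x) converts loglik
        lx <- log(x)
        f <- fit_via_fitdist(lx, "logis",
                             start = list(location = median(lx),
                                          scale = max(sqrt(3 * var(lx)) / pi,
                                                      1e-8)))
        list(params = list(shape = 1 / f$params$scale,
                           scale = exp(f$params$location)),
             loglik = f$loglik - sum(lx))
      }),
    "log-normal" = list(
      n_params = 2L, feasible = pos,
      fit = function(x) {
        lx <- log(x)
        ml <- mean(lx); sl <- sqrt(mean((lx - ml)^2))
        list(params = list(meanlog = ml, sdlog = sl),
             loglik = sum(dlnorm(x, ml, sl, log = TRUE)))
      }),
    "nakagami" = list(
      n_params = 2L, feasible = pos,
      fit = function(x) {
        om0 <- mean(x^2)
        m0 <- max(om0^2 / max(var(x^2), 1e-12), 0.55)
        nll <- function(th)
          -sum(dnakagami_log(x, 0.5 + exp(th[1]), exp(th[2])))
        o <- mle_optim(x, nll, c(log(max(m0 - 0.5, 0.05)), log(om0)))
        list(params = list(m = 0.5 + exp(o$par[1]), omega = exp(o$par[2])),
             loglik = -o$value)
      }),
    "rayleigh" = list(
      n_params = 1L, feasible = pos,
      fit = function(x) {
        sigma <- sqrt(mean(x^2) / 2)
        list(params = list(sigma = sigma),
             loglik = sum(drayleigh_log(x, sigma)))
      }),
    "rician" = list(
      n_params = 2L, feasible = pos,
      fit = function(x) {
        m2 <- mean(x^2)
        nu0 <- sqrt(max(2 * mean(x)^2 - m2, 1e-6))
        s20 <- max((m2 - nu0^2) / 2, 1e-6)
        nll <- function(th) {
          ld <- drician_log(x, exp(th[1]), exp(th[2]))
          if (any(!is.finite(ld))) return(1e10)
          -sum(ld)
        }
        o <- mle_optim(x, nll, c(log(nu0), 0.5 * log(s20)))
        list(params = list(nu = exp(o$par[1]), sigma = exp(o$par[2])),
             loglik = -o$value)
      }),
    "t location-scale" = list(
      n_params = 3L, feasible = anyx,
      fit = function(x) {
        s0 <- max(sd(x) * 0.9, 1e-8)
        nll <- function(th)
          -sum(dtls_log(x, th[1], exp(th[2]), exp(th[3])))
        o <- mle_optim(x, nll, c(median(x), log(s0), log(5)))
        list(params = list(location = o$par[1], scale = exp(o$par[2]),
                           df = exp(o$par[3])),
             loglik = -o$value)
      }),
    "weibull" = list(
      n_params = 2L, feasible = pos,
      fit = function(x) {
        p <- fit_weibull_mle(x)
        list(params = list(shape = p$shape, scale = p$scale),
             loglik = attr(p, "loglik"))
      }),
    "gaussian" = list(
      n_params = 2L, feasible = anyx,
      fit = function(x) {
        mu <- mean(x); s <- sqrt(mean((x - mu)^2)) # MLE variance
        list(params = list(mu = mu, sigma2 = s^2),
             loglik = sum(dnorm(x, mu, s, log = TRUE)))
      })
  )
}

#' Names of the candidate distribution families
#'
#' The sixteen-family catalog used by [select_distribution()], plus
#' `"gaussian"`. Parameter counts entering the BIC penalty are fixed per
#' family (1 for exponential and Rayleigh; 3 for the generalized extreme
#' value and t location-scale families; 2 otherwise; the Generalized
#' Pareto is fitted with its threshold held at 0 and so counts 2).
#'
#' @param include_gaussian append `"gaussian"` to the sixteen catalog
#'   names (default `TRUE`).
#' @return character vector of family names.
#' @export
catalog_families <- function(include_gaussian = TRUE) {
  fams <- names(catalog_table())
  if (!include_gaussian) fams <- setdiff(fams, "gaussian")
  fams
}
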