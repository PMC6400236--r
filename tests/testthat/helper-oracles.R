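# Shared oracles and fixture builders. Oracles are written independently of
# the implementation paths they check.

# reference GPD sampler by direct inverse-CDF transform of uniforms
rgpd_ref <- function(n, shape, scale, tau = 0) {
  u <- runif(n)
  if (abs(shape) < 1e-12) tau + scale * (-log(u))
  else tau + (scale / shape) * (u^(-shape) - 1)
}

# brute-force Weibull log-likelihood over a shape x scale grid
weibull_grid_best <- function(x, k_range, lam_range, m = 200L) {
  ks <- seq(k_range[1], k_range[2], length.out = m)
  lams <- seq(lam_range[1], lam_range[2], length.out = m)
  slx <- sum(log(x)); n <- length(x)
  best <- -Inf; best_par <- c(NA, NA)
  for (k in ks) {
    sxk <- sum(x^k)
    # loglik(k, lam) = n log k - n k log lam + (k-1) slx - lam^-k sxk
    ll <- n * log(k) - n * k * log(lams) + (k - 1) * slx - lams^(-k) * sxk
    i <- which.max(ll)
    if (ll[i] > best) { best <- ll[i]; best_par <- c(k, lams[i]) }
  }
  list(loglik = best, par = best_par)
}

# brute-force GPD (tau = 0) log-likelihood over a shape x scale grid
gpd_grid_best <- function(y, k_range, s_range, m = 200L) {
  ks <- seq(k_range[1], k_range[2], length.out = m)
  ss <- seq(s_range[1], s_range[2], length.out = m)
  n <- length(y)
  best <- -Inf; best_par <- c(NA, NA)
  for (k in ks) for (s in ss) {
    z <- 1 + k * y / s
    if (any(z <= 0)) next
    ll <- if (abs(k) < 1e-12) -n * log(s) - sum(y) / s
          else -n * log(s) - (1 + 1 / k) * sum(log(z))
    if (ll > best) { best <- ll; best_par <- c(k, s) }
  }
  list(loglik = best, par = best_par)
}

canonical_data <- function(seed) generate_responses(canonical_config(), seed)

# build a normalized train/test pair from two scalar pools
norm_split <- function(ds, seed = 1L, train_frac = 0.8) {
  parts <- split_dataset(ds, train_frac = train_frac, seed = seed)
  nm <- minmax_normalize(parts$train$features)
  parts$train$features <- nm$features
  parts$train$bounds <- nm$bounds
  parts$test$features <- minmax_normalize(parts$test$features,
                                          bounds = nm$bounds)$features
  parts$test$bounds <- nm$bounds
  parts
}
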