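# The extreme-response tail model: select the top-n responses, flip them
# so maxima become minima, fit a two-parameter Weibull to the flipped
# values, and read sensitivities off the back-transformed CDF. The flip is
# needed because the Weibull models minima of lower-bounded data; spike
# rates are bounded below at 0, so after flipping about an anchor the
# upper tail becomes a lower-bounded minimum problem.

#' Select the n largest responses
#'
#' @param samples numeric vector.
#' @param n how many maxima to keep, `1 <= n <= length(samples)`.
#' @return the `n` largest values in descending order; ties keep
#'   duplicates (multiset semantics).
#' @export
#' @examples
#' top_n(c(1, 5, 3, 2), 2) # 5, 3
top_n <- function(samples, n) {
  if (!is.numeric(samples) || length(samples) == 0L)
    stop_domain("top_n: samples must be a non-empty numeric vector")
  if (!is_count(n, 1L) || n > length(samples))
    stop_domain("top_n: n must satisfy 1 <= n <= length(samples)")
  sort(samples, decreasing = TRUE)[seq_len(n)]
}

#' Flip maxima into minima about an anchored offset
#'
#' Maps each maximum `m_i` to `(max_j m_j + offset_delta) - m_i`, so the
#' largest value becomes the smallest (equal to `offset_delta > 0`) and
#' order reverses. All outputs are strictly positive, as two-parameter
#' Weibull fitting requires.
#'
#' @param maxima non-empty numeric vector.
#' @param offset_delta positive offset.
#' @return the flipped values, in the input's order.
#' @export
#' @examples
#' flip(c(5, 3), 0.5) # 0.5, 2.5
flip <- function(maxima, offset_delta) {
  if (!is.numeric(maxima) || length(maxima) == 0L)
    stop_domain("flip: empty input")
  if (!is_scalar_num(offset_delta) || offset_delta <= 0)
    stop_domain("flip: offset_delta must be positive")
  (max(maxima) + offset_delta) - maxima
}

#' Fit the Weibull tail model to the top-n responses
#'
#' Composition of [top_n()], [flip()] and [fit_weibull_mle()]: the n
#' largest responses are flipped about their maximum (the anchor) plus a
#' small positive offset and a two-parameter Weibull is fitted to the
#' flipped values by maximum likelihood. The anchor and offset are
#' recorded so probabilities can be reported back on the original
#' response axis (spikes/s); see [response_probability()]. Deterministic
#' for fixed input.
#'
#' The default offset is `1e-3` times the range of the selected maxima
#' (floor `1e-6`): just enough to make the largest flipped value strictly
#' positive without displacing the fitted tail.
#'
#' @param samples numeric response vector (spikes/s).
#' @param n number of maxima to model, `n >= 3`.
#' @param offset_delta positive flip offset; `NULL` for the default.
#' @param condition optional source-condition label carried in the model.
#' @return an object of class `"evt_tail"` with components `n_top`,
#'   `anchor` (largest selected response), `offset_delta`, `weibull`
#'   ([weibull_params()] on the flipped axis), `maxima`,
#'   `source_condition` and `n_source`. Methods: [print()], [coef()],
#'   [predict()], [plot()], [simulate()].
#' @export
#' @examples
#' set.seed(1)
#' m <- fit_tail(rnorm(1000, 100, 10), n = 50)
#' predict(m, newdata = c(75, 100, 125))
fit_tail <- function(samples, n, offset_delta = NULL, condition = NULL) {
  if (!is_count(n, 3L))
    stop_domain("fit_tail: n must be an integer >= 3")
  m <- top_n(samples, n)
  rng <- diff(range(m))
  if (rng == 0)
    stop_domain("fit_tail: degenerate maxima (top-n values all identical)")
  if (is.null(offset_delta)) offset_delta <- max(1e-6, 1e-3 * rng)
  if (!is_scalar_num(offset_delta) || offset_delta <= 0)
    stop_domain("fit_tail: offset_delta must be positive")
  flipped <- flip(m, offset_delta)
  wb <- fit_weibull_mle(flipped)
  structure(list(n_top = as.integer(n), anchor = max(m),
                 offset_delta = offset_delta, weibull = wb, maxima = m,
                 source_condition = condition,
                 n_source = length(samples)),
            class = "evt_tail")
}

#' Probability that an extreme response does not exceed x
#'
#' The fitted tail CDF mapped back to the response axis:
#' `P(extreme <= x) = 1 - WeibullCDF(anchor + offset - x)` for
#' `x <= anchor + offset`, and 1 above. Non-decreasing in `x` with range
#' `[0, 1]`; total on the reals. A higher value at the response threshold
#' means the regime makes sub-threshold responses more probable -- i.e.
#' tuning is more sensitive.
#'
#' @param model an `"evt_tail"` object.
#' @param x responses (spikes/s), any numeric vector.
#' @return probabilities in `[0, 1]`.
#' @export
response_probability <- function(model, x) {
  if (!inherits(model, "evt_tail"))
    stop_domain("response_probability: expected an 'evt_tail' model")
  arg <- model$anchor + model$offset_delta - x
  out <- numeric(length(x))
  above <- arg <= 0
  out[above] <- 1
  out[!above] <- 1 - weibull_cdf(arg[!above], model$weibull)
  out
}

#' Olfaction-induced sensitivity shift at a response threshold
#'
#' The signed difference of tail probabilities at the threshold:
#' `response_probability(model_olf, T) - response_probability(model_ctrl,
#' T)`. A positive shift means the olfaction regime assigns higher
#' probability to responses at or below the threshold -- visual
#' sensitivity has shifted leftward, making sub-threshold responses
#' probable.
#'
#' @param model_olf,model_ctrl fitted `"evt_tail"` models.
#' @param threshold_T response threshold in spikes/s.
#' @return the signed probability difference.
#' @export
sensitivity_shift <- function(model_olf, model_ctrl, threshold_T) {
  response_probability(model_olf, threshold_T) -
    response_probability(model_ctrl, threshold_T)
}

#' @export
print.evt_tail <- function(x, ...) {
  cat(sprintf("Weibull tail model (top %d of %d%s)\n", x$n_top, x$n_source,
              if (is.null(x$source_condition)) ""
              else paste0(", ", x$source_condition)))
  cat(sprintf("  anchor %.4g spikes/s, offset %.4g\n", x$anchor,
              x$offset_delta))
  cat(sprintf("  flipped-axis Weibull: shape k = %.4g, scale lambda = %.4g\n",
              x$weibull$shape, x$weibull$scale))
  invisible(x)
}

#' @export
coef.evt_tail <- function(object, ...) {
  c(shape = object$weibull$shape, scale = object$weibull$scale,
    anchor = object$anchor, offset_delta = object$offset_delta)
}

#' @rdname fit_tail
#' @param object,newdata an `"evt_tail"` model and responses (spikes/s) at
#'   which to evaluate the tail CDF; `newdata = NULL` evaluates at the
#'   model's own maxima.
#' @param ... unused.
#' @export
predict.evt_tail <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) newdata <- object$maxima
  response_probability(object, newdata)
}

#' @rdname fit_tail
#' @param nsim,seed number of simulated extreme responses and RNG seed
#'   (for `simulate`).
#' @export
simulate.evt_tail <- function(object, nsim = 1, seed = NULL, ...) {
  draw <- function() object$anchor + object$offset_delta -
    rweibull(nsim, object$weibull$shape, object$weibull$scale)
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}

#' @rdname fit_tail
#' @param x an `"evt_tail"` model (for `plot`).
#' @param threshold_T optional threshold marked as a vertical line.
#' @export
plot.evt_tail <- function(x, threshold_T = NULL, ...) {
  lo <- min(x$maxima) - 3 * x$weibull$scale
  hi <- x$anchor + x$offset_delta
  if (!is.null(threshold_T)) lo <- min(lo, threshold_T * 0.9)
  grid <- seq(lo, hi, length.out = 512)
  plot(grid, response_probability(x, grid), type = "l",
       xlab = "response (spikes/s)", ylab = "P(extreme response <= x)",
       main = sprintf("Weibull tail CDF (top %d)", x$n_top), ...)
  if (!is.null(threshold_T)) abline(v = threshold_T, lty = 2)
  invisible(x)
}

#' Export a tail CDF curve as a two-column data frame
#'
#' @param model an `"evt_tail"` model.
#' @param from,to,length.out evaluation grid on the response axis.
#' @return data frame with columns `response` and `probability`.
#' @export
tail_cdf_curve <- function(model, from, to, length.out = 256L) {
  grid <- seq(from, to, length.out = length.out)
  data.frame(response = grid,
             probability = response_probability(model, grid))
}
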