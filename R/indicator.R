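# The indicator function I(x): a trainable binary classifier (linear SVM
# or multi-layer perceptron) deciding whether a 22-dimensional response
# vector arose under olfactory stimulation (label 1) or not (label 0).

#' Min-max feature normalization
#'
#' Per-column `(x - min) / (max - min)`. With `bounds = NULL` the matrix's
#' own column minima/maxima are used and returned (learn them on the
#' training partition only); with given bounds they are applied, so
#' held-out values may leave `[0, 1]`. Constant columns are zero-filled.
#'
#' @param features numeric matrix.
#' @param bounds `NULL`, or a list with `min` and `max` vectors as
#'   returned by a previous call.
#' @return a list with `features` (normalized matrix) and `bounds`.
#' @export
#' @examples
#' minmax_normalize(matrix(c(0, 5, 10)))$features # 0, 0.5, 1
minmax_normalize <- function(features, bounds = NULL) {
  features <- as.matrix(features)
  if (length(features) == 0L)
    stop_domain("minmax_normalize: empty feature matrix")
  if (is.null(bounds)) {
    bounds <- list(min = apply(features, 2, min),
                   max = apply(features, 2, max))
  } else if (!is.list(bounds) || is.null(bounds$min) || is.null(bounds$max) ||
             length(bounds$min) != ncol(features))
    stop_domain("minmax_normalize: malformed bounds")
  rng <- bounds$max - bounds$min
  out <- sweep(features, 2, bounds$min, "-")
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(out, 2, rng, "/")
  out[, const] <- 0
  list(features = out, bounds = bounds)
}

#' Assemble a labeled dataset from per-condition sample pools
#'
#' Consecutive disjoint groups of `dim` scalar draws form one feature
#' vector (the simplest construction mapping scalar response samples to
#' the classifier's 22-dimensional response-vector space); rows from the
#' olfaction pool get label 1, control rows label 0, and the rows are
#' shuffled with the given seed. Excess scalars that do not fill a
#' complete vector are dropped with a message.
#'
#' @param samples_olf,samples_ctrl `sample_set`s or numeric vectors.
#' @param dim feature dimension (default 22, the number of time bins in a
#'   with-olfaction response).
#' @param seed shuffle seed.
#' @return an object of class `"labeled_dataset"`: `features` (matrix
#'   with `dim` columns), `labels` (0/1 integer vector), `bounds`
#'   (normalization bounds, `NULL` until normalized).
#' @export
assemble_dataset <- function(samples_olf, samples_ctrl, dim = 22L, seed = 1L) {
  vals <- function(x) if (inherits(x, "sample_set")) x$values else
    as.numeric(x)
  o <- vals(samples_olf); c_ <- vals(samples_ctrl)
  if (!is_count(dim, 1L)) stop_domain("assemble_dataset: dim must be >= 1")
  if (length(o) < dim || length(c_) < dim)
    stop_domain("assemble_dataset: fewer than 'dim' values in a sample pool")
  to_rows <- function(v, lab) {
    k <- length(v) %/% dim
    dropped <- length(v) - k * dim
    if (dropped > 0)
      message(sprintf("assemble_dataset: dropping %d excess %s scalars",
                      dropped, if (lab == 1L) "olfaction" else "control"))
    list(x = matrix(v[seq_len(k * dim)], nrow = k, ncol = dim, byrow = TRUE),
         y = rep(lab, k))
  }
  ro <- to_rows(o, 1L); rc <- to_rows(c_, 0L)
  x <- rbind(ro$x, rc$x)
  y <- c(ro$y, rc$y)
  perm <- with_local_seed(seed, sample.int(nrow(x)))
  structure(list(features = x[perm, , drop = FALSE], labels = y[perm],
                 bounds = NULL),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled dataset: %d rows x %d features (%d olfaction, %d control)%s\n",
              nrow(x$features), ncol(x$features), sum(x$labels == 1L),
              sum(x$labels == 0L),
              if (is.null(x$bounds)) "" else ", normalized"))
  invisible(x)
}

#' Stratified train/test split
#'
#' Disjoint, exhaustive, label-stratified partition: within each label the
#' rows are permuted with the given seed and `round(train_frac * n)` go to
#' the training set, preserving class balance to within one row.
#'
#' @param dataset a `"labeled_dataset"` with at least 2 rows.
#' @param train_frac training fraction, strictly inside `(0, 1)`.
#' @param seed permutation seed.
#' @return a list with `train` and `test` labeled datasets.
#' @export
split_dataset <- function(dataset, train_frac = 0.8, seed = 1L) {
  if (!inherits(dataset, "labeled_dataset"))
    stop_domain("split_dataset: expected a 'labeled_dataset'")
  n <- nrow(dataset$features)
  if (n < 2L) stop_domain("split_dataset: need at least 2 rows")
  if (!is_scalar_num(train_frac) || train_frac <= 0 || train_frac >= 1)
    stop_domain("split_dataset: train_frac must lie strictly in (0, 1)")
  idx_train <- with_local_seed(seed, {
    unlist(lapply(unique(dataset$labels), function(lab) {
      rows <- which(dataset$labels == lab)
      rows <- rows[sample.int(length(rows))]
      rows[seq_len(min(length(rows) - 1L,
                       max(1L, round(train_frac * length(rows)))))]
    }), use.names = FALSE)
  })
  take <- function(rows) structure(
    list(features = dataset$features[rows, , drop = FALSE],
         labels = dataset$labels[rows], bounds = dataset$bounds),
    class = "labeled_dataset")
  list(train = take(idx_train), test = take(setdiff(seq_len(n), idx_train)))
}

#' Train the indicator function
#'
#' `kind = "linear_svm"` solves the linear soft-margin SVM
#' `min ||w||^2 + C * sum(xi_i)` subject to
#' `y_i (w.x_i + b) >= 1 - xi_i` (mapped onto `e1071::svm`, whose cost
#' parameter scales the slack term against `||w||^2 / 2`, hence
#' `cost = C/2`). `kind = "mlp"` trains a feed-forward network with one
#' hidden layer of logistic units by backpropagation (`nnet::nnet`,
#' entropy loss). Training is seeded and deterministic.
#'
#' @param train a `"labeled_dataset"` containing both labels, features
#'   already normalized to the training bounds.
#' @param kind `"linear_svm"` or `"mlp"`.
#' @param config options: `C` (soft-margin trade-off, default 4),
#'   `hidden` (hidden units, default 16), `epochs` (default 200).
#' @param seed RNG seed for the MLP's weight initialization.
#' @return an object of class `"indicator_fit"`; for the SVM it carries
#'   the weight vector `w` and bias `b` oriented so `w.x + b > 0` decides
#'   label 1.
#' @export
train_indicator <- function(train, kind = c("linear_svm", "mlp"),
                            config = list(), seed = 1L) {
  kind <- match.arg(kind)
  if (!inherits(train, "labeled_dataset"))
    stop_domain("train_indicator: expected a 'labeled_dataset'")
  if (length(unique(train$labels)) < 2L)
    stop_domain("train_indicator: training data contain a single class")
  x <- train$features
  y <- train$labels
  if (kind == "linear_svm") {
    C <- config$C %||% 4
    if (!is_scalar_num(C) || C <= 0)
      stop_domain("train_indicator: C must be positive")
    fit <- e1071::svm(x = x, y = factor(y, levels = c(0, 1)),
                      kernel = "linear", cost = C / 2, scale = FALSE)
    w <- drop(t(fit$coefs) %*% fit$SV)
    b <- -fit$rho
    # orient (w, b) so that w.x + b > 0 predicts label 1
    pred <- as.integer(as.character(predict(fit, x)))
    raw <- as.integer(drop(x %*% w + b) > 0)
    if (mean(raw == pred) < 0.5) {
      w <- -w; b <- -b
    }
    obj <- structure(list(kind = kind, fit = fit, w = w, b = b, C = C,
                          seed = seed),
                     class = "indicator_fit")
  } else {
    hidden <- config$hidden %||% 16L
    epochs <- config$epochs %||% 200L
    fit <- with_local_seed(seed, {
      nnet::nnet(x = x, y = y, size = hidden, maxit = epochs,
                 entropy = TRUE, decay = 0, trace = FALSE,
                 MaxNWts = 10000L)
    })
    obj <- structure(list(kind = kind, fit = fit, hidden = hidden,
                          epochs = epochs, seed = seed),
                     class = "indicator_fit")
  }
  obj
}

#' @export
print.indicator_fit <- function(x, ...) {
  if (x$kind == "linear_svm")
    cat(sprintf("indicator: linear SVM (C = %g, %d support vectors)\n",
                x$C, nrow(x$fit$SV)))
  else
    cat(sprintf("indicator: MLP (%d logistic hidden units, %d epochs)\n",
                x$hidden, x$epochs))
  invisible(x)
}

#' @rdname train_indicator
#' @param object an `"indicator_fit"`.
#' @param newdata feature matrix (normalized with the training bounds).
#' @param ... unused.
#' @return `predict` returns 0/1 integer labels.
#' @export
predict.indicator_fit <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (object$kind == "linear_svm")
    as.integer(drop(newdata %*% object$w + object$b) > 0)
  else
    as.integer(drop(predict(object$fit, newdata)) > 0.5)
}

#' Test accuracy of a trained indicator
#'
#' @param model an `"indicator_fit"`.
#' @param test a non-empty `"labeled_dataset"` normalized with the
#'   training bounds.
#' @return fraction of correctly predicted labels.
#' @export
evaluate_indicator <- function(model, test) {
  if (!inherits(test, "labeled_dataset") || nrow(test$features) == 0L)
    stop_domain("evaluate_indicator: empty test set")
  mean(predict(model, test$features) == test$labels)
}

#' Repeated train/test evaluation across derived seeds
#'
#' For each repeat a fresh dataset is built by `dataset_factory(seed)`
#' with a seed derived from `base_seed`, split 'train_frac'/'1 -
#' train_frac' with stratification, min-max normalized with bounds
#' learned on the training partition only, trained and evaluated. The
#' spread reported is the standard deviation of the per-repeat test
#' accuracies.
#'
#' @param dataset_factory function of one argument (a seed) returning a
#'   `"labeled_dataset"`.
#' @param kind,config as in [train_indicator()].
#' @param n_repeats number of repeats, `>= 2`.
#' @param base_seed seed from which per-repeat seeds are derived.
#' @param train_frac training fraction.
#' @return an object of class `"eval_result"`: `accuracies` (per repeat),
#'   `mean`, `spread` (sd), `n_repeats`, `train_frac`, `kind`.
#' @export
repeat_eval <- function(dataset_factory, kind = c("linear_svm", "mlp"),
                        config = list(), n_repeats = 5L, base_seed = 1L,
                        train_frac = 0.8) {
  kind <- match.arg(kind)
  if (!is_count(n_repeats, 2L))
    stop_domain("repeat_eval: n_repeats must be an integer >= 2")
  if (!is.function(dataset_factory))
    stop_domain("repeat_eval: dataset_factory must be a function")
  acc <- vapply(seq_len(n_repeats), function(i) {
    s_data <- derive_seed(base_seed, paste0("repeat-data-", i))
    s_split <- derive_seed(base_seed, paste0("repeat-split-", i))
    s_train <- derive_seed(base_seed, paste0("repeat-train-", i))
    ds <- dataset_factory(s_data)
    parts <- split_dataset(ds, train_frac = train_frac, seed = s_split)
    norm <- minmax_normalize(parts$train$features)
    parts$train$features <- norm$features
    parts$train$bounds <- norm$bounds
    parts$test$features <- minmax_normalize(parts$test$features,
                                            bounds = norm$bounds)$features
    parts$test$bounds <- norm$bounds
    model <- train_indicator(parts$train, kind = kind, config = config,
                             seed = s_train)
    evaluate_indicator(model, parts$test)
  }, numeric(1))
  structure(list(accuracies = acc, mean = mean(acc), spread = sd(acc),
                 n_repeats = as.integer(n_repeats), train_frac = train_frac,
                 kind = kind),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("%s: test accuracy %.3f (+/- %.4f sd) over %d repeats (%d/%d split)\n",
              x$kind, x$mean, x$spread, x$n_repeats,
              round(100 * x$train_frac), round(100 * (1 - x$train_frac))))
  invisible(x)
}
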