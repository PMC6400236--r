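test_that("min-max normalization matches the closed form and is idempotent", {
  out <- minmax_normalize(matrix(c(0, 5, 10)))
  expect_equal(drop(out$features), c(0, 0.5, 1))
  const <- minmax_normalize(matrix(7, nrow = 2))
  expect_equal(drop(const$features), c(0, 0))
  m <- matrix(rnorm(40), 10, 4)
  a <- minmax_normalize(m)
  b <- minmax_normalize(m, bounds = a$bounds)
  expect_equal(a$features, b$features)
  expect_true(all(a$features >= 0 & a$features <= 1))
  # held-out data may leave the unit interval under training bounds
  outside <- minmax_normalize(matrix(100, 1, 4), bounds = a$bounds)
  expect_true(any(outside$features > 1))
  expect_error(minmax_normalize(m, bounds = list(min = 1, max = 2)),
               "malformed")
})

test_that("dataset assembly groups consecutive scalars and labels conditions", {
  ds <- assemble_dataset(1:44, 101:144, dim = 22, seed = 1)
  expect_identical(dim(ds$features), c(4L, 22L))
  expect_identical(sum(ds$labels == 1L), 2L)
  expect_identical(sum(ds$labels == 0L), 2L)
  # grouping is by consecutive disjoint blocks
  row_of_first <- which(apply(ds$features, 1, function(r)
    all(r == 1:22)))
  expect_length(row_of_first, 1L)
  expect_identical(ds$labels[row_of_first], 1L)
  expect_message(assemble_dataset(1:1000, 1:1000, dim = 22, seed = 1),
                 "dropping 10 excess")
  expect_error(assemble_dataset(1:10, 1:100, dim = 22), "fewer than")
  # shuffle is seeded
  expect_identical(assemble_dataset(1:44, 101:144, seed = 3),
                   assemble_dataset(1:44, 101:144, seed = 3))
})

test_that("stratified splitting preserves class balance and is seeded", {
  ds <- assemble_dataset(rep(1:22, 50) + runif(1100), rep(23:44, 50),
                         dim = 22, seed = 2)
  parts <- split_dataset(ds, train_frac = 0.8, seed = 5)
  expect_identical(nrow(parts$train$features), 80L)
  expect_identical(nrow(parts$test$features), 20L)
  expect_lte(abs(sum(parts$train$labels == 1L) -
                 sum(parts$train$labels == 0L)), 1L)
  expect_identical(split_dataset(ds, 0.8, seed = 5)$train$labels,
                   parts$train$labels)
  expect_error(split_dataset(ds, train_frac = 1), "strictly in")
  expect_error(split_dataset(ds, train_frac = 0), "strictly in")
})

make_cloud_dataset <- function(seed, gap = 10, n_rows = 100, dim = 22) {
  # two Gaussian clouds with class means 'gap' pooled standard deviations
  # apart in every coordinate
  set.seed(seed)
  x1 <- matrix(rnorm(n_rows * dim, 0, 1), n_rows, dim)
  x0 <- matrix(rnorm(n_rows * dim, gap, 1), n_rows, dim)
  structure(list(features = rbind(x1, x0),
                 labels = c(rep(1L, n_rows), rep(0L, n_rows)),
                 bounds = NULL), class = "labeled_dataset")
}

test_that("both classifier kinds separate disjoint class supports", {
  for (kind in c("linear_svm", "mlp")) {
    parts <- norm_split(make_cloud_dataset(71, gap = 10, n_rows = 500))
    fit <- train_indicator(parts$train, kind = kind, seed = 7)
    expect_equal(evaluate_indicator(fit, parts$train), 1.0)
    expect_gte(evaluate_indicator(fit, parts$test), 0.99)
  }
  single <- make_cloud_dataset(72)
  single$labels <- rep(1L, length(single$labels))
  expect_error(train_indicator(single, "linear_svm"), "single class")
})

test_that("a linear SVM cannot solve the XOR arrangement", {
  xor_pts <- matrix(0, 4, 22)
  xor_pts[, 1] <- c(0, 0, 1, 1)
  xor_pts[, 2] <- c(0, 1, 0, 1)
  ds <- structure(list(features = xor_pts, labels = c(0L, 1L, 1L, 0L),
                       bounds = NULL), class = "labeled_dataset")
  fit <- train_indicator(ds, "linear_svm", config = list(C = 100))
  train_acc <- mean(predict(fit, ds$features) == ds$labels)
  # enumeration of hyperplane sign patterns: no linear rule exceeds 3/4
  expect_lte(train_acc, 0.75)
})

test_that("accuracy is at chance when both classes share one distribution", {
  factory <- function(seed) {
    set.seed(seed)
    suppressMessages(assemble_dataset(rnorm(3300, 50, 10),
                                      rnorm(3300, 50, 10), seed = seed))
  }
  for (kind in c("linear_svm", "mlp")) {
    ev <- repeat_eval(factory, kind = kind, n_repeats = 20, base_seed = 73)
    expect_gte(ev$mean, 0.45)
    expect_lte(ev$mean, 0.55)
  }
})

test_that("permuting training labels collapses accuracy to chance", {
  accs <- vapply(1:10, function(s) {
    parts <- norm_split(make_cloud_dataset(7400 + s, gap = 10, n_rows = 100),
                        seed = s)
    set.seed(s)
    parts$train$labels <- sample(parts$train$labels)
    fit <- train_indicator(parts$train, "linear_svm", seed = s)
    evaluate_indicator(fit, parts$test)
  }, numeric(1))
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})

test_that("the learned SVM beats random hyperplanes on its own objective", {
  parts <- norm_split(make_cloud_dataset(75, gap = 2, n_rows = 50, dim = 5))
  C <- 4
  fit <- train_indicator(parts$train, "linear_svm", config = list(C = C))
  obj <- function(w, b) {
    marg <- (2 * parts$train$labels - 1) *
      (drop(parts$train$features %*% w) + b)
    sum(w^2) + C * sum(pmax(0, 1 - marg))
  }
  learned <- obj(fit$w, fit$b)
  set.seed(76)
  scale <- sqrt(sum(fit$w^2))
  rand_objs <- vapply(1:10000, function(i) {
    w <- rnorm(5, 0, scale)
    b <- rnorm(1, 0, max(scale, 1))
    obj(w, b)
  }, numeric(1))
  # small tolerance for the quadratic-programming stopping rule
  expect_lte(learned, min(rand_objs) * (1 + 1e-6) + 1e-8)
})

test_that("repeated evaluation reports consistent spread and validates inputs", {
  sep_factory <- function(seed) make_cloud_dataset(77, gap = 10,
                                                   n_rows = 100)
  ev <- repeat_eval(sep_factory, "linear_svm", n_repeats = 3, base_seed = 5)
  expect_s3_class(ev, "eval_result")
  expect_length(ev$accuracies, 3L)
  expect_equal(ev$mean, mean(ev$accuracies))
  expect_equal(ev$spread, sd(ev$accuracies))
  # fully separable deterministic data: every repeat is perfect
  expect_identical(ev$accuracies, rep(1, 3))
  expect_identical(ev$spread, 0)
  expect_error(repeat_eval(sep_factory, "linear_svm", n_repeats = 1),
               ">= 2")
  parts <- norm_split(make_cloud_dataset(78))
  fit <- train_indicator(parts$train, "linear_svm")
  empty <- parts$test
  empty$features <- empty$features[0, , drop = FALSE]
  empty$labels <- integer(0)
  expect_error(evaluate_indicator(fit, empty), "empty")
})
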