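# helper: single-feature model with d = 1 whose eval-mode logits are
# (-x, x) for input x (identity normalization, gamma = 1, beta = 0)
sign_model <- function() {
  m <- classifier_model(c(erp = 1L), seed = 1)
  m$features$erp$W <- matrix(c(-1, 1), 1, 2)
  m$features$erp$b <- c(0, 0)
  m
}

test_that("forward pass matches softmax closed forms", {
  m <- classifier_model(c(erp = 3L), seed = 2)
  m$features$erp$W[] <- 0
  X <- list(erp = matrix(rnorm(12), 4, 3))
  # zero weights, identity normalization -> (0.5, 0.5)
  p <- model_forward(m, X)$probs
  expect_equal(p, matrix(0.5, 4, 2), tolerance = 1e-12)
  # equal logits (z, z) -> (0.5, 0.5) by shift invariance
  m$features$erp$b <- c(3.7, 3.7)
  expect_equal(model_forward(m, X)$probs[1, ], c(0.5, 0.5), tolerance = 1e-9)
  # logits (0, ln 3) -> (0.25, 0.75)
  m$features$erp$b <- c(0, log(3))
  expect_equal(model_forward(m, X)$probs[1, ], c(0.25, 0.75),
               tolerance = 1e-4)
  # dimension mismatch names the offending feature
  expect_error(model_forward(m, list(erp = matrix(0, 2, 5))),
               "feature 'erp'")
})

test_that("analytic gradients match central finite differences", {
  set.seed(2)
  dims <- c(erp = 5L, tf_power = 7L, phase_sync = 3L)
  model <- classifier_model(dims, seed = 3, fusion_init = "random")
  X <- lapply(dims, function(d) matrix(rnorm(4 * d), 4, d))
  y <- c(0L, 1L, 1L, 0L)
  g <- model_gradients(model, X, y, training = TRUE)
  num_grad <- function(get, set) {
    p <- get(model)
    gn <- p
    for (i in seq_along(p)) {
      h <- 1e-5 * max(1, abs(p[i]))
      up <- p; up[i] <- p[i] + h
      dn <- p; dn[i] <- p[i] - h
      gn[i] <- (model_loss(set(model, up), X, y, TRUE) -
                model_loss(set(model, dn), X, y, TRUE)) / (2 * h)
    }
    gn
  }
  worst <- 0
  for (kind in names(dims)) for (par in c("W", "b", "gamma", "beta")) {
    gn <- num_grad(function(m) m$features[[kind]][[par]],
                   function(m, v) { m$features[[kind]][[par]][] <- v; m })
    ga <- g$features[[kind]][[par]]
    worst <- max(worst, max(abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-6)))
  }
  for (par in c("W", "b")) {
    gn <- num_grad(function(m) m$fusion[[par]],
                   function(m, v) { m$fusion[[par]][] <- v; m })
    ga <- g$fusion[[par]]
    worst <- max(worst, max(abs(ga - gn) / pmax(abs(ga) + abs(gn), 1e-6)))
  }
  expect_lt(worst, 1e-4)
})

test_that("batch normalization standardizes the training-mode logits", {
  set.seed(4)
  m <- classifier_model(c(erp = 6L), seed = 5)  # gamma = 1, beta = 0
  X <- list(erp = matrix(rnorm(50 * 6, sd = 4), 50, 6))
  logits <- model_forward(m, X, training = TRUE)$logits
  expect_lt(max(abs(colMeans(logits))), 1e-10)
  expect_equal(colMeans(logits^2), c(1, 1), tolerance = 1e-4)
})

test_that("SGD converges on separable data and stays at chance on noise", {
  set.seed(4)
  n <- 100
  Xs <- list(erp = rbind(matrix(rnorm(n / 2 * 10), n / 2),
                         matrix(rnorm(n / 2 * 10, mean = 6), n / 2)))
  ys <- rep(c(0L, 1L), each = n / 2)
  fit <- train_model(classifier_model(c(erp = 10L), seed = 5), Xs, ys,
                     training_config(n_epochs = 200, seed = 6))
  expect_equal(accuracy(fit$model, Xs, ys), 1.0)
  expect_lt(fit$loss[200], fit$loss[1])

  set.seed(7)
  Xtr <- list(erp = matrix(rnorm(200 * 10), 200))
  ytr <- sample(0:1, 200, TRUE)
  Xte <- list(erp = matrix(rnorm(200 * 10), 200))
  yte <- sample(0:1, 200, TRUE)
  fit2 <- train_model(classifier_model(c(erp = 10L), seed = 8), Xtr, ytr,
                      training_config(n_epochs = 100, seed = 9))
  # 3 binomial sd around chance at n = 200
  expect_lt(abs(accuracy(fit2$model, Xte, yte) - 0.5), 3 * 0.5 / sqrt(200))
})

test_that("training is deterministic and records per-epoch validation accuracy", {
  set.seed(11)
  X <- list(erp = matrix(rnorm(40 * 4), 40, 4))
  y <- rep(0:1, 20)
  cfg <- training_config(n_epochs = 5, batch_size = 8, seed = 3)
  f1 <- train_model(classifier_model(c(erp = 4L), seed = 2), X, y, cfg, X, y)
  f2 <- train_model(classifier_model(c(erp = 4L), seed = 2), X, y, cfg, X, y)
  expect_identical(f1$model, f2$model)
  expect_identical(f1$val_accuracy, f2$val_accuracy)
  expect_length(f1$val_accuracy, 5)
  # oversized batch falls back to one full batch with a warning
  expect_warning(
    train_model(classifier_model(c(erp = 4L), seed = 2), X, y,
                training_config(n_epochs = 1, batch_size = 100, seed = 3)),
    "full batch")
})

test_that("transfer initialization copies blocks exactly and averages logits", {
  set.seed(12)
  dims <- c(erp = 4L, tf_power = 6L)
  X <- lapply(dims, function(d) matrix(rnorm(30 * d), 30, d))
  y <- rep(0:1, 15)
  singles <- lapply(names(dims), function(k) {
    suppressWarnings(train_model(
      classifier_model(dims[k], seed = match(k, names(dims))),
      X[k], y, training_config(n_epochs = 10, seed = 5))$model)
  })
  comp <- transfer_init(singles)
  for (i in seq_along(dims))
    expect_identical(comp$features[[names(dims)[i]]],
                     singles[[i]]$features[[1]])
  # averaging fusion: composite logits = mean of single-model logits
  lc <- model_forward(comp, X)$logits
  l1 <- model_forward(singles[[1]], X[1])$logits
  l2 <- model_forward(singles[[2]], X[2])$logits
  expect_equal(lc, (l1 + l2) / 2, tolerance = 1e-12)
  expect_error(transfer_init(list(comp)), "single-feature")
})

test_that("an untrained transfer composite is at least at chance on learnable data", {
  set.seed(13)
  n <- 80
  mk <- function(d, sep) rbind(matrix(rnorm(n / 2 * d), n / 2),
                               matrix(rnorm(n / 2 * d, mean = sep), n / 2))
  X <- list(erp = mk(5, 3), tf_power = mk(5, 0))  # signal only in erp
  y <- rep(c(0L, 1L), each = n / 2)
  singles <- lapply(c("erp", "tf_power"), function(k)
    suppressWarnings(train_model(
      classifier_model(setNames(5L, k), seed = 3), X[k], y,
      training_config(n_epochs = 100, seed = 4))$model))
  comp <- transfer_init(singles)
  expect_gte(accuracy(comp, X, y), 0.5)
})

test_that("accuracy is the fraction correct with ties to 'frequent'", {
  m <- sign_model()
  x <- c(rep(1, 50), rep(-1, 37), rep(1, 13))   # 13 rare misclassified
  y <- c(rep(1L, 50), rep(0L, 50))
  expect_equal(accuracy(m, list(erp = matrix(x)), y), 0.87)
  expect_equal(accuracy(m, list(erp = matrix(c(1, -1))), c(1L, 0L)), 1.0)
  # exact tie (x = 0) predicts class 0
  expect_equal(accuracy(m, list(erp = matrix(0)), 0L), 1.0)
  expect_equal(accuracy(m, list(erp = matrix(0)), 1L), 0.0)
  expect_error(accuracy(m, list(erp = matrix(0, 0, 1)), integer(0)), "empty")
})

test_that("checkpoints round-trip through HDF5", {
  set.seed(14)
  dims <- c(erp = 3L, phase_sync = 4L)
  X <- lapply(dims, function(d) matrix(rnorm(20 * d), 20, d))
  y <- rep(0:1, 10)
  fit <- suppressWarnings(train_model(
    classifier_model(dims, seed = 1), X, y,
    training_config(n_epochs = 3, seed = 2)))
  path <- withr::local_tempfile(fileext = ".h5")
  write_checkpoint(fit$model, path)
  back <- read_checkpoint(path)
  expect_equal(back$features, fit$model$features, tolerance = 1e-15)
  expect_equal(back$fusion, fit$model$fusion, tolerance = 1e-15)
  expect_equal(model_forward(back, X)$probs,
               model_forward(fit$model, X)$probs, tolerance = 1e-12)
})
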