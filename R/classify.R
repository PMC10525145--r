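#' Map condition labels to class indices
#'
#' Fixed convention: `frequent` = 0, `rare` = 1.
#'
#' @param labels character vector of `"rare"` / `"frequent"`.
#' @return integer vector of 0/1.
#' @export
label_index <- function(labels) {
  if (!all(labels %in% c("rare", "frequent")))
    stop("labels must be 'rare' or 'frequent'")
  as.integer(labels == "rare")
}

#' Perceptron classifier over one or more feature families
#'
#' Architecture: each feature kind gets its own vectorization + linear map to
#' 2 logits + per-logit batch normalization (batch statistics during
#' training, running statistics at evaluation, learned scale/shift). A
#' single-feature model feeds the normalized logits straight to softmax; a
#' composite model concatenates the normalized logits of its k features and
#' applies one fusion linear map before softmax. The normalization makes the
#' per-feature logit scales commensurate so that fusion starts from a level
#' playing field.
#'
#' @param feature_dims named integer vector: flattened input dimension per
#'   feature kind; names define the feature order (k = length, 1 to 3).
#' @param seed seed for the weight initialization (uniform in
#'   `+/- 1/sqrt(d)` per feature block).
#' @param fusion_init for k > 1: `"average"` starts the fusion map as the
#'   mean of the per-feature logit pairs (bias 0); `"random"` uses small
#'   uniform weights.
#' @param bn_eps,bn_momentum batch-norm variance epsilon and
#'   running-statistics update momentum.
#' @return object of class `classifier_model`.
#' @export
classifier_model <- function(feature_dims, seed = 1,
                             fusion_init = c("average", "random"),
                             bn_eps = 1e-5, bn_momentum = 0.1) {
  fusion_init <- match.arg(fusion_init)
  k <- length(feature_dims)
  stopifnot(k >= 1, k <= 3, !is.null(names(feature_dims)))
  set.seed(seed)
  features <- lapply(feature_dims, function(d) {
    lim <- 1 / sqrt(d)
    list(d = as.integer(d),
         W = matrix(stats::runif(d * 2, -lim, lim), d, 2),
         b = c(0, 0), gamma = c(1, 1), beta = c(0, 0),
         run_mean = c(0, 0), run_var = c(1, 1))
  })
  names(features) <- names(feature_dims)
  fusion <- NULL
  if (k > 1) {
    if (fusion_init == "average") {
      W <- matrix(0, 2 * k, 2)
      for (i in seq_len(k)) for (j in 1:2) W[2 * (i - 1) + j, j] <- 1 / k
    } else {
      W <- matrix(stats::runif(4 * k, -0.1, 0.1), 2 * k, 2)
    }
    fusion <- list(W = W, b = c(0, 0))
  }
  structure(list(kinds = names(feature_dims), features = features,
                 fusion = fusion, bn_eps = bn_eps, bn_momentum = bn_momentum),
            class = "classifier_model")
}

#' @export
print.classifier_model <- function(x, ...) {
  cat(sprintf("<classifier_model k=%d [%s]%s>\n", length(x$kinds),
              paste(x$kinds, collapse = " + "),
              if (is.null(x$fusion)) "" else " with fusion"))
  invisible(x)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

check_inputs <- function(model, X) {
  for (kind in model$kinds) {
    if (is.null(X[[kind]]))
      stop("missing feature matrix for kind '", kind, "'")
    if (ncol(X[[kind]]) != model$features[[kind]]$d)
      stop(sprintf("dimension mismatch for feature '%s': got %d, model expects %d",
                   kind, ncol(X[[kind]]), model$features[[kind]]$d))
  }
}

#' Forward pass
#'
#' @param model a [classifier_model()].
#' @param X named list of feature matrices (samples x flattened dims), one
#'   per feature kind of the model.
#' @param training use batch statistics for the logit normalization (TRUE)
#'   or the stored running statistics (FALSE).
#' @return list with `probs` (n x 2 softmax probabilities, columns =
#'   frequent/rare), `logits` (n x 2 pre-softmax), and an internal `cache`
#'   used by the backward pass.
#' @export
model_forward <- function(model, X, training = FALSE) {
  check_inputs(model, X)
  caches <- list()
  outs <- list()
  for (kind in model$kinds) {
    f <- model$features[[kind]]
    Z <- X[[kind]] %*% f$W
    Z <- sweep(Z, 2, f$b, "+")
    if (training) {
      mu <- colMeans(Z)
      v <- colMeans(Z^2) - mu^2
    } else {
      mu <- f$run_mean
      v <- f$run_var
    }
    istd <- 1 / sqrt(v + model$bn_eps)
    xc <- sweep(Z, 2, mu)
    zhat <- sweep(xc, 2, istd, "*")
    out <- sweep(sweep(zhat, 2, f$gamma, "*"), 2, f$beta, "+")
    caches[[kind]] <- list(Z = Z, mu = mu, v = v, istd = istd, xc = xc,
                           zhat = zhat)
    outs[[kind]] <- out
  }
  if (is.null(model$fusion)) {
    logits <- outs[[1]]
    H <- NULL
  } else {
    H <- do.call(cbind, outs[model$kinds])
    logits <- sweep(H %*% model$fusion$W, 2, model$fusion$b, "+")
  }
  list(probs = softmax_rows(logits), logits = logits,
       cache = list(per_kind = caches, H = H, training = training))
}

#' Mean cross-entropy loss
#'
#' `L = -(1/n) * sum log q(y_i)` between the softmax probabilities `q` and
#' the one-hot true labels.
#'
#' @inheritParams model_forward
#' @param y integer class labels (0 = frequent, 1 = rare).
#' @return scalar loss.
#' @export
model_loss <- function(model, X, y, training = FALSE) {
  fwd <- model_forward(model, X, training = training)
  n <- nrow(fwd$probs)
  -mean(log(fwd$probs[cbind(seq_len(n), y + 1L)]))
}

#' Analytic gradients of the mean cross-entropy loss
#'
#' Backpropagates through softmax, the fusion map (if any), and the batch
#' normalization (full batch-statistics backward in training mode).
#'
#' @inheritParams model_loss
#' @param fwd optional precomputed [model_forward()] result.
#' @return list mirroring the parameter structure: per-kind `W`, `b`,
#'   `gamma`, `beta`, and `fusion$W`, `fusion$b` for composites; plus the
#'   batch `mu`/`v` per kind (for running-statistics updates).
#' @export
model_gradients <- function(model, X, y, training = TRUE, fwd = NULL) {
  if (is.null(fwd)) fwd <- model_forward(model, X, training = training)
  n <- nrow(fwd$probs)
  onehot <- matrix(0, n, 2)
  onehot[cbind(seq_len(n), y + 1L)] <- 1
  dlogits <- (fwd$probs - onehot) / n
  grads <- list(features = list(), fusion = NULL)
  if (is.null(model$fusion)) {
    douts <- list(dlogits)
    names(douts) <- model$kinds
  } else {
    H <- fwd$cache$H
    grads$fusion <- list(W = crossprod(H, dlogits), b = colSums(dlogits))
    dH <- dlogits %*% t(model$fusion$W)
    douts <- list()
    for (i in seq_along(model$kinds))
      douts[[model$kinds[i]]] <- dH[, (2 * i - 1):(2 * i), drop = FALSE]
  }
  for (kind in model$kinds) {
    f <- model$features[[kind]]
    cc <- fwd$cache$per_kind[[kind]]
    dout <- douts[[kind]]
    dgamma <- colSums(dout * cc$zhat)
    dbeta <- colSums(dout)
    dzhat <- sweep(dout, 2, f$gamma, "*")
    if (fwd$cache$training) {
      dvar <- colSums(dzhat * cc$xc) * (-0.5) * cc$istd^3
      dmu <- -cc$istd * colSums(dzhat) - 2 * dvar * colMeans(cc$xc)
      dZ <- sweep(dzhat, 2, cc$istd, "*") +
        sweep(cc$xc, 2, 2 * dvar / n, "*") +
        matrix(dmu / n, n, 2, byrow = TRUE)
    } else {
      dZ <- sweep(dzhat, 2, cc$istd, "*")
    }
    grads$features[[kind]] <- list(
      W = crossprod(X[[kind]], dZ), b = colSums(dZ),
      gamma = dgamma, beta = dbeta, batch_mu = cc$mu, batch_v = cc$v)
  }
  grads
}

zero_velocity <- function(model) {
  v <- list(features = lapply(model$features, function(f)
    list(W = f$W * 0, b = c(0, 0), gamma = c(0, 0), beta = c(0, 0))))
  if (!is.null(model$fusion))
    v$fusion <- list(W = model$fusion$W * 0, b = c(0, 0))
  v
}

#' Training configuration
#'
#' Defaults follow the standard protocol for trial-average samples: SGD with
#' learning rate 1e-4, momentum 0.9, batch size 50, 200 epochs,
#' cross-entropy loss.
#'
#' @param learning_rate SGD step size (> 0).
#' @param momentum SGD momentum in `[0, 1]`.
#' @param batch_size mini-batch size (>= 1).
#' @param n_epochs training epochs.
#' @param seed seed controlling the per-epoch shuffles.
#' @return object of class `training_config`.
#' @export
training_config <- function(learning_rate = 1e-4, momentum = 0.9,
                            batch_size = 50, n_epochs = 200, seed = 1) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum <= 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed)),
            class = "training_config")
}

#' Train a classifier by mini-batch SGD with momentum
#'
#' Cross-entropy loss; the sample order is reshuffled every epoch from
#' `cfg$seed`; batch normalization uses batch statistics during training and
#' updates running statistics for evaluation. If `eval_X`/`eval_y` are given,
#' held-out accuracy is recorded after every epoch (evaluation-mode
#' normalization).
#'
#' @param model a [classifier_model()].
#' @param X named list of training feature matrices.
#' @param y integer labels (0 = frequent, 1 = rare).
#' @param cfg a [training_config()].
#' @param eval_X,eval_y optional held-out set for per-epoch validation.
#' @return list with the trained `model`, per-epoch mean training `loss`,
#'   and per-epoch `val_accuracy` (NULL if no eval set).
#' @export
train_model <- function(model, X, y, cfg = training_config(),
                        eval_X = NULL, eval_y = NULL) {
  check_inputs(model, X)
  n <- nrow(X[[1]])
  batch_size <- cfg$batch_size
  if (batch_size > n) {
    warning(sprintf("batch_size %d > %d samples; using one full batch",
                    batch_size, n))
    batch_size <- n
  }
  set.seed(cfg$seed)
  vel <- zero_velocity(model)
  lr <- cfg$learning_rate
  mom <- cfg$momentum
  bn_m <- model$bn_momentum
  losses <- numeric(cfg$n_epochs)
  val_acc <- if (is.null(eval_X)) NULL else numeric(cfg$n_epochs)
  for (epoch in seq_len(cfg$n_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1, n, by = batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      idx <- perm[starts[bi]:min(starts[bi] + batch_size - 1L, n)]
      Xb <- lapply(X[model$kinds], function(m) m[idx, , drop = FALSE])
      yb <- y[idx]
      fwd <- model_forward(model, Xb, training = TRUE)
      batch_losses[bi] <-
        -mean(log(fwd$probs[cbind(seq_along(idx), yb + 1L)]))
      g <- model_gradients(model, Xb, yb, fwd = fwd)
      for (kind in model$kinds) {
        f <- model$features[[kind]]
        gf <- g$features[[kind]]
        for (p in c("W", "b", "gamma", "beta")) {
          vel$features[[kind]][[p]] <- mom * vel$features[[kind]][[p]] + gf[[p]]
          f[[p]] <- f[[p]] - lr * vel$features[[kind]][[p]]
        }
        f$run_mean <- (1 - bn_m) * f$run_mean + bn_m * gf$batch_mu
        f$run_var <- (1 - bn_m) * f$run_var + bn_m * gf$batch_v
        model$features[[kind]] <- f
      }
      if (!is.null(model$fusion)) {
        for (p in c("W", "b")) {
          vel$fusion[[p]] <- mom * vel$fusion[[p]] + g$fusion[[p]]
          model$fusion[[p]] <- model$fusion[[p]] - lr * vel$fusion[[p]]
        }
      }
    }
    losses[epoch] <- mean(batch_losses)
    if (!is.null(eval_X))
      val_acc[epoch] <- accuracy(model, eval_X, eval_y)
  }
  list(model = model, loss = losses, val_accuracy = val_acc)
}

#' Build a composite model from trained single-feature models
#'
#' Each single model's linear map and normalization state (weights, bias,
#' scale/shift, running statistics) is copied bit-exactly into the
#' corresponding block of the composite; only the fusion map is freshly
#' initialized (by default as the average of the per-feature logit pairs, so
#' the untrained composite starts at the ensemble of its parts).
#'
#' @param single_models list of trained k = 1 [classifier_model()]s with
#'   distinct feature kinds.
#' @param fusion_init `"average"` or `"random"`.
#' @param seed seed for `fusion_init = "random"`.
#' @return a composite [classifier_model()].
#' @export
transfer_init <- function(single_models, fusion_init = c("average", "random"),
                          seed = 1) {
  fusion_init <- match.arg(fusion_init)
  kinds <- vapply(single_models, function(m) {
    if (length(m$kinds) != 1) stop("transfer_init needs single-feature models")
    m$kinds
  }, "")
  if (anyDuplicated(kinds)) stop("duplicate feature kinds in single models")
  dims <- vapply(single_models, function(m) m$features[[1]]$d, 1L)
  names(dims) <- kinds
  comp <- classifier_model(dims, seed = seed, fusion_init = fusion_init,
                           bn_eps = single_models[[1]]$bn_eps,
                           bn_momentum = single_models[[1]]$bn_momentum)
  for (i in seq_along(kinds))
    comp$features[[kinds[i]]] <- single_models[[i]]$features[[1]]
  comp
}

#' Classification accuracy on a labelled set
#'
#' Predicted class = argmax of the evaluation-mode softmax probabilities;
#' exact ties go to class 0 (frequent).
#'
#' @inheritParams model_loss
#' @return fraction of correctly classified samples, `n_c / n_all`.
#' @export
accuracy <- function(model, X, y) {
  if (length(y) == 0) stop("empty evaluation set")
  probs <- model_forward(model, X, training = FALSE)$probs
  pred <- as.integer(probs[, 2] > probs[, 1])
  mean(pred == y)
}

#' Save / load classifier checkpoints (HDF5)
#'
#' Weights, biases and normalization state per feature block plus the fusion
#' map under `/model/...`, with a JSON attribute carrying dims and kinds.
#'
#' @param model a [classifier_model()].
#' @param path HDF5 file path.
#' @return `path` invisibly; `read_checkpoint()` returns the model.
#' @export
write_checkpoint <- function(model, path) {
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "model")
  for (kind in model$kinds) {
    g <- paste0("model/feature_", kind)
    rhdf5::h5createGroup(path, g)
    f <- model$features[[kind]]
    for (p in c("W", "b", "gamma", "beta", "run_mean", "run_var"))
      rhdf5::h5write(f[[p]], path, paste0(g, "/", p))
  }
  if (!is.null(model$fusion)) {
    rhdf5::h5createGroup(path, "model/fusion")
    rhdf5::h5write(model$fusion$W, path, "model/fusion/W")
    rhdf5::h5write(model$fusion$b, path, "model/fusion/b")
  }
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  meta <- jsonlite::toJSON(list(
    kinds = model$kinds,
    dims = vapply(model$features, `[[`, 1L, "d"),
    bn_eps = model$bn_eps, bn_momentum = model$bn_momentum),
    auto_unbox = TRUE)
  rhdf5::h5writeAttribute(as.character(meta), fid, "meta")
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  meta <- jsonlite::fromJSON(
    as.character(rhdf5::h5readAttributes(path, "/")$meta))
  dims <- as.integer(meta$dims)
  names(dims) <- meta$kinds
  model <- classifier_model(dims, bn_eps = meta$bn_eps,
                            bn_momentum = meta$bn_momentum)
  for (kind in meta$kinds) {
    g <- paste0("model/feature_", kind)
    f <- model$features[[kind]]
    f$W <- matrix(rhdf5::h5read(path, paste0(g, "/W")), f$d, 2)
    for (p in c("b", "gamma", "beta", "run_mean", "run_var"))
      f[[p]] <- as.numeric(rhdf5::h5read(path, paste0(g, "/", p)))
    model$features[[kind]] <- f
  }
  if (!is.null(model$fusion)) {
    model$fusion$W <- matrix(rhdf5::h5read(path, "model/fusion/W"),
                             2 * length(meta$kinds), 2)
    model$fusion$b <- as.numeric(rhdf5::h5read(path, "model/fusion/b"))
  }
  model
}
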