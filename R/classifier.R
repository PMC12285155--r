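#' Configure the cell-type MLP classifier
#'
#' Two hidden layers (default 800 each), each followed by batch
#' normalization and ReLU, a linear output layer over all cell types,
#' cross-entropy loss, Adam.
#'
#' @param hidden_dims hidden widths (default `c(800, 800)`).
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 64).
#' @param learning_rate Adam learning rate.
#' @param seed initialization/minibatch seed.
#' @return An `mlp_config` object.
#' @export
mlp_config <- function(hidden_dims = c(800, 800), epochs = 50,
                       batch_size = 64, learning_rate = 0.001, seed = 1L) {
  structure(list(hidden_dims = as.integer(hidden_dims),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "mlp_config")
}

#' Z-score features on training statistics
#'
#' Columns are centered and scaled with the *training* fold's mean and
#' SD; the same statistics are applied to the test fold so no test
#' information leaks into the normalization. Zero-variance features map
#' to 0 with a warning.
#'
#' @param train training-fold matrix.
#' @param test optional test-fold matrix, normalized with train stats.
#' @return `list(train, test, center, scale)` (`test` NULL if absent).
#' @export
zscore_features <- function(train, test = NULL) {
  if (nrow(train) < 2) stop_fsb("need >= 2 rows to estimate scale", "fsb_invalid")
  ctr <- colMeans(train)
  scl <- apply(train, 2, stats::sd)
  if (any(scl == 0)) {
    warning(sprintf("%d zero-variance feature(s) set to 0", sum(scl == 0)))
    scl[scl == 0] <- Inf  # (x - mean)/Inf -> 0
  }
  norm <- function(m) sweep(sweep(m, 2, ctr, "-"), 2, scl, "/")
  list(train = norm(train), test = if (!is.null(test)) norm(test),
       center = ctr, scale = scl)
}

mlp_init <- function(input_dim, hidden_dims, n_classes, seed) {
  dims <- c(input_dim, hidden_dims, n_classes)
  with_seed(seed, {
    layers <- list()
    for (i in seq_len(length(dims) - 1)) {
      lim <- sqrt(6 / (dims[i] + dims[i + 1]))
      layers[[i]] <- list(
        W = matrix(stats::runif(dims[i] * dims[i + 1], -lim, lim),
                   nrow = dims[i]),
        b = numeric(dims[i + 1]),
        # batchnorm parameters/statistics on all but the output layer
        gamma = if (i < length(dims) - 1) rep(1, dims[i + 1]),
        beta = if (i < length(dims) - 1) numeric(dims[i + 1]),
        run_mean = if (i < length(dims) - 1) numeric(dims[i + 1]),
        run_var = if (i < length(dims) - 1) rep(1, dims[i + 1]))
    }
    layers
  })
}

mlp_forward <- function(layers, X, training = FALSE, momentum = 0.1,
                        eps = 1e-5) {
  nl <- length(layers)
  cache <- vector("list", nl)
  h <- X
  for (i in seq_len(nl)) {
    L <- layers[[i]]
    a <- sweep(h %*% L$W, 2, L$b, "+")
    if (i < nl) {
      if (training) {
        mu <- colMeans(a)
        v <- colMeans(sweep(a, 2, mu, "-")^2)
        layers[[i]]$run_mean <- (1 - momentum) * L$run_mean + momentum * mu
        layers[[i]]$run_var <- (1 - momentum) * L$run_var + momentum * v
      } else {
        mu <- L$run_mean
        v <- L$run_var
      }
      xc <- sweep(a, 2, mu, "-")
      inv_sd <- 1 / sqrt(v + eps)
      xhat <- sweep(xc, 2, inv_sd, "*")
      y <- sweep(sweep(xhat, 2, L$gamma, "*"), 2, L$beta, "+")
      r <- relu(y)
      cache[[i]] <- list(h = h, a = a, xc = xc, inv_sd = inv_sd,
                         xhat = xhat, y = y)
      h <- r
    } else {
      cache[[i]] <- list(h = h)
      h <- a
    }
  }
  list(logits = h, cache = cache, layers = layers)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

mlp_backward <- function(layers, fw, y_onehot) {
  nl <- length(layers)
  m <- nrow(y_onehot)
  probs <- softmax_rows(fw$logits)
  d <- (probs - y_onehot) / m
  grads <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    L <- layers[[i]]
    cc <- fw$cache[[i]]
    if (i < nl) {
      d <- d * (cc$y > 0)  # back through ReLU
      # back through batchnorm
      dgamma <- colSums(d * cc$xhat)
      dbeta <- colSums(d)
      dxhat <- sweep(d, 2, L$gamma, "*")
      mb <- nrow(d)
      dx <- sweep(
        mb * dxhat - matrix(rep(colSums(dxhat), each = mb), nrow = mb) -
          cc$xhat * matrix(rep(colSums(dxhat * cc$xhat), each = mb), nrow = mb),
        2, cc$inv_sd / mb, "*")
      d <- dx
      grads[[i]] <- list(W = crossprod(cc$h, d), b = colSums(d),
                         gamma = dgamma, beta = dbeta)
    } else {
      grads[[i]] <- list(W = crossprod(cc$h, d), b = colSums(d))
    }
    d <- d %*% t(L$W)
  }
  grads
}

#' Train the MLP cell-type classifier
#'
#' @param X feature matrix (z-scored latent representations).
#' @param y factor of cell-type labels; its level set defines the output
#'   layer, so pass a factor carrying *all* classes even if some are
#'   absent from this training fold.
#' @param config an [mlp_config()].
#' @return An `mlp_model` (layers + class levels + config).
#' @export
mlp_train <- function(X, y, config = mlp_config()) {
  y <- as.factor(y)
  classes <- levels(y)
  layers <- mlp_init(ncol(X), config$hidden_dims, length(classes), config$seed)
  n <- nrow(X)
  onehot <- diag(length(classes))[as.integer(y), , drop = FALSE]
  state <- list(t = 0L, m = NULL, v = NULL)
  for (e in seq_len(config$epochs)) {
    layers <- with_seed(mix_seed(config$seed, e), {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      for (s in starts) {
        idx <- perm[s:min(s + config$batch_size - 1, n)]
        if (length(idx) < 2) next  # batchnorm needs > 1 row
        fw <- mlp_forward(layers, X[idx, , drop = FALSE], training = TRUE)
        layers <- fw$layers  # running stats updated
        grads <- mlp_backward(layers, fw, onehot[idx, , drop = FALSE])
        state$t <- state$t + 1L
        bc1 <- 1 - 0.9^state$t; bc2 <- 1 - 0.999^state$t
        for (i in seq_along(layers)) for (nm in names(grads[[i]])) {
          g <- grads[[i]][[nm]]
          key <- paste0(i, ".", nm)
          if (is.null(state$m[[key]])) { state$m[[key]] <- g * 0; state$v[[key]] <- g * 0 }
          state$m[[key]] <- 0.9 * state$m[[key]] + 0.1 * g
          state$v[[key]] <- 0.999 * state$v[[key]] + 0.001 * g^2
          layers[[i]][[nm]] <- layers[[i]][[nm]] -
            config$learning_rate * (state$m[[key]] / bc1) /
            (sqrt(state$v[[key]] / bc2) + 1e-8)
        }
      }
      layers
    })
  }
  structure(list(layers = layers, classes = classes, config = config),
            class = "mlp_model")
}

#' Predict cell types with a trained MLP
#'
#' @param model an `mlp_model`.
#' @param X feature matrix (normalized with the training statistics).
#' @return Factor of predicted labels over the model's class set.
#' @export
mlp_predict <- function(model, X) {
  fw <- mlp_forward(model$layers, as.matrix(X), training = FALSE)
  factor(model$classes[max.col(fw$logits, ties.method = "first")],
         levels = model$classes)
}

#' Leave-one-batch-out cell-type classification
#'
#' Each batch is left out in turn: the MLP is trained on the remaining
#' batches (features z-scored on the training fold only) and scored on
#' the left-out batch. Cells of types absent from the training fold are
#' necessarily misclassified and stay in the denominator.
#'
#' @param latents cells x features matrix (corrected latent
#'   representations).
#' @param type_labels,batch_labels per-cell labels.
#' @param config an [mlp_config()].
#' @return `list(folds, mean_accuracy, var_accuracy)`; `folds` is a
#'   data.frame (left_out_batch, n_test, n_unseen_type, accuracy).
#' @export
lobo_cv <- function(latents, type_labels, batch_labels,
                    config = mlp_config()) {
  latents <- as.matrix(latents)
  type_labels <- as.factor(type_labels)
  batch_labels <- droplevels(as.factor(batch_labels))
  if (nlevels(batch_labels) < 2) stop_fsb("need >= 2 batches", "fsb_invalid")
  folds <- lapply(levels(batch_labels), function(b) {
    test_idx <- which(batch_labels == b)
    train_idx <- which(batch_labels != b)
    if (length(unique(type_labels[train_idx])) < 2) {
      stop_fsb(sprintf("training fold for batch '%s' has < 2 cell types", b),
               "fsb_invalid")
    }
    zs <- zscore_features(latents[train_idx, , drop = FALSE],
                          latents[test_idx, , drop = FALSE])
    model <- mlp_train(zs$train, type_labels[train_idx], config)
    pred <- mlp_predict(model, zs$test)
    truth <- type_labels[test_idx]
    unseen <- !(as.character(truth) %in%
                  as.character(unique(type_labels[train_idx])))
    data.frame(left_out_batch = b, n_test = length(test_idx),
               n_unseen_type = sum(unseen),
               accuracy = mean(as.character(pred) == as.character(truth)))
  })
  folds <- do.call(rbind, folds)
  list(folds = folds, mean_accuracy = mean(folds$accuracy),
       var_accuracy = stats::var(folds$accuracy))
}
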