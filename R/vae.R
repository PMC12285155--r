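#' Configure the variational autoencoder
#'
#' A fully connected VAE: encoder `input_dim -> hidden_dims -> latent_dim`
#' (mean and log-variance heads), decoder mirroring the encoder in
#' reverse with a linear output layer. Hidden layers use ReLU and, in
#' training mode only, inverted dropout. The loss is mean squared
#' reconstruction error plus `kl_weight` times the KL divergence of the
#' variational posterior from the standard normal prior.
#'
#' @param input_dim number of input genes.
#' @param hidden_dims hidden layer widths (default `c(800, 800)`).
#' @param latent_dim latent dimensionality (default 10).
#' @param dropout dropout rate on hidden layers during training (default 0.05).
#' @param kl_weight weight of the KL term in the loss (default 0.005).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param batch_size minibatch size (default 32).
#' @param seed seed controlling parameter initialization.
#' @return A `vae_config` object.
#' @export
vae_config <- function(input_dim, hidden_dims = c(800, 800), latent_dim = 10,
                       dropout = 0.05, kl_weight = 0.005,
                       learning_rate = 0.001, batch_size = 32, seed = 1) {
  if (input_dim < 1 || latent_dim < 1 || any(hidden_dims < 1)) {
    stop_fsb("all dimensions must be >= 1", "fsb_invalid")
  }
  if (dropout < 0 || dropout >= 1) stop_fsb("dropout must be in [0, 1)", "fsb_invalid")
  if (kl_weight < 0) stop_fsb("kl_weight must be >= 0", "fsb_invalid")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 latent_dim = as.integer(latent_dim),
                 dropout = dropout, kl_weight = kl_weight,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "vae_config")
}

# layer dimension plan: named list tensor -> c(in, out) or length for biases
vae_shapes <- function(config) {
  d <- config$input_dim; h <- config$hidden_dims; k <- config$latent_dim
  enc_dims <- c(d, h)
  dec_dims <- c(k, rev(h))
  shapes <- list()
  for (i in seq_along(h)) {
    shapes[[paste0("enc", i, ".W")]] <- c(enc_dims[i], enc_dims[i + 1])
    shapes[[paste0("enc", i, ".b")]] <- enc_dims[i + 1]
  }
  shapes[["mu.W"]] <- c(h[length(h)], k)
  shapes[["mu.b"]] <- k
  shapes[["lv.W"]] <- c(h[length(h)], k)
  shapes[["lv.b"]] <- k
  for (i in seq_along(h)) {
    shapes[[paste0("dec", i, ".W")]] <- c(dec_dims[i], dec_dims[i + 1])
    shapes[[paste0("dec", i, ".b")]] <- dec_dims[i + 1]
  }
  shapes[["out.W"]] <- c(rev(h)[length(h)], d)
  shapes[["out.b"]] <- d
  shapes
}

#' Initialize VAE parameters
#'
#' Glorot-uniform weights, zero biases; bitwise deterministic given
#' `config$seed` so every federated client can start from identical
#' parameters.
#'
#' @param config a [vae_config()].
#' @return A `vae_params` object: a named list of weight matrices and bias
#'   vectors with the config attached as an attribute.
#' @export
init_vae <- function(config) {
  shapes <- vae_shapes(config)
  params <- with_seed(config$seed, {
    lapply(shapes, function(s) {
      if (length(s) == 2) {
        lim <- sqrt(6 / (s[1] + s[2]))
        matrix(stats::runif(s[1] * s[2], -lim, lim), nrow = s[1], ncol = s[2])
      } else {
        numeric(s)
      }
    })
  })
  structure(params, class = "vae_params", config = attr_config(config))
}

attr_config <- function(config) config

#' Flatten VAE parameters to a single numeric vector
#'
#' The flatten/unflatten pair is an exact bijection; it backs parameter
#' digests, secure aggregation, and checkpointing.
#'
#' @param params a `vae_params`.
#' @return Numeric vector.
#' @export
flatten_params <- function(params) {
  unlist(lapply(params, as.numeric), use.names = FALSE)
}

#' Rebuild VAE parameters from a flat vector
#'
#' @param vec numeric vector produced by [flatten_params()].
#' @param config the matching [vae_config()].
#' @return A `vae_params`.
#' @export
unflatten_params <- function(vec, config) {
  shapes <- vae_shapes(config)
  out <- list()
  pos <- 0
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    len <- prod(s)
    vals <- vec[pos + seq_len(len)]
    out[[nm]] <- if (length(s) == 2) matrix(vals, nrow = s[1], ncol = s[2]) else vals
    pos <- pos + len
  }
  if (pos != length(vec)) stop_fsb("flat vector length does not match config", "fsb_invalid")
  structure(out, class = "vae_params", config = config)
}

#' Save / load VAE parameters
#'
#' Checkpoints are RDS archives of the named tensors plus config; the
#' SHA-256 digest of the flattened parameters is stored alongside for
#' audit.
#'
#' @param params a `vae_params`.
#' @param path file path.
#' @return `save_vae` returns the digest invisibly; `load_vae` the params.
#' @export
save_vae <- function(params, path) {
  dig <- tensor_digest(flatten_params(params))
  saveRDS(list(params = unclass(params), config = attr(params, "config"),
               digest = dig), path)
  invisible(dig)
}

#' @rdname save_vae
#' @export
load_vae <- function(path) {
  obj <- readRDS(path)
  p <- structure(obj$params, class = "vae_params", config = obj$config)
  if (!identical(tensor_digest(flatten_params(p)), obj$digest)) {
    stop_fsb("checkpoint digest mismatch", "fsb_invalid")
  }
  p
}

relu <- function(x) (x > 0) * x

# Forward pass. training = TRUE draws dropout masks and the
# reparameterization noise from the current RNG stream and returns the
# cache needed for backprop; training = FALSE is a pure function of
# (params, X) with z = mu.
vae_forward <- function(params, X, config, training = FALSE) {
  p <- config$dropout
  nh <- length(config$hidden_dims)
  cache <- list(h = vector("list", nh), a = vector("list", nh),
                mask = vector("list", nh),
                g = vector("list", nh), ga = vector("list", nh),
                gmask = vector("list", nh))
  h <- X
  for (i in seq_len(nh)) {
    a <- sweep(h %*% params[[paste0("enc", i, ".W")]], 2,
               params[[paste0("enc", i, ".b")]], "+")
    r <- relu(a)
    if (training && p > 0) {
      mask <- matrix((stats::runif(length(r)) >= p) / (1 - p), nrow = nrow(r))
      r <- r * mask
      cache$mask[[i]] <- mask
    }
    cache$a[[i]] <- a
    cache$h[[i]] <- h
    h <- r
  }
  mu <- sweep(h %*% params[["mu.W"]], 2, params[["mu.b"]], "+")
  lv <- sweep(h %*% params[["lv.W"]], 2, params[["lv.b"]], "+")
  cache$henc <- h
  if (training) {
    eps <- matrix(stats::rnorm(length(mu)), nrow = nrow(mu))
    z <- mu + exp(0.5 * lv) * eps
    cache$eps <- eps
  } else {
    z <- mu
  }
  g <- z
  for (i in seq_len(nh)) {
    a <- sweep(g %*% params[[paste0("dec", i, ".W")]], 2,
               params[[paste0("dec", i, ".b")]], "+")
    r <- relu(a)
    if (training && p > 0) {
      mask <- matrix((stats::runif(length(r)) >= p) / (1 - p), nrow = nrow(r))
      r <- r * mask
      cache$gmask[[i]] <- mask
    }
    cache$ga[[i]] <- a
    cache$g[[i]] <- g
    g <- r
  }
  xhat <- sweep(g %*% params[["out.W"]], 2, params[["out.b"]], "+")
  cache$gdec <- g
  list(mu = mu, logvar = lv, z = z, xhat = xhat, cache = cache)
}

#' Encode expression profiles into the latent space
#'
#' Runs the encoder in evaluation mode (dropout off). With
#' `deterministic = TRUE` (the default, and the mode every correction
#' step uses) only the posterior mean is returned, making encoding a pure
#' function of `(params, X)`.
#'
#' @param params trained `vae_params`.
#' @param X cells x genes numeric matrix on the log-transformed layer.
#' @param deterministic return the mean only (TRUE) or both mean and
#'   log-variance (FALSE).
#' @return A cells x latent_dim matrix, or `list(mu, logvar)`.
#' @export
encode <- function(params, X, deterministic = TRUE) {
  config <- attr(params, "config")
  X <- as.matrix(X)
  if (ncol(X) != config$input_dim) {
    stop_fsb(sprintf("X has %d columns but the model expects %d",
                     ncol(X), config$input_dim), "fsb_invalid")
  }
  fw <- vae_forward(params, X, config, training = FALSE)
  if (deterministic) fw$mu else list(mu = fw$mu, logvar = fw$logvar)
}

#' Decode latent vectors back to expression space
#'
#' Evaluation-mode decoder; a pure function of `(params, Z)`.
#'
#' @param params trained `vae_params`.
#' @param Z cells x latent_dim matrix.
#' @return cells x genes reconstruction (not clipped).
#' @export
decode <- function(params, Z) {
  config <- attr(params, "config")
  Z <- as.matrix(Z)
  if (ncol(Z) != config$latent_dim) {
    stop_fsb("Z latent dimension mismatch", "fsb_invalid")
  }
  nh <- length(config$hidden_dims)
  g <- Z
  for (i in seq_len(nh)) {
    g <- relu(sweep(g %*% params[[paste0("dec", i, ".W")]], 2,
                    params[[paste0("dec", i, ".b")]], "+"))
  }
  sweep(g %*% params[["out.W"]], 2, params[["out.b"]], "+")
}

#' Reparameterization trick
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps ~ N(0, I)` drawn from the
#' current RNG stream (or a local stream when `seed` is given).
#'
#' @param mu,logvar matrices of identical shape.
#' @param seed optional seed for a local reproducible draw.
#' @return Sampled latent matrix `z`.
#' @export
reparameterize <- function(mu, logvar, seed = NULL) {
  stopifnot(all(dim(mu) == dim(logvar)))
  draw <- function() matrix(stats::rnorm(length(mu)), nrow = nrow(mu))
  eps <- if (is.null(seed)) draw() else with_seed(seed, draw())
  mu + exp(0.5 * logvar) * eps
}

#' VAE loss
#'
#' Reconstruction term: mean squared error over all entries. KL term:
#' `0.5 * sum_dims(exp(logvar) + mu^2 - 1 - logvar)` averaged over cells.
#' Total: `recon + kl_weight * kl`.
#'
#' @param X input minibatch.
#' @param X_recon reconstruction.
#' @param mu,logvar posterior parameters.
#' @param kl_weight KL weighting factor.
#' @return `list(total, recon, kl)`.
#' @export
vae_loss <- function(X, X_recon, mu, logvar, kl_weight) {
  recon <- mean((X - X_recon)^2)
  kl <- mean(0.5 * rowSums(exp(logvar) + mu^2 - 1 - logvar))
  list(total = recon + kl_weight * kl, recon = recon, kl = kl)
}

# gradients for one minibatch; returns list matching params plus the loss
vae_backward <- function(params, X, config, fw) {
  m <- nrow(X); d <- ncol(X)
  nh <- length(config$hidden_dims)
  alpha <- config$kl_weight
  cache <- fw$cache
  grads <- vector("list", length(params))
  names(grads) <- names(params)

  dxhat <- 2 * (fw$xhat - X) / (m * d)
  grads[["out.W"]] <- crossprod(cache$gdec, dxhat)
  grads[["out.b"]] <- colSums(dxhat)
  dg <- dxhat %*% t(params[["out.W"]])
  for (i in rev(seq_len(nh))) {
    if (!is.null(cache$gmask[[i]])) dg <- dg * cache$gmask[[i]]
    dg <- dg * (cache$ga[[i]] > 0)
    grads[[paste0("dec", i, ".W")]] <- crossprod(cache$g[[i]], dg)
    grads[[paste0("dec", i, ".b")]] <- colSums(dg)
    dg <- dg %*% t(params[[paste0("dec", i, ".W")]])
  }
  dz <- dg
  dmu <- dz + alpha * fw$mu / m
  dlv <- dz * cache$eps * 0.5 * exp(0.5 * fw$logvar) +
    alpha * 0.5 * (exp(fw$logvar) - 1) / m
  grads[["mu.W"]] <- crossprod(cache$henc, dmu)
  grads[["mu.b"]] <- colSums(dmu)
  grads[["lv.W"]] <- crossprod(cache$henc, dlv)
  grads[["lv.b"]] <- colSums(dlv)
  dh <- dmu %*% t(params[["mu.W"]]) + dlv %*% t(params[["lv.W"]])
  for (i in rev(seq_len(nh))) {
    if (!is.null(cache$mask[[i]])) dh <- dh * cache$mask[[i]]
    dh <- dh * (cache$a[[i]] > 0)
    grads[[paste0("enc", i, ".W")]] <- crossprod(cache$h[[i]], dh)
    grads[[paste0("enc", i, ".b")]] <- colSums(dh)
    dh <- dh %*% t(params[[paste0("enc", i, ".W")]])
  }
  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Train the VAE locally for a fixed number of epochs
#'
#' Full passes over the data in shuffled minibatches with Adam. Each
#' epoch's RNG stream (shuffle order, dropout masks, reparameterization
#' noise) is seeded by `mix_seed(base_seed, epoch_offset + epoch)`, so a
#' run split into consecutive segments (as the federated workflow does per
#' round, passing a running `epoch_offset` and the returned `opt_state`)
#' replays exactly the same sequence as one uninterrupted run.
#'
#' @param params starting `vae_params`.
#' @param ds a `log_transformed` `expression_dataset`.
#' @param epochs number of epochs (>= 1).
#' @param base_seed seed of the minibatch/noise stream.
#' @param epoch_offset global index of the epoch preceding this call.
#' @param opt_state Adam state from a previous call, or NULL to start fresh.
#' @return `list(params, trace, opt_state)`; `trace` is a data.frame with
#'   one `(epoch, total, recon, kl)` row per epoch (mean over minibatches).
#' @export
train_local <- function(params, ds, epochs, base_seed = 1L,
                        epoch_offset = 0L, opt_state = NULL) {
  config <- attr(params, "config")
  require_layer(ds, "log_transformed", "train_local")
  if (epochs < 1) stop_fsb("epochs must be >= 1", "fsb_invalid")
  n <- n_cells(ds)
  if (n == 0) stop_fsb("cannot train on an empty dataset", "fsb_empty")
  X <- ds$matrix
  if (is.null(opt_state)) opt_state <- adam_init(params)
  trace <- data.frame(epoch = integer(), total = numeric(),
                      recon = numeric(), kl = numeric())
  for (e in seq_len(epochs)) {
    ep <- epoch_offset + e
    losses <- with_seed(mix_seed(base_seed, ep), {
      perm <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      acc <- matrix(0, nrow = length(starts), ncol = 3)
      for (s in seq_along(starts)) {
        idx <- perm[starts[s]:min(starts[s] + config$batch_size - 1, n)]
        Xb <- X[idx, , drop = FALSE]
        fw <- vae_forward(params, Xb, config, training = TRUE)
        L <- vae_loss(Xb, fw$xhat, fw$mu, fw$logvar, config$kl_weight)
        grads <- vae_backward(params, Xb, config, fw)
        upd <- adam_step(params, grads, opt_state, config$learning_rate)
        params <- upd$params
        opt_state <- upd$state
        acc[s, ] <- c(L$total, L$recon, L$kl)
      }
      colMeans(acc)
    })
    trace <- rbind(trace, data.frame(epoch = ep, total = losses[1],
                                     recon = losses[2], kl = losses[3]))
  }
  list(params = params, trace = trace, opt_state = opt_state)
}

# deterministic (z = mu) loss on a held-aside set
eval_loss <- function(params, X, config) {
  fw <- vae_forward(params, X, config, training = FALSE)
  vae_loss(X, fw$xhat, fw$mu, fw$logvar, config$kl_weight)$total
}

#' Train with validation-based early stopping
#'
#' Splits off a validation fraction, trains epoch by epoch, and stops
#' when the best validation loss has not improved by more than
#' `min_delta` for `patience` consecutive epochs. Returns the parameters
#' of the best-validation epoch.
#'
#' @inheritParams train_local
#' @param max_epochs epoch budget (default 100).
#' @param patience epochs without improvement before stopping (default 20).
#' @param min_delta minimum improvement that resets patience (default 0).
#' @param val_fraction fraction of cells held out for validation.
#' @return `list(params, trace, stopped_epoch, best_epoch, val_trace)`.
#' @export
train_with_early_stopping <- function(params, ds, max_epochs = 100,
                                      patience = 20, min_delta = 0,
                                      val_fraction = 0.1, base_seed = 1L) {
  config <- attr(params, "config")
  require_layer(ds, "log_transformed", "train_with_early_stopping")
  if (val_fraction <= 0 || val_fraction >= 1) {
    stop_fsb("val_fraction must be in (0, 1)", "fsb_invalid")
  }
  n <- n_cells(ds)
  if (n < 2) stop_fsb("need at least 2 cells to split off validation", "fsb_empty")
  n_val <- max(1, round(n * val_fraction))
  val_idx <- with_seed(mix_seed(base_seed, 777L), sample.int(n, n_val))
  train_ds <- subset_dataset(ds, i = setdiff(seq_len(n), val_idx))
  X_val <- ds$matrix[val_idx, , drop = FALSE]

  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  opt_state <- NULL
  val_trace <- numeric(0)
  trace <- NULL
  stopped <- max_epochs
  for (e in seq_len(max_epochs)) {
    res <- train_local(params, train_ds, epochs = 1, base_seed = base_seed,
                       epoch_offset = e - 1L, opt_state = opt_state)
    params <- res$params
    opt_state <- res$opt_state
    trace <- rbind(trace, res$trace)
    vl <- eval_loss(params, X_val, config)
    val_trace <- c(val_trace, vl)
    if (vl < best$loss - min_delta) {
      best <- list(loss = vl, params = params, epoch = e)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) { stopped <- e; break }
    }
  }
  list(params = best$params, trace = trace, stopped_epoch = stopped,
       best_epoch = best$epoch, val_trace = val_trace)
}
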