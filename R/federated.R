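#' Configure a federated run
#'
#' @param n_rounds communication rounds R (default 8).
#' @param local_epochs local epochs e per round (default 2).
#' @param secure aggregate under additive secret sharing.
#' @param n_parties computational parties when `secure` (default 3).
#' @param seed global seed; every client/round stream derives from it.
#' @return A `fed_config` object.
#' @export
fed_config <- function(n_rounds = 8, local_epochs = 2, secure = FALSE,
                       n_parties = 3, seed = 1L) {
  if (n_rounds < 1) stop_fsb("n_rounds must be >= 1", "fsb_invalid")
  if (local_epochs < 1) stop_fsb("local_epochs must be >= 1", "fsb_invalid")
  if (n_parties < 2) stop_fsb("n_parties must be >= 2", "fsb_invalid")
  structure(list(n_rounds = as.integer(n_rounds),
                 local_epochs = as.integer(local_epochs),
                 secure = isTRUE(secure), n_parties = as.integer(n_parties),
                 seed = as.integer(seed)),
            class = "fed_config")
}

#' Sample-size-weighted federated averaging
#'
#' Every tensor of the result is the convex combination of the clients'
#' tensors with normalized weights `N_c / sum(N)`.
#'
#' @param params_list list of `vae_params` sharing one shape signature.
#' @param weights positive client weights (cell counts).
#' @return Averaged `vae_params`.
#' @export
fedavg <- function(params_list, weights) {
  stopifnot(length(params_list) >= 1, length(params_list) == length(weights))
  if (any(weights <= 0)) stop_fsb("weights must be positive", "fsb_invalid")
  nms <- names(params_list[[1]])
  for (p in params_list) {
    if (!identical(names(p), nms)) stop_fsb("parameter shape signatures differ", "fsb_invalid")
  }
  w <- weights / sum(weights)
  out <- params_list[[1]]
  for (nm in nms) {
    acc <- params_list[[1]][[nm]] * w[1]
    for (c in seq_along(params_list)[-1]) {
      acc <- acc + params_list[[c]][[nm]] * w[c]
    }
    out[[nm]] <- acc
  }
  out
}

#' Train a VAE across clients with federated averaging
#'
#' All clients start from the same initial parameters. Each round, every
#' client trains locally for `local_epochs` epochs (its Adam state and
#' global epoch counter persist across rounds) and uploads parameters and
#' cell counts; the coordinator aggregates by sample-size-weighted
#' averaging — through the secret-sharing protocol when
#' `fed_config$secure` — and broadcasts the update. The coordinator's
#' visible state is restricted to parameter digests, counts (or shares)
#' and losses, which the returned transcript records.
#'
#' @param clients list from [partition_by_batch()] (datasets must be
#'   `log_transformed`).
#' @param fed a [fed_config()].
#' @param config a [vae_config()].
#' @return `list(params, round_logs, transcript)`; `round_logs` is a
#'   data.frame (round, client, n_cells, total, recon, kl, digest).
#' @export
federated_train <- function(clients, fed, config) {
  if (length(clients) < 1) stop_fsb("need at least one client", "fsb_empty")
  global <- init_vae(config)
  opt_states <- vector("list", length(clients))
  weights <- vapply(clients, function(cl) cl$n_cells, numeric(1))
  logs <- NULL
  transcript <- list()
  for (r in seq_len(fed$n_rounds)) {
    local_params <- vector("list", length(clients))
    for (c in seq_along(clients)) {
      res <- train_local(global, clients[[c]]$dataset,
                         epochs = fed$local_epochs,
                         base_seed = mix_seed(fed$seed, clients[[c]]$client_id),
                         epoch_offset = (r - 1L) * fed$local_epochs,
                         opt_state = opt_states[[c]])
      local_params[[c]] <- res$params
      opt_states[[c]] <- res$opt_state
      last <- res$trace[nrow(res$trace), ]
      logs <- rbind(logs, data.frame(
        round = r, client = clients[[c]]$client_id,
        n_cells = clients[[c]]$n_cells,
        total = last$total, recon = last$recon, kl = last$kl,
        digest = tensor_digest(flatten_params(res$params))))
    }
    if (fed$secure) {
      flat <- lapply(local_params, flatten_params)
      agg <- secure_weighted_sum(flat, weights, n_parties = fed$n_parties,
                                 seed = mix_seed(fed$seed, 5000L, r))
      global <- unflatten_params(agg$value, config)
      transcript <- c(transcript, agg$transcript)
    } else {
      global <- fedavg(local_params, weights)
      for (c in seq_along(clients)) {
        transcript[[length(transcript) + 1]] <- transcript_entry(
          from = paste0("client", clients[[c]]$client_id), to = "coordinator",
          kind = "params_digest",
          digest = tensor_digest(flatten_params(local_params[[c]])))
      }
    }
    transcript[[length(transcript) + 1]] <- transcript_entry(
      from = "coordinator", to = "all", kind = "broadcast",
      digest = tensor_digest(flatten_params(global)))
  }
  list(params = global, round_logs = logs, transcript = transcript)
}

#' Federated shared/standalone cell-type identification
#'
#' Clients report only which cell types they hold (presence, not counts).
#' A type held by two or more clients is shared; by exactly one,
#' standalone. With one client per batch this matches the centralized
#' rule on pooled data.
#'
#' @param clients list from [partition_by_batch()].
#' @return `list(shared, standalone)`.
#' @export
global_type_sharing <- function(clients) {
  presence <- lapply(clients, function(cl) names(cl$type_counts)[cl$type_counts > 0])
  types <- sort(unique(unlist(presence)))
  n_holders <- vapply(types, function(t) {
    sum(vapply(presence, function(p) t %in% p, logical(1)))
  }, numeric(1))
  list(shared = types[n_holders >= 2], standalone = types[n_holders == 1])
}

#' Federated delta-vector estimation and correction
#'
#' Three steps per shared cell type: (1) the dominant client is
#' identified from per-client counts — via the secure-argmax protocol
#' when `fed$secure`, so only the winner's identity is revealed; (2) the
#' dominant client encodes its own type-t cells deterministically and
#' broadcasts their latent mean `M^t`; (3) every client shifts its local
#' latents with [correct_latent()] and decodes. Standalone types are not
#' corrected. Clients absent from training (held-out studies) may
#' participate; the model is never retrained on them.
#'
#' @param clients list from [partition_by_batch()]; may include held-out
#'   clients that did not train.
#' @param params the trained global `vae_params`.
#' @param fed a [fed_config()].
#' @return A `correction_result`: per-client `corrected` datasets and
#'   `latent`/`latent_corrected` matrices, the global `means`
#'   (`type_mean_map`), `sharing`, `dominant_client` per shared type, and
#'   the protocol `transcript`.
#' @export
federated_correction <- function(clients, params, fed = fed_config()) {
  if (length(clients) < 1) stop_fsb("need at least one client", "fsb_empty")
  sharing <- global_type_sharing(clients)
  transcript <- list()
  client_ids <- vapply(clients, function(cl) as.character(cl$client_id), character(1))

  # step 1: dominant client per shared type from per-client counts
  dominant <- list()
  for (t in sharing$shared) {
    counts <- vapply(clients, function(cl) {
      v <- cl$type_counts[t]
      if (is.na(v)) 0L else as.integer(v)
    }, integer(1))
    names(counts) <- client_ids
    if (fed$secure) {
      res <- secure_argmax(counts, n_parties = fed$n_parties,
                           seed = mix_seed(fed$seed, 9000L, match(t, sharing$shared)))
      dominant[[t]] <- res$winner
      transcript <- c(transcript, res$transcript)
    } else {
      ord <- order(-counts, as.integer(client_ids))
      dominant[[t]] <- client_ids[ord[1]]
      transcript[[length(transcript) + 1]] <- transcript_entry(
        from = "clients", to = "coordinator", kind = "count",
        digest = paste(counts, collapse = ","))
    }
    transcript[[length(transcript) + 1]] <- transcript_entry(
      from = "coordinator", to = "all", kind = "dominant_id",
      digest = dominant[[t]])
  }

  # step 2: dominant clients compute and broadcast their type means
  means <- list()
  for (t in sharing$shared) {
    cl <- clients[[match(dominant[[t]], client_ids)]]
    idx <- which(cl$dataset$cell_type == t)
    if (length(idx) == 0) stop_fsb(
      sprintf("dominant client for '%s' holds no such cells", t), "fsb_internal")
    Z <- encode(params, cl$dataset$matrix[idx, , drop = FALSE],
                deterministic = TRUE)
    means[[t]] <- list(mean_latent = colMeans(Z),
                       dominant_batch = cl$batch,
                       dominant_count = length(idx))
    transcript[[length(transcript) + 1]] <- transcript_entry(
      from = paste0("client", dominant[[t]]), to = "all", kind = "mean_vector",
      digest = tensor_digest(means[[t]]$mean_latent))
  }
  means <- structure(means, class = "type_mean_map")

  # step 3: local correction and decoding at every client
  per_client <- lapply(clients, function(cl) {
    Z <- encode(params, cl$dataset$matrix, deterministic = TRUE)
    Zc <- correct_latent(Z, cl$dataset$cell_type,
                         rep(cl$batch, n_cells(cl$dataset)), means)
    list(client_id = cl$client_id, batch = cl$batch,
         latent = Z, latent_corrected = Zc,
         corrected = decode_corrected(params, Zc, cl$dataset))
  })
  structure(list(per_client = per_client, means = means, sharing = sharing,
                 dominant_client = dominant, transcript = transcript),
            class = "correction_result")
}

#' Export a portable public mean-latent artifact
#'
#' A self-contained artifact (model digest plus per-type means, no
#' per-cell data) that lets a new site correct its batch locally without
#' rejoining the federation, valid as long as dominance is unchanged.
#'
#' @param result a `correction_result`.
#' @param params the global model whose digest is embedded.
#' @return A `public_means` object (serializable with [saveRDS()]).
#' @export
export_public_means <- function(result, params) {
  structure(list(model_digest = tensor_digest(flatten_params(params)),
                 means = result$means),
            class = "public_means")
}

#' Correct a local dataset with a public mean artifact
#'
#' @param ds a `log_transformed` `expression_dataset` held by one site
#'   (one batch).
#' @param params the global `vae_params`; its digest must match the
#'   artifact.
#' @param artifact a `public_means` object.
#' @return `list(latent, latent_corrected, corrected)`.
#' @export
correct_with_public_means <- function(ds, params, artifact) {
  stopifnot(inherits(artifact, "public_means"))
  if (!identical(artifact$model_digest,
                 tensor_digest(flatten_params(params)))) {
    stop_fsb("model digest does not match the public artifact", "fsb_invalid")
  }
  Z <- encode(params, ds$matrix, deterministic = TRUE)
  Zc <- correct_latent(Z, ds$cell_type, ds$batch, artifact$means)
  list(latent = Z, latent_corrected = Zc,
       corrected = decode_corrected(params, Zc, ds))
}
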