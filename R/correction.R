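#' Identify shared and standalone cell types
#'
#' A cell type present in two or more batches is *shared* and eligible
#' for latent-shift correction; a type confined to a single batch is
#' *standalone* and is never corrected.
#'
#' @param ds an `expression_dataset`.
#' @return `list(shared, standalone)` of cell-type label vectors.
#' @export
identify_sharing <- function(ds) {
  tab <- table(ds$cell_type, ds$batch)
  present <- rowSums(tab > 0)
  types <- rownames(tab)[present > 0]
  n_b <- present[types]
  list(shared = types[n_b >= 2], standalone = types[n_b == 1])
}

#' Dominant batch for a shared cell type
#'
#' The batch holding the most cells of type `t`; ties go to the
#' lexicographically smallest batch label.
#'
#' @param ds an `expression_dataset`.
#' @param t a shared cell-type label.
#' @return `list(batch, count)`.
#' @export
dominant_batch_for <- function(ds, t) {
  sharing <- identify_sharing(ds)
  if (!(t %in% sharing$shared)) {
    stop_fsb(sprintf("cell type '%s' is not shared across batches", t),
             "fsb_contract")
  }
  counts <- table(ds$batch[ds$cell_type == t])
  counts <- counts[counts > 0]
  ord <- order(-as.integer(counts), names(counts))
  list(batch = names(counts)[ord[1]], count = as.integer(counts[ord[1]]))
}

#' Mean latent vectors of dominant batches
#'
#' For every shared cell type `t`, encodes (deterministically) the type-t
#' cells of its dominant batch and averages them. These per-type means
#' are the delta-vector sources for correction.
#'
#' @param params trained `vae_params`.
#' @param ds the `log_transformed` `expression_dataset`.
#' @param sharing optional result of [identify_sharing()].
#' @return A `type_mean_map`: named list over shared types with
#'   `mean_latent`, `dominant_batch`, `dominant_count`.
#' @export
compute_type_means <- function(params, ds, sharing = NULL) {
  if (is.null(sharing)) sharing <- identify_sharing(ds)
  Z <- encode(params, ds$matrix, deterministic = TRUE)
  out <- lapply(sharing$shared, function(t) {
    dom <- dominant_batch_for(ds, t)
    idx <- which(ds$cell_type == t & ds$batch == dom$batch)
    list(mean_latent = colMeans(Z[idx, , drop = FALSE]),
         dominant_batch = dom$batch,
         dominant_count = dom$count)
  })
  names(out) <- sharing$shared
  structure(out, class = "type_mean_map")
}

#' Export a type-mean map as a data.frame
#'
#' @param means a `type_mean_map`.
#' @return data.frame (cell_type, dominant_batch, dominant_count,
#'   z1..zk), suitable for CSV export.
#' @export
type_means_table <- function(means) {
  rows <- lapply(names(means), function(t) {
    m <- means[[t]]
    cbind(data.frame(cell_type = t, dominant_batch = m$dominant_batch,
                     dominant_count = m$dominant_count),
          as.data.frame(t(stats::setNames(m$mean_latent,
                                          paste0("z", seq_along(m$mean_latent))))))
  })
  do.call(rbind, rows)
}

#' Correct latent representations by delta-vector shifts
#'
#' For each cell of shared type `t` in batch `b`, the latent vector is
#' shifted by the delta vector `M^t - mean(Z over type-t cells of batch
#' b)`, which moves every batch's type-t centroid exactly onto the
#' dominant batch's centroid `M^t`. Cells of standalone types are left
#' untouched. Setting `literal_subtraction = TRUE` instead subtracts
#' `M^t` from every type-t cell (centering types rather than aligning
#' batches) for comparison.
#'
#' @param Z cells x latent matrix aligned with the labels.
#' @param type_labels,batch_labels per-cell labels.
#' @param means a `type_mean_map` covering all shared types present.
#' @param literal_subtraction use the plain `Z - M^t` form.
#' @return Corrected latent matrix of the same shape.
#' @export
correct_latent <- function(Z, type_labels, batch_labels, means,
                           literal_subtraction = FALSE) {
  Z <- as.matrix(Z)
  type_labels <- as.character(type_labels)
  batch_labels <- as.character(batch_labels)
  stopifnot(nrow(Z) == length(type_labels), nrow(Z) == length(batch_labels))
  # every type spanning >= 2 batches in these labels must have a mean
  tab <- table(type_labels, batch_labels)
  spans <- rowSums(tab > 0)
  shared_here <- rownames(tab)[spans >= 2]
  missing <- setdiff(shared_here, names(means))
  if (length(missing) > 0) {
    stop_fsb(paste0("shared cell types missing from the mean map: ",
                    paste(missing, collapse = ", ")), "fsb_contract")
  }
  out <- Z
  for (t in intersect(names(means), unique(type_labels))) {
    M <- means[[t]]$mean_latent
    idx_t <- which(type_labels == t)
    if (literal_subtraction) {
      out[idx_t, ] <- sweep(Z[idx_t, , drop = FALSE], 2, M, "-")
      next
    }
    for (b in unique(batch_labels[idx_t])) {
      idx <- idx_t[batch_labels[idx_t] == b]
      centroid <- colMeans(Z[idx, , drop = FALSE])
      out[idx, ] <- sweep(Z[idx, , drop = FALSE], 2, M - centroid, "+")
    }
  }
  out
}

#' Decode corrected latents into a corrected expression dataset
#'
#' Applies the decoder to the corrected latent matrix, clips negatives to
#' zero, and carries over the original annotations.
#'
#' @param params trained `vae_params`.
#' @param Z_corrected corrected latent matrix.
#' @param ds the source `expression_dataset` providing labels and gene ids.
#' @return An `expression_dataset` on the `log_transformed` layer.
#' @export
decode_corrected <- function(params, Z_corrected, ds) {
  Xc <- pmax(decode(params, Z_corrected), 0)
  expression_dataset(Xc, batch = ds$batch, cell_type = ds$cell_type,
                     gene_ids = ds$gene_ids, cell_ids = ds$cell_ids,
                     layer = "log_transformed")
}

#' Centralized train-and-correct baseline
#'
#' The pooled-data reference workflow: train the VAE on all cells, encode
#' deterministically, compute dominant-batch type means, shift latents,
#' decode. This is the baseline against which the federated workflow is
#' compared.
#'
#' @param ds a `log_transformed` `expression_dataset`.
#' @param config a [vae_config()].
#' @param epochs training epochs (default 100).
#' @param base_seed minibatch stream seed.
#' @param early_stopping use validation-based early stopping.
#' @param literal_subtraction passed to [correct_latent()].
#' @return `list(params, corrected, latent, latent_corrected, means,
#'   sharing, trace)`.
#' @export
run_centralized <- function(ds, config, epochs = 100, base_seed = 1L,
                            early_stopping = FALSE,
                            literal_subtraction = FALSE) {
  require_layer(ds, "log_transformed", "run_centralized")
  params <- init_vae(config)
  if (early_stopping) {
    res <- train_with_early_stopping(params, ds, max_epochs = epochs,
                                     base_seed = base_seed)
  } else {
    res <- train_local(params, ds, epochs = epochs, base_seed = base_seed)
  }
  params <- res$params
  sharing <- identify_sharing(ds)
  Z <- encode(params, ds$matrix, deterministic = TRUE)
  means <- compute_type_means(params, ds, sharing)
  Zc <- correct_latent(Z, ds$cell_type, ds$batch, means,
                       literal_subtraction = literal_subtraction)
  corrected <- decode_corrected(params, Zc, ds)
  list(params = params, corrected = corrected, latent = Z,
       latent_corrected = Zc, means = means, sharing = sharing,
       trace = res$trace)
}
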