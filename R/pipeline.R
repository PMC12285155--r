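#' Hyperparameter sweep over local epochs and communication rounds
#'
#' Trains the federated workflow for every (local_epochs, n_rounds) cell
#' of the grid, corrects, evaluates the six tuning metrics (NMI, ARI,
#' ASW_B, ASW_C, kNN accuracy, EBM) on the decoded corrected expression,
#' and reports each as a difference against a centralized baseline that
#' is computed once and reused across cells.
#'
#' @param ds a `log_transformed` `expression_dataset`.
#' @param epochs_grid,rounds_grid nonempty integer grids.
#' @param config a [vae_config()].
#' @param seed global seed.
#' @param baseline_epochs centralized training epochs for the baseline.
#' @return data.frame with one row per grid cell: the six federated
#'   metric values, their deltas vs the baseline, and the baseline
#'   digest (identical across rows by construction).
#' @export
sweep_grid <- function(ds, epochs_grid, rounds_grid, config, seed = 1L,
                       baseline_epochs = max(epochs_grid) * max(rounds_grid)) {
  stopifnot(length(epochs_grid) >= 1, length(rounds_grid) >= 1)
  cent <- run_centralized(ds, config, epochs = baseline_epochs,
                          base_seed = mix_seed(seed, 1L))
  emb_c <- pca_embed(cent$corrected$matrix)
  base <- tuning_metrics(emb_c, ds$batch, ds$cell_type, seed = seed)
  base_digest <- tensor_digest(flatten_params(cent$params))
  clients <- partition_by_batch(ds)
  rows <- list()
  for (e in epochs_grid) for (r in rounds_grid) {
    fed <- fed_config(n_rounds = r, local_epochs = e, seed = seed)
    tr <- federated_train(clients, fed, config)
    corr <- federated_correction(clients, tr$params, fed)
    merged <- merge_correction(corr, ds)
    emb <- pca_embed(merged$corrected$matrix)
    vals <- tuning_metrics(emb, ds$batch, ds$cell_type, seed = seed)
    row <- data.frame(local_epochs = e, n_rounds = r)
    for (m in names(vals)) {
      row[[m]] <- vals[[m]]
      row[[paste0("delta_", m)]] <- vals[[m]] - base[[m]]
    }
    row$baseline_digest <- base_digest
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}

tuning_metrics <- function(emb, batch_labels, type_labels, seed = 1L) {
  list(nmi = nmi_score(emb, type_labels, seed = seed),
       ari = ari_score(emb, type_labels, seed = seed),
       asw_b = asw_batch(emb, batch_labels, type_labels),
       asw_c = asw_cell(emb, type_labels),
       knn_acc = knn_accuracy(emb, type_labels),
       ebm = ebm_score(emb, batch_labels, seed = seed))
}

#' Reassemble a federated correction into pooled datasets
#'
#' Concatenates the per-client corrected outputs and latent matrices and
#' reorders them to match the cell order of a reference dataset.
#'
#' @param result a `correction_result`.
#' @param ds the pooled reference `expression_dataset`.
#' @return `list(corrected, latent, latent_corrected)` aligned with
#'   `ds$cell_ids`.
#' @export
merge_correction <- function(result, ds) {
  corrected <- concat_datasets(lapply(result$per_client, `[[`, "corrected"))
  ord <- match(ds$cell_ids, corrected$cell_ids)
  if (anyNA(ord)) stop_fsb("correction result does not cover the reference cells",
                           "fsb_invalid")
  Z <- do.call(rbind, lapply(result$per_client, `[[`, "latent"))[ord, , drop = FALSE]
  Zc <- do.call(rbind, lapply(result$per_client, `[[`, "latent_corrected"))[ord, , drop = FALSE]
  list(corrected = subset_dataset(corrected, i = ord), latent = Z,
       latent_corrected = Zc)
}

#' End-to-end federated batch-correction pipeline
#'
#' simulate (or load) -> preprocess -> federated training (optionally
#' secure) -> federated correction -> metric evaluation on raw vs
#' corrected embeddings -> leave-one-batch-out classification on the
#' corrected latents. A manifest capturing all parameters and seeds is
#' written alongside the outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param input_h5ad optional input file; when NULL, `preset` is simulated.
#' @param preset [sim_preset()] name used when simulating.
#' @param seed global seed for simulation, training, and metrics.
#' @param n_rounds,local_epochs,secure,n_parties federated settings.
#' @param hidden_dims,latent_dim,kl_weight VAE settings (the narrow
#'   default keeps desk-scale runs fast; widen for real data).
#' @param preprocess_data run the preprocessing pipeline (set FALSE when
#'   the input is already log-transformed).
#' @param classify run the leave-one-batch-out classifier.
#' @return Invisibly, `list(metrics, comparison, classification, manifest)`;
#'   files written: `manifest.json`, `metrics.csv`, `corrected.h5ad`,
#'   `classification.csv` (when requested), `round_logs.csv`.
#' @export
run_pipeline <- function(out_dir, input_h5ad = NULL,
                         preset = "two_batch_shared", seed = 1L,
                         n_rounds = 8, local_epochs = 2, secure = FALSE,
                         n_parties = 3, hidden_dims = c(64, 64),
                         latent_dim = 10, kl_weight = 0.005,
                         preprocess_data = TRUE, classify = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  res <- tryCatch({
    if (is.null(input_h5ad)) {
      sim <- generate_dataset(sim_preset(preset, seed = seed))
      ds <- sim$dataset
    } else {
      if (!file.exists(input_h5ad)) stop_fsb(
        sprintf("input file not found: %s", input_h5ad), "fsb_config")
      ds <- read_h5ad(input_h5ad)
    }
    stage <- "preprocess"
    if (preprocess_data && ds$layer == "raw_counts") ds <- preprocess(ds)
    stage <- "train"
    config <- vae_config(input_dim = n_genes(ds), hidden_dims = hidden_dims,
                         latent_dim = latent_dim, kl_weight = kl_weight,
                         seed = seed)
    fed <- fed_config(n_rounds = n_rounds, local_epochs = local_epochs,
                      secure = secure, n_parties = n_parties, seed = seed)
    clients <- partition_by_batch(ds)
    tr <- federated_train(clients, fed, config)
    stage <- "correct"
    corr <- federated_correction(clients, tr$params, fed)
    merged <- merge_correction(corr, ds)
    stage <- "evaluate"
    emb_raw <- pca_embed(ds$matrix)
    emb_cor <- pca_embed(merged$corrected$matrix)
    m_raw <- evaluate_embedding(emb_raw, ds$batch, ds$cell_type, seed = seed)
    m_cor <- evaluate_embedding(emb_cor, ds$batch, ds$cell_type, seed = seed)
    metrics <- data.frame(
      metric = names(m_raw),
      raw = unlist(m_raw, use.names = FALSE),
      corrected = unlist(m_cor, use.names = FALSE))
    stage <- "classify"
    classification <- NULL
    if (classify) {
      cls <- lobo_cv(merged$latent_corrected, ds$cell_type, ds$batch,
                     mlp_config(hidden_dims = c(64, 64), epochs = 30,
                                seed = seed))
      classification <- cls$folds
    }
    stage <- "write"
    manifest <- list(
      version = as.character(utils::packageVersion("fedscbatch")),
      seed = seed, preset = if (is.null(input_h5ad)) preset else NULL,
      input = input_h5ad, n_rounds = n_rounds, local_epochs = local_epochs,
      secure = secure, n_parties = n_parties, hidden_dims = hidden_dims,
      latent_dim = latent_dim, kl_weight = kl_weight,
      n_cells = n_cells(ds), n_genes = n_genes(ds),
      model_digest = tensor_digest(flatten_params(tr$params)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(tr$round_logs, file.path(out_dir, "round_logs.csv"),
                     row.names = FALSE)
    if (!is.null(classification)) {
      utils::write.csv(classification, file.path(out_dir, "classification.csv"),
                       row.names = FALSE)
    }
    write_h5ad(merged$corrected, file.path(out_dir, "corrected.h5ad"))
    invisible(list(metrics = metrics, classification = classification,
                   manifest = manifest, model = tr$params,
                   correction = corr))
  }, fedscbatch_error = function(e) {
    stop_fsb(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
             class(e)[1])
  })
  res
}
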