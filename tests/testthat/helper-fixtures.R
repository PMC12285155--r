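# Fixture builders shared across test files. Heavier artifacts (the
# preprocessed two-batch dataset and a trained narrow VAE) are built once
# per test run and memoized.

make_tiny_dataset <- function(n_per = 10, seed = 1) {
  # 2 batches x 2 types, tiny deterministic counts
  withr::with_seed(seed, {
    n <- n_per * 4
    m <- matrix(rpois(n * 30, lambda = 5), nrow = n)
    expression_dataset(
      m,
      batch = rep(c("A", "B"), each = n_per * 2),
      cell_type = rep(c("t1", "t2", "t1", "t2"), each = n_per),
      layer = "raw_counts")
  })
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

two_batch_prepped <- function() {
  memo("two_batch_prepped", function() {
    sim <- generate_dataset(sim_preset("two_batch_shared", seed = 11))
    list(ds = preprocess(sim$dataset), truth = sim$truth)
  })
}

# narrow VAE trained on the two-batch fixture: reused by correction,
# federated and metric tests
trained_two_batch <- function() {
  memo("trained_two_batch", function() {
    ds <- two_batch_prepped()$ds
    config <- vae_config(input_dim = n_genes(ds), hidden_dims = c(64, 64),
                         seed = 7)
    fit <- train_local(init_vae(config), ds, epochs = 10, base_seed = 5)
    list(ds = ds, config = config, params = fit$params)
  })
}

# well-separated Gaussian type blobs with randomized batch labels: the
# canonical "perfectly integrated" geometry for metric null checks
make_blob_embedding <- function(n_per = 150, n_types = 2, d = 5, sep = 12,
                                seed = 1) {
  withr::with_seed(seed, {
    coords <- do.call(rbind, lapply(seq_len(n_types), function(t) {
      ctr <- numeric(d); ctr[1] <- (t - 1) * sep
      matrix(rnorm(n_per * d), ncol = d) + rep(ctr, each = n_per)
    }))
    list(emb = coords,
         type = factor(rep(paste0("t", seq_len(n_types)), each = n_per)),
         batch = factor(sample(c("A", "B"), n_per * n_types, replace = TRUE)))
  })
}
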