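single_client <- function(ds) {
  list(list(client_id = 1L, batch = "pooled", dataset = ds,
            n_cells = n_cells(ds),
            type_counts = {
              tc <- table(ds$cell_type)
              stats::setNames(as.integer(tc), names(tc))
            }))
}

test_that("fedavg is the normalized convex combination of client parameters", {
  cfg <- vae_config(input_dim = 6, hidden_dims = c(4), latent_dim = 2, seed = 1)
  p <- init_vae(cfg)
  expect_identical(fedavg(list(p), 17)[], p[])

  neg <- unflatten_params(-flatten_params(p), cfg)
  zero <- fedavg(list(p, neg), c(1, 1))
  expect_equal(max(abs(flatten_params(zero))), 0)

  a <- unflatten_params(rep(0, length(flatten_params(p))), cfg)
  b <- unflatten_params(rep(4, length(flatten_params(p))), cfg)
  expect_equal(unique(flatten_params(fedavg(list(a, b), c(1, 3)))), 3)

  # envelope invariant: within per-coordinate min/max of inputs
  withr::with_seed(2, {
    ps <- lapply(1:3, function(i) {
      unflatten_params(rnorm(length(flatten_params(p))), cfg)
    })
    avg <- flatten_params(fedavg(ps, c(2, 5, 1)))
    lo <- pmin(flatten_params(ps[[1]]), flatten_params(ps[[2]]), flatten_params(ps[[3]]))
    hi <- pmax(flatten_params(ps[[1]]), flatten_params(ps[[2]]), flatten_params(ps[[3]]))
    expect_true(all(avg >= lo - 1e-12 & avg <= hi + 1e-12))
  })
  expect_error(fedavg(list(p), 0), class = "fsb_invalid")
})

test_that("one-client federated training equals uninterrupted local training", {
  ds <- two_batch_prepped()$ds
  cfg <- vae_config(input_dim = n_genes(ds), hidden_dims = c(32, 32),
                    latent_dim = 8, seed = 2)
  fed <- fed_config(n_rounds = 3, local_epochs = 2, seed = 21)
  ft <- federated_train(single_client(ds), fed, cfg)
  ct <- train_local(init_vae(cfg), ds, epochs = 6,
                    base_seed = mix_seed(21L, 1L))
  expect_identical(flatten_params(ft$params), flatten_params(ct$params))
  expect_error(fed_config(n_rounds = 0), class = "fsb_invalid")
  expect_error(federated_train(list(), fed, cfg), class = "fsb_empty")
})

test_that("identical clients with equal weights reproduce single-client training", {
  ds <- two_batch_prepped()$ds
  sub <- fedscbatch:::subset_dataset(ds, i = 1:120)
  cfg <- vae_config(input_dim = n_genes(ds), hidden_dims = c(16, 16),
                    latent_dim = 4, seed = 2)
  fed <- fed_config(n_rounds = 2, local_epochs = 1, seed = 8)
  twin <- function(id) list(client_id = id, batch = paste0("b", id),
                            dataset = sub, n_cells = n_cells(sub),
                            type_counts = stats::setNames(
                              as.integer(table(sub$cell_type)),
                              names(table(sub$cell_type))))
  # clients share the data but have distinct seed streams; after averaging
  # identical-data clients the result equals a client whose stream is its own
  ft2 <- federated_train(list(twin(1L), twin(1L)), fed, cfg)
  ft1 <- federated_train(list(twin(1L)), fed, cfg)
  expect_equal(flatten_params(ft2$params), flatten_params(ft1$params),
               tolerance = 1e-12)
})

test_that("federated sharing detection agrees with the centralized rule", {
  ds <- generate_dataset(sim_preset("standalone_type", seed = 4))$dataset
  clients <- partition_by_batch(ds)
  fed_sh <- global_type_sharing(clients)
  cent_sh <- identify_sharing(ds)
  expect_setequal(fed_sh$shared, cent_sh$shared)
  expect_setequal(fed_sh$standalone, cent_sh$standalone)
  expect_true("lonely" %in% fed_sh$standalone)
})

test_that("federated correction equals centralized correction under one model", {
  fx <- trained_two_batch()
  ds <- fx$ds
  clients <- partition_by_batch(ds)
  fed <- fed_config(seed = 3)
  fc <- federated_correction(clients, fx$params, fed)
  merged <- merge_correction(fc, ds)

  Z <- encode(fx$params, ds$matrix)
  means <- compute_type_means(fx$params, ds)
  Zc <- correct_latent(Z, ds$cell_type, ds$batch, means)
  expect_equal(merged$latent_corrected, Zc, tolerance = 1e-12)
  for (t in names(fc$means)) {
    expect_equal(fc$means[[t]]$mean_latent, means[[t]]$mean_latent,
                 tolerance = 1e-12)
  }
  # one-client federation equals centralized correction exactly
  fc1 <- federated_correction(single_client(ds), fx$params, fed)
  expect_identical(fc1$per_client[[1]]$latent, Z)
})

test_that("held-out clients reshape the mean map only when they dominate", {
  fx <- trained_two_batch()
  ds <- fx$ds
  clients <- partition_by_batch(ds)
  fed <- fed_config(seed = 3)
  base <- federated_correction(clients, fx$params, fed)

  # held-out client too small to dominate anything
  tiny_idx <- which(ds$cell_type == "alpha")[1:3]
  tiny <- fedscbatch:::subset_dataset(ds, i = tiny_idx)
  tiny$batch <- factor(rep("newstudy", 3))
  ho_small <- list(client_id = 3L, batch = "newstudy", dataset = tiny,
                   n_cells = 3L, type_counts = c(alpha = 3L))
  with_small <- federated_correction(c(clients, list(ho_small)), fx$params, fed)
  for (t in names(base$means)) {
    expect_equal(with_small$means[[t]]$mean_latent, base$means[[t]]$mean_latent)
    expect_equal(with_small$dominant_client[[t]], base$dominant_client[[t]])
  }

  # held-out client dominating one type updates exactly that type's mean
  big_idx <- which(ds$cell_type == "alpha")
  big <- fedscbatch:::subset_dataset(ds, i = big_idx)
  big$batch <- factor(rep("newstudy", length(big_idx)))
  ho_big <- list(client_id = 3L, batch = "newstudy", dataset = big,
                 n_cells = length(big_idx),
                 type_counts = c(alpha = length(big_idx)))
  with_big <- federated_correction(c(clients, list(ho_big)), fx$params, fed)
  expect_equal(with_big$dominant_client[["alpha"]], "3")
  # pooled-data oracle: the new mean is the held-out client's own average
  Zho <- encode(fx$params, big$matrix)
  expect_equal(with_big$means[["alpha"]]$mean_latent, colMeans(Zho),
               tolerance = 1e-12)
  for (t in setdiff(names(base$means), "alpha")) {
    expect_equal(with_big$means[[t]]$mean_latent, base$means[[t]]$mean_latent)
  }
})

test_that("public mean artifacts enable equivalent local correction", {
  fx <- trained_two_batch()
  ds <- fx$ds
  clients <- partition_by_batch(ds)
  fed <- fed_config(seed = 3)
  fc <- federated_correction(clients, fx$params, fed)
  art <- export_public_means(fc, fx$params)

  # round trip through serialization
  f <- withr::local_tempfile(fileext = ".rds")
  saveRDS(art, f)
  art2 <- readRDS(f)
  expect_equal(art2, art)

  # artifact holds aggregate vectors only: nothing scales with cell count
  sizes <- vapply(art$means, function(m) length(m$mean_latent), numeric(1))
  expect_true(all(sizes == attr(fx$params, "config")$latent_dim))

  # a client correcting with the artifact matches its federated result
  local <- correct_with_public_means(clients[[1]]$dataset, fx$params, art)
  expect_equal(local$latent_corrected, fc$per_client[[1]]$latent_corrected)
  wrong <- init_vae(attr(fx$params, "config"))
  expect_error(correct_with_public_means(clients[[1]]$dataset, wrong, art),
               class = "fsb_invalid")
})

test_that("coordinator-visible state carries digests, counts and means only", {
  fx <- trained_two_batch()
  ds <- fx$ds
  clients <- partition_by_batch(ds)
  cfg <- vae_config(input_dim = n_genes(ds), hidden_dims = c(16, 16),
                    latent_dim = 4, seed = 2)
  fed <- fed_config(n_rounds = 1, local_epochs = 1, seed = 5)
  tr <- federated_train(clients, fed, cfg)
  kinds <- vapply(tr$transcript, `[[`, character(1), "kind")
  expect_true(all(kinds %in% c("params_digest", "broadcast")))
  # digests are hashes, never payload-sized
  lens <- vapply(tr$transcript, function(e) length(e$digest), numeric(1))
  expect_true(all(lens == 1))
  fc <- federated_correction(clients, fx$params, fed)
  kinds_c <- vapply(fc$transcript, `[[`, character(1), "kind")
  expect_true(all(kinds_c %in% c("count", "dominant_id", "mean_vector")))
})
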