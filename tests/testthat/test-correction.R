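sharing_fixture <- function() {
  # batches A, B; t_shared in both, t_alone only in B
  withr::with_seed(5, {
    expression_dataset(
      matrix(runif(30 * 12, 0, 5), nrow = 30),
      batch = c(rep("A", 10), rep("B", 20)),
      cell_type = c(rep("t_shared", 10), rep("t_shared", 12), rep("t_alone", 8)),
      layer = "log_transformed")
  })
}

test_that("sharing identification splits types by batch span", {
  ds <- sharing_fixture()
  sh <- identify_sharing(ds)
  expect_equal(sh$shared, "t_shared")
  expect_equal(sh$standalone, "t_alone")
  single <- expression_dataset(matrix(1, 4, 3), batch = rep("A", 4),
                               cell_type = c("x", "x", "y", "y"))
  sh1 <- identify_sharing(single)
  expect_length(sh1$shared, 0)
  expect_setequal(sh1$standalone, c("x", "y"))
})

test_that("dominant batch maximizes the count with lexicographic ties", {
  ds <- sharing_fixture()
  dom <- dominant_batch_for(ds, "t_shared")   # A:10, B:12
  expect_equal(dom$batch, "B")
  expect_equal(dom$count, 12)
  expect_error(dominant_batch_for(ds, "t_alone"), class = "fsb_contract")

  # tie goes to the lexicographically smaller batch
  tie <- expression_dataset(matrix(1, 10, 3),
                            batch = rep(c("B", "A"), each = 5),
                            cell_type = rep("t", 10))
  expect_equal(dominant_batch_for(tie, "t")$batch, "A")

  # brute-force check on random count tables
  withr::with_seed(31, {
    for (i in 1:25) {
      nb <- sample(2:5, 1)
      counts <- sample(1:20, nb, replace = TRUE)
      batches <- sample(LETTERS[1:10], nb)
      dsr <- expression_dataset(
        matrix(1, sum(counts), 2),
        batch = rep(batches, counts), cell_type = rep("t", sum(counts)))
      got <- dominant_batch_for(dsr, "t")
      best <- max(counts)
      expect_equal(got$count, best)
      expect_equal(got$batch, min(batches[counts == best]))
    }
  })
})

test_that("type means equal the brute-force dominant-batch latent average", {
  fx <- trained_two_batch()
  ds <- fx$ds
  means <- compute_type_means(fx$params, ds)
  sh <- identify_sharing(ds)
  expect_setequal(names(means), sh$shared)
  for (t in names(means)) {
    dom <- dominant_batch_for(ds, t)
    idx <- which(ds$cell_type == t & ds$batch == dom$batch)
    # independent re-encode and mean
    Zt <- t(vapply(idx, function(i) {
      encode(fx$params, ds$matrix[i, , drop = FALSE])[1, ]
    }, numeric(attr(fx$params, "config")$latent_dim)))
    expect_equal(means[[t]]$mean_latent, colMeans(Zt), tolerance = 1e-12)
    expect_equal(means[[t]]$dominant_batch, dom$batch)
  }
  # single-cell dominant batch: mean is that cell's latent vector
  one <- expression_dataset(
    rbind(ds$matrix[1:3, ], ds$matrix[4, , drop = FALSE]),
    batch = c("A", "A", "A", "B"),
    cell_type = rep("t", 4), layer = "log_transformed")
  m1 <- compute_type_means(fx$params, one)
  expect_equal(m1[["t"]]$dominant_batch, "A")
})

test_that("latent correction aligns per-batch type centroids exactly", {
  fx <- trained_two_batch()
  ds <- fx$ds
  Z <- encode(fx$params, ds$matrix)
  means <- compute_type_means(fx$params, ds)
  Zc <- correct_latent(Z, ds$cell_type, ds$batch, means)
  for (t in names(means)) {
    for (b in levels(ds$batch)) {
      idx <- which(ds$cell_type == t & ds$batch == b)
      if (length(idx) == 0) next
      expect_lt(max(abs(colMeans(Zc[idx, , drop = FALSE]) -
                          means[[t]]$mean_latent)), 1e-8)
    }
  }
  # idempotence: a second pass has delta = 0
  Zc2 <- correct_latent(Zc, ds$cell_type, ds$batch, means)
  expect_lt(max(abs(Zc2 - Zc)), 1e-10)
})

test_that("standalone cells are untouched and missing means are a contract error", {
  fx <- trained_two_batch()
  ds <- sharing_fixture()
  dsn <- expression_dataset(
    matrix(runif(30 * n_genes(fx$ds), 0, 5), nrow = 30),
    batch = ds$batch, cell_type = ds$cell_type, layer = "log_transformed")
  Z <- encode(fx$params, dsn$matrix)
  means <- compute_type_means(fx$params, dsn)
  Zc <- correct_latent(Z, dsn$cell_type, dsn$batch, means)
  alone <- which(dsn$cell_type == "t_alone")
  expect_identical(Zc[alone, ], Z[alone, ])
  expect_error(
    correct_latent(Z, dsn$cell_type, dsn$batch, structure(list(), class = "type_mean_map")),
    class = "fsb_contract")
})

test_that("literal mean subtraction centers types instead of aligning batches", {
  fx <- trained_two_batch()
  ds <- fx$ds
  Z <- encode(fx$params, ds$matrix)
  means <- compute_type_means(fx$params, ds)
  Zl <- correct_latent(Z, ds$cell_type, ds$batch, means,
                       literal_subtraction = TRUE)
  t1 <- names(means)[1]
  idx <- which(ds$cell_type == t1)
  expect_equal(Zl[idx, ], sweep(Z[idx, ], 2, means[[t1]]$mean_latent, "-"))
})

test_that("correction with every type in its dominant batch is the identity", {
  fx <- trained_two_batch()
  ds <- fx$ds
  dom_only <- expression_dataset(
    ds$matrix[1:50, ], batch = rep("batchA", 50),
    cell_type = ds$cell_type[1:50], layer = "log_transformed")
  # all types live in one batch -> nothing is shared -> no shifts
  Z <- encode(fx$params, dom_only$matrix)
  means <- compute_type_means(fx$params, dom_only)
  expect_length(names(means), 0)
  Zc <- correct_latent(Z, dom_only$cell_type, dom_only$batch, means)
  expect_identical(Zc, Z)
})

test_that("decoded corrected output is nonnegative and row-aligned", {
  fx <- trained_two_batch()
  ds <- fx$ds
  Z <- encode(fx$params, ds$matrix)
  means <- compute_type_means(fx$params, ds)
  Zc <- correct_latent(Z, ds$cell_type, ds$batch, means)
  out <- decode_corrected(fx$params, Zc, ds)
  expect_equal(n_cells(out), n_cells(ds))
  expect_true(all(out$matrix >= 0))
  expect_equal(out$cell_ids, ds$cell_ids)
})

test_that("the centralized pipeline runs deterministically and reduces batch separation", {
  ds <- two_batch_prepped()$ds
  cfg <- vae_config(input_dim = n_genes(ds), hidden_dims = c(32, 32),
                    latent_dim = 8, seed = 3)
  r1 <- run_centralized(ds, cfg, epochs = 6, base_seed = 9)
  r2 <- run_centralized(ds, cfg, epochs = 6, base_seed = 9)
  expect_identical(flatten_params(r1$params), flatten_params(r2$params))
  # per-type distance between batch centroids shrinks after correction
  for (t in r1$sharing$shared) {
    iA <- which(ds$cell_type == t & ds$batch == "batchA")
    iB <- which(ds$cell_type == t & ds$batch == "batchB")
    d_raw <- sqrt(sum((colMeans(r1$latent[iA, ]) - colMeans(r1$latent[iB, ]))^2))
    d_cor <- sqrt(sum((colMeans(r1$latent_corrected[iA, ]) -
                         colMeans(r1$latent_corrected[iB, ]))^2))
    expect_lt(d_cor, d_raw)
  }
})
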