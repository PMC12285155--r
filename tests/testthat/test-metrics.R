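test_that("PCA embedding orders components by variance deterministically", {
  withr::with_seed(1, {
    X <- cbind(matrix(rnorm(200 * 3, sd = c(5, 2, 0.5)), ncol = 3, byrow = TRUE),
               matrix(rnorm(200 * 4, sd = 0.1), ncol = 4))
  })
  emb <- pca_embed(X, n_components = 5)
  vars <- apply(emb, 2, var)
  expect_true(all(diff(vars) <= 1e-10))
  # duplicated rows map to identical coordinates
  X2 <- rbind(X, X[1, ])
  emb2 <- pca_embed(X2, n_components = 5)
  expect_equal(emb2[nrow(X2), ], emb2[1, ])
  expect_warning(pca_embed(matrix(rnorm(30), 10, 3), n_components = 20),
                 "rank")
})

test_that("kBET accepts a well-mixed null and rejects separated batches", {
  withr::with_seed(5, {
    emb <- matrix(rnorm(1000 * 5), ncol = 5)
    mixed_batch <- sample(c("A", "B"), 1000, replace = TRUE)
  })
  expect_gte(kbet_acceptance(emb, mixed_batch), 0.9)

  sep <- rbind(matrix(rnorm(500 * 5), ncol = 5),
               matrix(rnorm(500 * 5, mean = 50), ncol = 5))
  sep_batch <- rep(c("A", "B"), each = 500)
  expect_lte(kbet_acceptance(sep, sep_batch), 0.05)

  expect_equal(kbet_acceptance(emb, rep("only", 1000)), 1)
})

test_that("LISI hits its closed-form extremes and the mixed-cloud band", {
  # all neighbors share one label -> score 1
  blob <- make_blob_embedding(n_per = 100, n_types = 2, sep = 50, seed = 2)
  s <- lisi(blob$emb, blob$type, perplexity = 20)
  expect_lt(max(abs(s - 1)), 0.05)
  # two labels at equal weight -> score near 2: well-mixed single cloud
  withr::with_seed(3, {
    emb <- matrix(rnorm(900 * 4), ncol = 4)
    lab <- sample(c("A", "B"), 900, replace = TRUE)
  })
  m <- mean(lisi(emb, lab))
  expect_gte(m, 1.8)
  expect_lte(m, 2.0)
  expect_warning(lisi(matrix(rnorm(40), 20), rep(c("a", "b"), 10),
                      perplexity = 30), "perplexity")
})

test_that("type and batch silhouettes behave at their geometric extremes", {
  blob <- make_blob_embedding(n_per = 120, n_types = 2, sep = 40, seed = 4)
  expect_gte(asw_cell(blob$emb, blob$type), 0.9)
  # random labels on one cloud: s ~ 0 -> ASW_C ~ 0.5
  withr::with_seed(6, {
    emb <- matrix(rnorm(400 * 4), ncol = 4)
    lab <- sample(c("x", "y"), 400, replace = TRUE)
  })
  expect_lt(abs(asw_cell(emb, lab) - 0.5), 0.05)
  expect_error(asw_cell(emb, rep("x", 400)), class = "fsb_invalid")

  # batches mixed within each type -> ASW_B ~ 1
  expect_gte(asw_batch(blob$emb, blob$batch, blob$type), 0.9)
  # batches fully separated within each type -> ASW_B near 0
  sep_emb <- rbind(matrix(rnorm(100 * 3), ncol = 3),
                   matrix(rnorm(100 * 3, mean = 30), ncol = 3))
  expect_lte(asw_batch(sep_emb, rep(c("A", "B"), each = 100),
                       rep("t", 200)), 0.1)
  expect_error(asw_batch(blob$emb, blob$batch, factor(seq_len(nrow(blob$emb)))),
               class = "fsb_invalid")
})

test_that("Louvain separates distant blobs and is seed-stable", {
  blob <- make_blob_embedding(n_per = 100, n_types = 2, sep = 30, seed = 7)
  cl <- louvain_clusters(blob$emb, k = 15, resolution = 0.5, seed = 3)
  expect_length(cl, nrow(blob$emb))
  expect_equal(length(unique(cl)), 2)
  expect_identical(cl, louvain_clusters(blob$emb, k = 15, resolution = 0.5, seed = 3))
  # at any resolution, no community spans the two distant blobs
  cl1 <- louvain_clusters(blob$emb, k = 15, resolution = 1, seed = 3)
  expect_true(all(rowSums(table(cl1, blob$type) > 0) == 1))
})

test_that("ARI matches a brute-force pair-counting oracle", {
  pair_ari <- function(a, b) {
    n <- length(a)
    s_both <- 0; s_a <- 0; s_b <- 0
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s_both <- s_both + 1
      if (sa) s_a <- s_a + 1
      if (sb) s_b <- s_b + 1
    }
    tot <- choose(n, 2)
    exp_idx <- s_a * s_b / tot
    (s_both - exp_idx) / ((s_a + s_b) / 2 - exp_idx)
  }
  withr::with_seed(9, {
    for (i in 1:10) {
      a <- sample(1:3, 30, replace = TRUE)
      b <- sample(1:4, 30, replace = TRUE)
      expect_equal(mclust::adjustedRandIndex(a, b), pair_ari(a, b),
                   tolerance = 1e-12)
    }
  })
  # planted partition recovered exactly -> ARI 1
  blob <- make_blob_embedding(n_per = 80, n_types = 3, sep = 40, seed = 5)
  expect_equal(ari_score(blob$emb, blob$type), 1)
})

test_that("NMI grid search attains 1 on recoverable structure and beats a fixed resolution", {
  blob <- make_blob_embedding(n_per = 80, n_types = 3, sep = 40, seed = 8)
  nmi_max <- nmi_score(blob$emb, blob$type, resolutions = seq(0.5, 1.5, 0.5))
  expect_equal(nmi_max, 1)
  cl_fixed <- louvain_clusters(blob$emb, resolution = 1, seed = 1)
  nmi_fixed <- igraph::compare(cl_fixed,
                               as.integer(blob$type), method = "nmi")
  expect_gte(nmi_max, nmi_fixed)
})

test_that("EBM spans its closed-form extremes", {
  # fully separated batches: every neighborhood pure -> 0
  sep <- rbind(matrix(rnorm(200 * 3), ncol = 3),
               matrix(rnorm(200 * 3, mean = 100), ncol = 3))
  expect_equal(ebm_score(sep, rep(c("A", "B"), each = 200), seed = 2), 0)
  # random labels on one cloud: near-uniform neighbor batches -> >= 0.9
  withr::with_seed(10, {
    emb <- matrix(rnorm(600 * 4), ncol = 4)
    lab <- sample(c("A", "B"), 600, replace = TRUE)
  })
  expect_gte(ebm_score(emb, lab, seed = 2), 0.9)
  expect_warning(v <- ebm_score(emb, rep("A", 600), seed = 2), "single batch")
  expect_equal(v, 0)
})

test_that("ILF1 uses the harmonic mean and finds planted isolated clusters", {
  # closed form: precision 0.5, recall 1 -> 2/3
  clusters <- c(rep(1, 20), rep(2, 10))
  is_label <- c(rep(TRUE, 10), rep(FALSE, 20))
  expect_equal(fedscbatch:::best_cluster_f1(clusters, is_label), 2 / 3)

  # a pure, complete isolated cluster scores 1
  blob <- make_blob_embedding(n_per = 60, n_types = 3, sep = 40, seed = 11)
  batch <- rep("B1", nrow(blob$emb))
  batch[blob$type != "t3"] <- rep(c("B1", "B2"), length.out = sum(blob$type != "t3"))
  ilf1 <- ilf1_score(blob$emb, blob$type, batch,
                     resolutions = c(0.5, 1))
  expect_equal(ilf1, 1)

  # brute-force best-cluster scan on a small instance
  withr::with_seed(12, {
    emb40 <- matrix(rnorm(40 * 3), ncol = 3)
    types40 <- rep(c("a", "b"), each = 20)
    batches40 <- c(rep("x", 20), rep(c("x", "y"), 10))
  })
  parts <- lapply(c(0.5, 1), function(r) louvain_clusters(emb40, k = 5,
                                                          resolution = r, seed = 1))
  iso <- fedscbatch:::isolated_labels(types40, batches40)
  expect_equal(iso, "a")
  oracle <- max(vapply(parts, function(p) {
    best <- 0
    for (cl in unique(p)) {
      tp <- sum(p == cl & types40 == "a")
      if (tp == 0) next
      pr <- tp / sum(p == cl); rc <- tp / sum(types40 == "a")
      best <- max(best, 2 * pr * rc / (pr + rc))
    }
    best
  }, numeric(1)))
  expect_equal(ilf1_score(emb40, types40, batches40, k = 5,
                          resolutions = c(0.5, 1)), oracle)
})

test_that("graph connectivity counts largest components per type", {
  blob <- make_blob_embedding(n_per = 100, n_types = 2, sep = 40, seed = 13)
  expect_equal(graph_connectivity(blob$emb, blob$type), 1)
  # a type split 30/10 into far components at small k scores 0.75
  withr::with_seed(14, {
    emb <- rbind(matrix(rnorm(30 * 3), ncol = 3),
                 matrix(rnorm(10 * 3, mean = 100), ncol = 3))
  })
  expect_equal(graph_connectivity(emb, rep("t", 40), k = 5), 0.75)
  # a single-cell type scores 1
  emb1 <- rbind(emb, c(500, 500, 500))
  expect_equal(graph_connectivity(emb1, c(rep("t", 40), "solo"), k = 5),
               mean(c(0.75, 1)))
})

test_that("kNN accuracy macro-averages over cell types", {
  blob <- make_blob_embedding(n_per = 100, n_types = 2, sep = 40, seed = 15)
  expect_equal(knn_accuracy(blob$emb, blob$type), 1)
  withr::with_seed(16, {
    emb <- matrix(rnorm(500 * 4), ncol = 4)
    lab <- sample(c("x", "y"), 500, replace = TRUE)
  })
  expect_lt(abs(knn_accuracy(emb, lab) - 0.5), 0.07)
  # macro averaging: the rare type counts as much as the majority
  withr::with_seed(17, {
    maj <- matrix(rnorm(190 * 2), ncol = 2)
    rare <- matrix(rnorm(10 * 2, mean = 60), ncol = 2)
  })
  emb2 <- rbind(maj, rare)
  lab2 <- c(rep("maj", 190), rep("rare", 10))
  expect_equal(knn_accuracy(emb2, lab2, k = 5), 1)
  # merge the rare cloud into the majority: its cells go mostly wrong and
  # drag the macro mean toward 0.5 despite 5% prevalence
  emb3 <- rbind(maj, matrix(rnorm(10 * 2), ncol = 2))
  expect_lt(knn_accuracy(emb3, lab2, k = 5), 0.6)
})

test_that("performance differences subtract with antisymmetry", {
  a <- list(kbet = 0.8, nmi = 0.5)
  b <- list(kbet = 0.6, nmi = 0.5)
  expect_equal(perf_diff(a, b, "kbet"), 0.2)
  expect_equal(perf_diff(a, b, "nmi"), 0)
  expect_equal(perf_diff(a, b, "kbet"), -perf_diff(b, a, "kbet"))
  expect_error(perf_diff(a, list(x = 1), "kbet"), class = "fsb_invalid")
})

test_that("the comparison harness enters every pair into one BH correction", {
  withr::with_seed(18, {
    grid <- expand.grid(dataset = paste0("d", 1:7), metric = paste0("m", 1:8),
                        stringsAsFactors = FALSE)
    mk <- function(shift) do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      data.frame(dataset = grid$dataset[i], metric = grid$metric[i],
                 seed = 1:10,
                 value = runif(10) + ifelse(i == 1, shift, 0))
    }))
    ra <- mk(0.8); rb <- mk(0)
  })
  tab <- compare_methods(ra, rb)
  expect_equal(nrow(tab), 56)
  expect_true(all(tab$p_adjusted >= tab$p_value - 1e-12))
  # BH is monotone in raw-p rank order
  ord <- order(tab$p_value)
  expect_true(all(diff(tab$p_adjusted[ord]) >= -1e-12))
  expect_equal(tab$significant, tab$p_adjusted < 0.05)

  # identical samples on both sides: p = 1, never significant
  same <- compare_methods(ra, ra)
  expect_true(all(same$p_value == 1))
  expect_false(any(same$significant))
})

test_that("metrics are invariant to label renaming", {
  blob <- make_blob_embedding(n_per = 80, n_types = 2, sep = 15, seed = 19)
  relab_t <- factor(paste0("renamed_", blob$type))
  relab_b <- factor(chartr("AB", "ZQ", blob$batch))
  expect_equal(kbet_acceptance(blob$emb, blob$batch),
               kbet_acceptance(blob$emb, relab_b))
  expect_equal(asw_cell(blob$emb, blob$type), asw_cell(blob$emb, relab_t))
  expect_equal(asw_batch(blob$emb, blob$batch, blob$type),
               asw_batch(blob$emb, relab_b, relab_t))
  expect_equal(ebm_score(blob$emb, blob$batch, seed = 3),
               ebm_score(blob$emb, relab_b, seed = 3))
  expect_equal(knn_accuracy(blob$emb, blob$type),
               knn_accuracy(blob$emb, relab_t))
  expect_equal(mean(lisi(blob$emb, blob$batch)), mean(lisi(blob$emb, relab_b)))
})
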