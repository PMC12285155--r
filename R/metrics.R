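#' PCA embedding for metric computation
#'
#' Centered PCA keeping `n_components` components ordered by decreasing
#' variance, with a deterministic sign convention (the largest-magnitude
#' loading of each component is positive). All integration metrics are
#' computed on this embedding.
#'
#' @param X cells x genes matrix (typically corrected expression).
#' @param n_components number of principal components (default 20).
#' @return cells x d coordinate matrix (d may be less than requested when
#'   the data has lower rank, with a warning).
#' @export
pca_embed <- function(X, n_components = 20) {
  X <- as.matrix(X)
  r <- min(nrow(X) - 1, ncol(X))
  if (r < n_components) {
    warning(sprintf("rank %d < %d requested components; keeping %d",
                    r, n_components, r))
    n_components <- r
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE, rank. = n_components)
  rot <- pc$rotation
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  sweep(pc$x, 2, flip, "*")
}

knn_index <- function(emb, k) {
  FNN::get.knn(emb, k = k)$nn.index
}

#' kBET acceptance rate
#'
#' For each neighborhood size (fractions of the dataset), every cell's
#' k-nearest-neighbor batch composition is tested against the global
#' batch proportions with a Pearson chi-square test; the acceptance rate
#' is the fraction of cells with p >= `alpha`, and the median over the
#' neighborhood sizes is returned. High acceptance means local batch
#' composition is indistinguishable from global, i.e. good mixing.
#'
#' @param emb embedding matrix from [pca_embed()].
#' @param batch_labels per-cell batch labels.
#' @param k_fracs neighborhood sizes as fractions of n (default
#'   `c(0.05, 0.10, 0.15, 0.20, 0.25)`); pass a single small value (e.g.
#'   0.001) for very large data.
#' @param alpha test level (default 0.05).
#' @return Median acceptance rate in `[0, 1]`.
#' @export
kbet_acceptance <- function(emb, batch_labels,
                            k_fracs = c(0.05, 0.10, 0.15, 0.20, 0.25),
                            alpha = 0.05) {
  batch_labels <- as.factor(droplevels(as.factor(batch_labels)))
  nb <- nlevels(batch_labels)
  if (nb < 2) return(1)
  n <- nrow(emb)
  props <- as.numeric(table(batch_labels)) / n
  rates <- numeric(0)
  for (f in k_fracs) {
    k <- round(f * n)
    if (k < nb) {
      warning(sprintf("skipping k = %d (< %d batches)", k, nb))
      next
    }
    if (k > n - 1) k <- n - 1
    nn <- knn_index(emb, k)
    expected <- k * props
    codes <- as.integer(batch_labels)
    pvals <- vapply(seq_len(n), function(i) {
      obs <- tabulate(codes[nn[i, ]], nbins = nb)
      stat <- sum((obs - expected)^2 / expected)
      stats::pchisq(stat, df = nb - 1, lower.tail = FALSE)
    }, numeric(1))
    rates <- c(rates, mean(pvals >= alpha))
  }
  if (length(rates) == 0) {
    stop_fsb("no neighborhood size was usable; increase k_fracs", "fsb_invalid")
  }
  stats::median(rates)
}

# perplexity-calibrated neighbor probabilities, as in SNE-family methods:
# binary-search the Gaussian bandwidth until the entropy of the neighbor
# distribution matches log(perplexity)
calibrate_p <- function(d2, perplexity, tol = 1e-5, max_iter = 64) {
  target <- log(perplexity)
  beta <- 1
  lo <- -Inf; hi <- Inf
  for (it in seq_len(max_iter)) {
    w <- exp(-d2 * beta)
    s <- sum(w)
    if (s == 0) { beta <- beta / 2; next }
    p <- w / s
    h <- -sum(ifelse(p > 0, p * log(p), 0))
    if (abs(h - target) < tol) break
    if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
    else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
  }
  w <- exp(-d2 * beta)
  w / sum(w)
}

#' Local inverse Simpson's index (LISI)
#'
#' Per cell, neighbor weights are Gaussian with bandwidth calibrated to
#' the target perplexity; the score is `1 / sum_l p_l^2` over the
#' neighbor probability mass per label — the effective number of labels
#' in the neighborhood. With batch labels (iLISI, conventionally
#' restricted to cells of shared types) higher is better mixing; with
#' cell-type labels (cLISI) lower means better-preserved biology.
#'
#' @param emb embedding matrix.
#' @param labels per-cell labels.
#' @param perplexity target perplexity (default 30; reduced with a
#'   warning when the dataset is too small).
#' @param restrict_to optional logical/integer subset of cells to score
#'   (neighbors are also drawn from the subset).
#' @return Per-cell scores in `[1, nlevels(labels)]`.
#' @export
lisi <- function(emb, labels, perplexity = 30, restrict_to = NULL) {
  if (!is.null(restrict_to)) {
    emb <- emb[restrict_to, , drop = FALSE]
    labels <- labels[restrict_to]
  }
  labels <- droplevels(as.factor(labels))
  n <- nrow(emb)
  if (n <= 3 * perplexity) {
    perplexity <- max(2, floor((n - 1) / 3))
    warning(sprintf("too few cells; perplexity reduced to %d", perplexity))
  }
  k <- min(n - 1, 3 * perplexity)
  nn <- FNN::get.knn(emb, k = k)
  codes <- as.integer(labels)
  nb <- nlevels(labels)
  vapply(seq_len(n), function(i) {
    p <- calibrate_p(nn$nn.dist[i, ]^2, perplexity)
    pl <- vapply(seq_len(nb), function(l) sum(p[codes[nn$nn.index[i, ]] == l]),
                 numeric(1))
    1 / sum(pl^2)
  }, numeric(1))
}

#' Cell-type silhouette score (ASW_C)
#'
#' Mean silhouette width over cells using cell-type labels, mapped from
#' `[-1, 1]` to `[0, 1]` via `(s + 1) / 2`. Higher means tighter,
#' better-separated cell types.
#'
#' @param emb embedding matrix.
#' @param type_labels per-cell cell-type labels.
#' @return ASW_C in `[0, 1]`.
#' @export
asw_cell <- function(emb, type_labels) {
  type_labels <- droplevels(as.factor(type_labels))
  if (nlevels(type_labels) < 2) {
    stop_fsb("ASW_C needs at least two cell types", "fsb_invalid")
  }
  sil <- cluster::silhouette(as.integer(type_labels), stats::dist(emb))
  (mean(sil[, "sil_width"]) + 1) / 2
}

#' Batch silhouette score, reversed and cell-type stratified (ASW_B)
#'
#' Within each cell type spanning at least two batches, per-cell batch
#' silhouettes `s_i` are computed and the type's score is
#' `mean(1 - |s_i|)`; ASW_B is the mean over eligible types. 1 means
#' batches are indistinguishable within every type (perfect mixing).
#'
#' @param emb embedding matrix.
#' @param batch_labels,type_labels per-cell labels.
#' @return ASW_B in `[0, 1]`.
#' @export
asw_batch <- function(emb, batch_labels, type_labels) {
  batch_labels <- as.factor(batch_labels)
  type_labels <- droplevels(as.factor(type_labels))
  scores <- numeric(0)
  for (t in levels(type_labels)) {
    idx <- which(type_labels == t)
    b <- droplevels(batch_labels[idx])
    if (nlevels(b) < 2 || length(idx) <= nlevels(b)) next
    sil <- cluster::silhouette(as.integer(b), stats::dist(emb[idx, , drop = FALSE]))
    scores <- c(scores, mean(1 - abs(sil[, "sil_width"])))
  }
  if (length(scores) == 0) {
    stop_fsb("no cell type spans two batches; ASW_B undefined", "fsb_invalid")
  }
  mean(scores)
}

#' Louvain clustering on a kNN graph
#'
#' Builds an undirected kNN graph (union-mutualized) on the embedding
#' and partitions it with the Louvain algorithm at the given resolution.
#'
#' @param emb embedding matrix.
#' @param k neighbors per cell (default 15).
#' @param resolution Louvain resolution parameter (default 1).
#' @param seed RNG seed for the (stochastic) community search.
#' @return Integer cluster labels, one per cell.
#' @export
louvain_clusters <- function(emb, k = 15, resolution = 1, seed = 1L) {
  n <- nrow(emb)
  if (n <= k) stop_fsb("need more cells than neighbors", "fsb_invalid")
  nn <- knn_index(emb, k)
  edges <- cbind(rep(seq_len(n), each = k), as.integer(t(nn)))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  memb <- with_seed(seed, {
    igraph::membership(igraph::cluster_louvain(g, resolution = resolution))
  })
  as.integer(memb)
}

#' Adjusted Rand index between Louvain clusters and cell types
#'
#' Louvain at resolution 1 on the 15-NN graph versus the annotated cell
#' types, chance-adjusted. Negative values (worse than chance) are
#' reported as-is with a warning.
#'
#' @param emb embedding matrix.
#' @param type_labels per-cell labels.
#' @param k,resolution,seed passed to [louvain_clusters()].
#' @return ARI (1 = perfect agreement, 0 = chance).
#' @export
ari_score <- function(emb, type_labels, k = 15, resolution = 1, seed = 1L) {
  cl <- louvain_clusters(emb, k = k, resolution = resolution, seed = seed)
  v <- mclust::adjustedRandIndex(cl, as.integer(droplevels(as.factor(type_labels))))
  if (v < 0) warning(sprintf("ARI is negative (%.3f): worse than chance", v))
  v
}

#' Resolution-optimized normalized mutual information
#'
#' Louvain partitions are computed over a resolution grid and the maximal
#' NMI (arithmetic normalization, `I / ((H(U) + H(V)) / 2)`) against the
#' cell-type labels is returned.
#'
#' @param emb embedding matrix.
#' @param type_labels per-cell labels.
#' @param k neighbors for the graph.
#' @param resolutions resolution grid (default 0.1 to 2 in steps of 0.1).
#' @param seed RNG seed.
#' @return Maximal NMI over the grid, in `[0, 1]`.
#' @export
nmi_score <- function(emb, type_labels, k = 15,
                      resolutions = seq(0.1, 2, by = 0.1), seed = 1L) {
  truth <- as.integer(droplevels(as.factor(type_labels)))
  max(vapply(resolutions, function(r) {
    cl <- louvain_clusters(emb, k = k, resolution = r, seed = seed)
    igraph::compare(cl, truth, method = "nmi")
  }, numeric(1)))
}

shannon_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Entropy of batch mixing (EBM)
#'
#' For pools of randomly sampled cells, the Shannon entropy of batch
#' labels among each cell's 15 nearest neighbors is averaged within the
#' pool, across pools, and normalized by `log(n_batches)`; 1 is uniform
#' mixing, 0 pure batch neighborhoods.
#'
#' @param emb embedding matrix.
#' @param batch_labels per-cell batch labels.
#' @param k neighbors (default 15).
#' @param n_cells_per_pool sampled cells per pool (default 100).
#' @param n_pools number of pools (default 50).
#' @param seed sampling seed.
#' @return EBM in `[0, 1]`.
#' @export
ebm_score <- function(emb, batch_labels, k = 15, n_cells_per_pool = 100,
                      n_pools = 50, seed = 1L) {
  batch_labels <- droplevels(as.factor(batch_labels))
  nb <- nlevels(batch_labels)
  if (nb < 2) {
    warning("single batch: EBM is 0 by convention")
    return(0)
  }
  n <- nrow(emb)
  if (n <= k) stop_fsb("need more cells than neighbors", "fsb_invalid")
  nn <- knn_index(emb, k)
  codes <- as.integer(batch_labels)
  cell_entropy <- vapply(seq_len(n), function(i) {
    shannon_entropy(tabulate(codes[nn[i, ]], nbins = nb))
  }, numeric(1))
  pool_means <- with_seed(seed, {
    vapply(seq_len(n_pools), function(p) {
      mean(cell_entropy[sample.int(n, min(n_cells_per_pool, n))])
    }, numeric(1))
  })
  mean(pool_means) / log(nb)
}

# labels present in the fewest batches; none when every type spans the
# same (maximal) number of batches
isolated_labels <- function(type_labels, batch_labels) {
  tab <- table(as.character(type_labels), as.character(batch_labels))
  spans <- rowSums(tab > 0)
  if (length(spans) == 0) return(character(0))
  if (min(spans) == max(spans)) return(character(0))
  names(spans)[spans == min(spans)]
}

best_cluster_f1 <- function(clusters, is_label) {
  best <- 0
  for (cl in unique(clusters)) {
    in_cl <- clusters == cl
    tp <- sum(in_cl & is_label)
    if (tp == 0) next
    precision <- tp / sum(in_cl)
    recall <- tp / sum(is_label)
    f1 <- 2 * precision * recall / (precision + recall)
    best <- max(best, f1)
  }
  best
}

#' Isolated-label F1 (ILF1)
#'
#' For each isolated label (cell types present in the fewest batches),
#' Louvain partitions across the resolution grid are scanned for the
#' cluster maximizing the F1 score (harmonic mean of precision and
#' recall) of cluster-vs-label membership; ILF1 is the mean of those best
#' F1 values across isolated labels.
#'
#' @param emb embedding matrix.
#' @param type_labels,batch_labels per-cell labels.
#' @param k neighbors for the graph.
#' @param resolutions resolution grid.
#' @param seed RNG seed.
#' @return ILF1 in `[0, 1]`.
#' @export
ilf1_score <- function(emb, type_labels, batch_labels, k = 15,
                       resolutions = seq(0.1, 2, by = 0.1), seed = 1L) {
  iso <- isolated_labels(type_labels, batch_labels)
  if (length(iso) == 0) {
    stop_fsb("no isolated labels (all cell types span the same batches)",
             "fsb_invalid")
  }
  partitions <- lapply(resolutions, function(r) {
    louvain_clusters(emb, k = k, resolution = r, seed = seed)
  })
  f1s <- vapply(iso, function(lab) {
    is_lab <- as.character(type_labels) == lab
    max(vapply(partitions, best_cluster_f1, numeric(1), is_label = is_lab))
  }, numeric(1))
  mean(f1s)
}

#' Graph connectivity (GC)
#'
#' Per cell type, a kNN graph is built among that type's cells only and
#' the fraction of them in the largest connected component is recorded;
#' GC is the mean over types. 1 means every type forms one connected
#' neighborhood structure.
#'
#' @param emb embedding matrix.
#' @param type_labels per-cell labels.
#' @param k neighbors (default 15, reduced per type when a type is small).
#' @return GC in `[0, 1]`.
#' @export
graph_connectivity <- function(emb, type_labels, k = 15) {
  type_labels <- droplevels(as.factor(type_labels))
  scores <- vapply(levels(type_labels), function(t) {
    idx <- which(type_labels == t)
    nt <- length(idx)
    if (nt == 1) return(1)
    kt <- min(k, nt - 1)
    nn <- knn_index(emb[idx, , drop = FALSE], kt)
    edges <- cbind(rep(seq_len(nt), each = kt), as.integer(t(nn)))
    g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
    max(igraph::components(g)$csize) / nt
  }, numeric(1))
  mean(scores)
}

#' kNN label accuracy (KNN Acc)
#'
#' Per cell, the fraction of its k nearest neighbors sharing its
#' cell-type label; averaged within each type and then across types
#' (macro average), so rare types weigh equally.
#'
#' @param emb embedding matrix.
#' @param type_labels per-cell labels.
#' @param k neighbors (default 15).
#' @return KNN accuracy in `[0, 1]`.
#' @export
knn_accuracy <- function(emb, type_labels, k = 15) {
  type_labels <- droplevels(as.factor(type_labels))
  n <- nrow(emb)
  if (n <= k) stop_fsb("need more cells than neighbors", "fsb_invalid")
  nn <- knn_index(emb, k)
  codes <- as.integer(type_labels)
  frac <- vapply(seq_len(n), function(i) mean(codes[nn[i, ]] == codes[i]),
                 numeric(1))
  mean(vapply(seq_len(nlevels(type_labels)), function(l) {
    mean(frac[codes == l])
  }, numeric(1)))
}

#' Run the full metric suite on an embedding
#'
#' @param emb embedding from [pca_embed()].
#' @param batch_labels,type_labels per-cell labels.
#' @param shared_types types used to restrict iLISI (default: types
#'   spanning >= 2 batches).
#' @param seed seed for the stochastic metrics (Louvain, EBM pools).
#' @param kbet_fracs passed to [kbet_acceptance()].
#' @return Named list of metric values (`kbet`, `ilisi_mean`,
#'   `clisi_mean`, `asw_b`, `asw_c`, `ari`, `nmi`, `ebm`, `ilf1`
#'   (NA when no isolated label exists), `gc`, `knn_acc`).
#' @export
evaluate_embedding <- function(emb, batch_labels, type_labels,
                               shared_types = NULL, seed = 1L,
                               kbet_fracs = c(0.05, 0.10, 0.15, 0.20, 0.25)) {
  if (is.null(shared_types)) {
    tab <- table(as.character(type_labels), as.character(batch_labels))
    shared_types <- rownames(tab)[rowSums(tab > 0) >= 2]
  }
  in_shared <- as.character(type_labels) %in% shared_types
  ilf1 <- tryCatch(
    ilf1_score(emb, type_labels, batch_labels, seed = seed),
    fedscbatch_error = function(e) NA_real_)
  list(
    kbet = kbet_acceptance(emb, batch_labels, k_fracs = kbet_fracs),
    ilisi_mean = mean(lisi(emb, batch_labels, restrict_to = which(in_shared))),
    clisi_mean = mean(lisi(emb, type_labels)),
    asw_b = asw_batch(emb, batch_labels, type_labels),
    asw_c = asw_cell(emb, type_labels),
    ari = ari_score(emb, type_labels, seed = seed),
    nmi = nmi_score(emb, type_labels, seed = seed),
    ebm = ebm_score(emb, batch_labels, seed = seed),
    ilf1 = ilf1,
    gc = graph_connectivity(emb, type_labels),
    knn_acc = knn_accuracy(emb, type_labels)
  )
}

#' Performance difference between two methods on one metric
#'
#' `delta = value_a - value_b`; for metrics on `[0, 1]` this lies in
#' `[-1, 1]`, positive when method a is better on a higher-is-better
#' metric.
#'
#' @param a,b named lists or single values; when named lists, `metric`
#'   selects the entry and the names must match.
#' @param metric metric name when `a`/`b` are result lists.
#' @return The difference.
#' @export
perf_diff <- function(a, b, metric = NULL) {
  if (!is.null(metric)) {
    if (!(metric %in% names(a)) || !(metric %in% names(b))) {
      stop_fsb(sprintf("metric '%s' missing from one side", metric), "fsb_invalid")
    }
    a <- a[[metric]]; b <- b[[metric]]
  }
  a - b
}

#' Compare two methods across metrics and datasets
#'
#' For every (metric, dataset) pair, a two-sided Wilcoxon-Mann-Whitney
#' test compares the per-seed values of the two methods; all raw p-values
#' enter one joint Benjamini-Hochberg correction, and pairs with adjusted
#' p below `alpha` are flagged significant. The per-pair performance
#' difference is the difference of per-seed means.
#'
#' @param results_a,results_b data.frames with columns `dataset`,
#'   `metric`, `seed`, `value` (>= 2 seeds per pair on each side).
#' @param alpha significance level (default 0.05).
#' @return data.frame (dataset, metric, delta, p_value, p_adjusted,
#'   significant), one row per pair.
#' @export
compare_methods <- function(results_a, results_b, alpha = 0.05) {
  need <- c("dataset", "metric", "seed", "value")
  stopifnot(all(need %in% names(results_a)), all(need %in% names(results_b)))
  key_a <- unique(results_a[c("dataset", "metric")])
  key_b <- unique(results_b[c("dataset", "metric")])
  if (!identical(key_a[order(key_a$dataset, key_a$metric), ],
                 key_b[order(key_b$dataset, key_b$metric), ])) {
    a_k <- paste(key_a$dataset, key_a$metric)
    b_k <- paste(key_b$dataset, key_b$metric)
    if (!setequal(a_k, b_k)) {
      stop_fsb("the two result sets cover different (metric, dataset) pairs",
               "fsb_invalid")
    }
  }
  keys <- key_a[order(key_a$dataset, key_a$metric), , drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    d <- keys$dataset[i]; m <- keys$metric[i]
    va <- results_a$value[results_a$dataset == d & results_a$metric == m]
    vb <- results_b$value[results_b$dataset == d & results_b$metric == m]
    if (length(va) < 2 || length(vb) < 2) {
      stop_fsb("each (metric, dataset) pair needs >= 2 seeds per side",
               "fsb_invalid")
    }
    p <- suppressWarnings(stats::wilcox.test(va, vb, exact = FALSE)$p.value)
    if (is.nan(p)) p <- 1  # identical constant samples carry no evidence
    data.frame(dataset = d, metric = m, delta = mean(va) - mean(vb),
               p_value = p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_adjusted < alpha
  out
}
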