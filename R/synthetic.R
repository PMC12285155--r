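#' Configure a multi-batch scRNA-seq simulation
#'
#' The generator draws counts per cell from a negative binomial whose mean
#' is the product of a cell-type expression program, a gene-wise
#' multiplicative batch factor (log-normal with scale `sigma_batch`), and a
#' log-normal per-cell library-size factor, followed by constant-probability
#' dropout zeroing. Composition is a batches x types matrix of cell counts,
#' which is how dominant, minority and standalone structure is encoded.
#'
#' @param n_genes number of genes.
#' @param composition integer matrix (batches x cell types, dimnames used
#'   as labels) of cell counts per (batch, type); zero means the type is
#'   absent from that batch.
#' @param sigma_batch per-batch log-normal sd of the gene-wise batch
#'   factor; scalar or one value per batch. 0 disables batch effects.
#' @param library_sdlog sd(log) of the per-cell library-size factor.
#' @param dropout_rate probability of zeroing any count (technical dropout).
#' @param base_mean median expression scale of the type programs.
#' @param base_sdlog sd(log) of the gene baseline abundances; the default
#'   1.5 gives the heavy-tailed abundance profile of real scRNA-seq, where
#'   a few genes carry most of the library and most genes sit well below
#'   the mean after total-count normalization.
#' @param de_prob fraction of genes differentially expressed per type
#'   (marker genes defining the type program).
#' @param de_lfc log2 fold change of marker genes.
#' @param dispersion_range gene-level NB dispersion range, drawn
#'   log-uniformly.
#' @param seed RNG seed; the generator is deterministic given the config.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_genes = 1200,
                       composition,
                       sigma_batch = 0,
                       library_sdlog = 0.3,
                       dropout_rate = 0.1,
                       base_mean = 2,
                       base_sdlog = 1.5,
                       de_prob = 0.2,
                       de_lfc = 2,
                       dispersion_range = c(0.1, 1),
                       seed = 1) {
  composition <- as.matrix(composition)
  if (any(composition < 0) || any(composition != round(composition))) {
    stop_fsb("composition must be nonnegative integers", "fsb_invalid")
  }
  if (sum(composition) == 0) stop_fsb("composition is empty", "fsb_empty")
  if (is.null(rownames(composition))) {
    rownames(composition) <- paste0("batch", seq_len(nrow(composition)))
  }
  if (is.null(colnames(composition))) {
    colnames(composition) <- paste0("type", seq_len(ncol(composition)))
  }
  sigma_batch <- rep_len(sigma_batch, nrow(composition))
  if (any(sigma_batch < 0)) stop_fsb("sigma_batch must be >= 0", "fsb_invalid")
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop_fsb("dropout_rate must be in [0, 1)", "fsb_invalid")
  }
  structure(list(
    n_genes = n_genes, composition = composition, sigma_batch = sigma_batch,
    library_sdlog = library_sdlog, dropout_rate = dropout_rate,
    base_mean = base_mean, base_sdlog = base_sdlog,
    de_prob = de_prob, de_lfc = de_lfc,
    dispersion_range = dispersion_range, seed = seed
  ), class = "sim_config")
}

#' Generate a synthetic multi-batch scRNA-seq dataset
#'
#' @param config a [sim_config()].
#' @return A list with `dataset` (an `expression_dataset` of raw counts)
#'   and `truth` (ground truth: per-cell batch/type, the type programs,
#'   the injected gene-wise batch factors, library factors, dispersions).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  comp <- config$composition
  G <- config$n_genes
  batches <- rownames(comp)
  types <- colnames(comp)
  with_seed(config$seed, {
    # gene-level baseline and dispersion
    base <- stats::rlnorm(G, meanlog = log(config$base_mean),
                          sdlog = config$base_sdlog)
    disp <- exp(stats::runif(G, log(config$dispersion_range[1]),
                             log(config$dispersion_range[2])))
    # type programs: baseline with a marker subset shifted up/down
    programs <- matrix(rep(base, each = length(types)),
                       nrow = length(types), ncol = G,
                       dimnames = list(types, NULL))
    for (t in seq_along(types)) {
      de <- which(stats::runif(G) < config$de_prob)
      fc <- 2^(sample(c(-1, 1), length(de), replace = TRUE) * config$de_lfc)
      programs[t, de] <- programs[t, de] * fc
    }
    # gene-wise multiplicative batch factors
    bf <- matrix(1, nrow = length(batches), ncol = G,
                 dimnames = list(batches, NULL))
    for (b in seq_along(batches)) {
      if (config$sigma_batch[b] > 0) {
        bf[b, ] <- exp(stats::rnorm(G, 0, config$sigma_batch[b]))
      }
    }
    n_total <- sum(comp)
    cell_batch <- character(n_total)
    cell_type <- character(n_total)
    pos <- 0
    for (b in seq_along(batches)) for (t in seq_along(types)) {
      k <- comp[b, t]
      if (k > 0) {
        cell_batch[pos + seq_len(k)] <- batches[b]
        cell_type[pos + seq_len(k)] <- types[t]
        pos <- pos + k
      }
    }
    lib <- stats::rlnorm(n_total, 0, config$library_sdlog)
    counts <- matrix(0, nrow = n_total, ncol = G)
    for (i in seq_len(n_total)) {
      mu <- programs[cell_type[i], ] * bf[cell_batch[i], ] * lib[i]
      counts[i, ] <- stats::rnbinom(G, size = 1 / disp, mu = mu)
    }
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(n_total * G) < config$dropout_rate,
                     nrow = n_total)
      counts[drop] <- 0
    }
    ds <- expression_dataset(
      counts, batch = cell_batch, cell_type = cell_type,
      gene_ids = paste0("g", seq_len(G)),
      cell_ids = paste0("cell", seq_len(n_total)),
      layer = "raw_counts")
    list(dataset = ds,
         truth = list(batch = cell_batch, cell_type = cell_type,
                      programs = programs, batch_factors = bf,
                      library_factors = lib, dispersion = disp))
  })
}

#' Named simulation presets
#'
#' Ready-made study designs: `two_batch_shared` (2 batches x 4 shared
#' types, strong batch effect), `five_batch_hp_like` (5 batches, shared
#' types with different dominant batches, mimicking a multi-protocol
#' pancreas-style design), `standalone_type` (one type confined to one
#' batch), `minority_types` (types under the minority threshold), and
#' `held_out` (a batch tagged for exclusion from training).
#'
#' @param name preset name.
#' @param seed RNG seed stored in the config.
#' @return A `sim_config`; for `held_out` the config carries a
#'   `held_out_batch` attribute naming the excluded batch.
#' @export
sim_preset <- function(name = c("two_batch_shared", "five_batch_hp_like",
                                "standalone_type", "minority_types",
                                "held_out"),
                       seed = 1) {
  name <- match.arg(name)
  cfg <- switch(name,
    two_batch_shared = {
      comp <- matrix(c(160, 120, 140, 80,
                       120, 160, 100, 120), nrow = 2, byrow = TRUE,
                     dimnames = list(c("batchA", "batchB"),
                                     c("alpha", "beta", "gamma", "delta")))
      sim_config(composition = comp, sigma_batch = 1.0,
                 seed = seed)
    },
    five_batch_hp_like = {
      types <- c("alpha", "beta", "gamma", "delta", "ductal", "acinar")
      comp <- matrix(c(
        80, 40, 20, 10, 30, 20,
        40, 80, 30, 20, 10, 10,
        20, 30, 80, 40, 20, 10,
        10, 20, 40, 80, 10, 30,
        30, 10, 10, 20, 80, 40), nrow = 5, byrow = TRUE,
        dimnames = list(paste0("study", 1:5), types))
      sim_config(composition = comp, sigma_batch = 0.8,
                 seed = seed)
    },
    standalone_type = {
      comp <- matrix(c(100, 80, 60,
                       80, 100, 0), nrow = 2, byrow = TRUE,
                     dimnames = list(c("batchA", "batchB"),
                                     c("shared1", "shared2", "lonely")))
      sim_config(composition = comp, sigma_batch = 0.8,
                 seed = seed)
    },
    minority_types = {
      comp <- matrix(c(120, 100, 4, 3,
                       100, 120, 3, 0), nrow = 2, byrow = TRUE,
                     dimnames = list(c("batchA", "batchB"),
                                     c("major1", "major2", "rare1", "rare2")))
      sim_config(composition = comp, sigma_batch = 0.8,
                 seed = seed)
    },
    held_out = {
      comp <- matrix(c(80, 60, 40,
                       60, 80, 40,
                       40, 40, 100), nrow = 3, byrow = TRUE,
                     dimnames = list(c("batchA", "batchB", "newstudy"),
                                     c("alpha", "beta", "gamma")))
      sim_config(composition = comp, sigma_batch = 0.8,
                 seed = seed)
    })
  if (name == "held_out") attr(cfg, "held_out_batch") <- "newstudy"
  cfg
}
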