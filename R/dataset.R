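#' Expression dataset container
#'
#' A lightweight container for a cells-by-genes expression matrix with
#' per-cell batch and cell-type annotations. The `layer` field tracks where
#' the matrix sits in the preprocessing pipeline (`raw_counts` ->
#' `normalized` -> `log_transformed`), and every preprocessing step checks
#' it so steps cannot be applied out of order.
#'
#' @param matrix numeric cells x genes matrix, finite and non-negative.
#' @param batch per-cell batch labels (coerced to factor).
#' @param cell_type per-cell cell-type labels (coerced to factor).
#' @param gene_ids unique gene identifiers; defaults to colnames or g1..gG.
#' @param cell_ids cell identifiers; defaults to rownames or c1..cN.
#' @param layer one of `"raw_counts"`, `"normalized"`, `"log_transformed"`.
#' @return An `expression_dataset` object.
#' @export
expression_dataset <- function(matrix, batch, cell_type,
                               gene_ids = NULL, cell_ids = NULL,
                               layer = c("raw_counts", "normalized",
                                         "log_transformed")) {
  layer <- match.arg(layer)
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  n <- nrow(matrix)
  if (length(batch) != n || length(cell_type) != n) {
    stop_fsb(sprintf(
      "batch (%d) and cell_type (%d) must match n_cells (%d)",
      length(batch), length(cell_type), n), "fsb_invalid")
  }
  if (n > 0 && ncol(matrix) > 0) {
    if (any(!is.finite(matrix))) stop_fsb("matrix has non-finite entries", "fsb_invalid")
    if (any(matrix < 0)) stop_fsb("matrix has negative entries", "fsb_invalid")
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(matrix)
    if (is.null(gene_ids)) gene_ids <- paste0("g", seq_len(ncol(matrix)))
  }
  if (anyDuplicated(gene_ids)) stop_fsb("gene_ids must be unique", "fsb_invalid")
  if (is.null(cell_ids)) {
    cell_ids <- rownames(matrix)
    if (is.null(cell_ids)) cell_ids <- paste0("c", seq_len(n))
  }
  dimnames(matrix) <- NULL
  structure(list(
    matrix = matrix,
    batch = factor(batch),
    cell_type = factor(cell_type),
    gene_ids = as.character(gene_ids),
    cell_ids = as.character(cell_ids),
    layer = layer
  ), class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "expression_dataset: %d cells x %d genes [%s]\n  batches: %s\n  cell types: %s\n",
    n_cells(x), n_genes(x), x$layer,
    paste(levels(droplevels(x$batch)), collapse = ", "),
    paste(levels(droplevels(x$cell_type)), collapse = ", ")))
  invisible(x)
}

#' Number of cells / genes in a dataset
#' @param ds an `expression_dataset`.
#' @return integer count.
#' @export
n_cells <- function(ds) nrow(ds$matrix)

#' @rdname n_cells
#' @export
n_genes <- function(ds) ncol(ds$matrix)

# subset cells (i) and/or genes (j), keeping labels in lockstep
subset_dataset <- function(ds, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(n_cells(ds))
  if (is.null(j)) j <- seq_len(n_genes(ds))
  expression_dataset(
    ds$matrix[i, j, drop = FALSE],
    droplevels(ds$batch[i]),
    droplevels(ds$cell_type[i]),
    gene_ids = ds$gene_ids[j],
    cell_ids = ds$cell_ids[i],
    layer = ds$layer
  )
}

require_layer <- function(ds, layer, op) {
  if (ds$layer != layer) {
    stop_fsb(sprintf("%s requires layer '%s' but dataset is '%s'",
                     op, layer, ds$layer), "fsb_state")
  }
}

#' Remove cells with low gene coverage
#'
#' Drops cells expressing fewer than `min_genes` genes, the usual guard
#' against empty droplets. A gene counts as expressed when its entry is
#' strictly positive; cells with exactly `min_genes` expressed genes are
#' kept.
#'
#' @param ds an `expression_dataset` holding raw counts.
#' @param min_genes minimum number of expressed genes per cell (default 200).
#' @return Filtered `expression_dataset`.
#' @export
filter_low_coverage <- function(ds, min_genes = 200) {
  require_layer(ds, "raw_counts", "filter_low_coverage")
  keep <- rowSums(ds$matrix > 0) >= min_genes
  subset_dataset(ds, i = which(keep))
}

#' Scale every cell to the same total count
#'
#' Each cell's row is rescaled so it sums to `target_sum`; all-zero cells
#' are left untouched. Moves the dataset's layer to `normalized`.
#'
#' @param ds an `expression_dataset` holding raw counts.
#' @param target_sum desired per-cell total (default 10000).
#' @return Normalized `expression_dataset`.
#' @export
normalize_total <- function(ds, target_sum = 10000) {
  require_layer(ds, "raw_counts", "normalize_total")
  if (target_sum <= 0) stop_fsb("target_sum must be > 0", "fsb_invalid")
  rs <- rowSums(ds$matrix)
  scale <- ifelse(rs > 0, target_sum / rs, 0)
  out <- ds
  out$matrix <- ds$matrix * scale
  out$layer <- "normalized"
  out
}

# Seurat-flavor normalized dispersion: per-gene variance/mean on the
# normalized layer, z-scored within `n_bins` equal-frequency mean bins.
normalized_dispersion <- function(m, n_bins = 20) {
  mu <- colMeans(m)
  v <- apply(m, 2, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  n_bins <- max(1, min(n_bins, length(unique(mu))))
  breaks <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- cut(mu, breaks = breaks, include.lowest = TRUE)
  out <- disp
  for (b in levels(bins)) {
    idx <- which(bins == b)
    m_b <- mean(disp[idx])
    s_b <- stats::sd(disp[idx])
    if (length(idx) == 1 || !is.finite(s_b) || s_b == 0) {
      # a lone or constant bin carries no spread information; its genes
      # sit at the bin centre
      out[idx] <- 0
    } else {
      out[idx] <- (disp[idx] - m_b) / s_b
    }
  }
  list(mean = mu, dispersion = disp, dispersion_norm = out)
}

#' Select highly variable genes
#'
#' Keeps genes whose mean (on the normalized layer) lies strictly inside
#' `(min_mean, max_mean)` and whose normalized dispersion exceeds
#' `min_disp`. Dispersion is variance/mean z-scored within 20
#' equal-frequency mean bins.
#'
#' @param ds a normalized `expression_dataset`.
#' @param min_mean,max_mean open bounds on gene mean expression.
#' @param min_disp strict lower bound on normalized dispersion.
#' @param n_bins number of equal-frequency mean bins for the z-score.
#' @return `expression_dataset` restricted to the selected genes, in the
#'   original gene order.
#' @export
select_hvg <- function(ds, min_mean = 0.0125, max_mean = 2.5,
                       min_disp = 0.7, n_bins = 20) {
  require_layer(ds, "normalized", "select_hvg")
  st <- normalized_dispersion(ds$matrix, n_bins = n_bins)
  keep <- st$mean > min_mean & st$mean < max_mean & st$dispersion_norm > min_disp
  if (!any(keep)) {
    stop_fsb("no genes pass the variability thresholds; relax min_mean/max_mean/min_disp",
             "fsb_empty")
  }
  subset_dataset(ds, j = which(keep))
}

#' Capped log1p transform
#'
#' Applies `x -> min(log(1 + x), cap)` entrywise to stabilize variance,
#' and moves the layer to `log_transformed`.
#'
#' @param ds a normalized `expression_dataset`.
#' @param cap upper cap on the transformed values (default 10).
#' @return Log-transformed `expression_dataset`.
#' @export
log1p_cap <- function(ds, cap = 10) {
  require_layer(ds, "normalized", "log1p_cap")
  if (n_cells(ds) > 0 && any(ds$matrix < 0)) {
    stop_fsb("negative entries cannot be log-transformed", "fsb_state")
  }
  out <- ds
  out$matrix <- pmin(log1p(ds$matrix), cap)
  out$layer <- "log_transformed"
  out
}

#' Run the full preprocessing pipeline
#'
#' coverage filter -> total-count normalization -> highly-variable-gene
#' selection -> capped log transform, in that fixed order.
#'
#' @inheritParams filter_low_coverage
#' @inheritParams normalize_total
#' @inheritParams select_hvg
#' @inheritParams log1p_cap
#' @return A `log_transformed` `expression_dataset` on the HVG subset.
#' @export
preprocess <- function(ds, min_genes = 200, target_sum = 10000,
                       min_mean = 0.0125, max_mean = 2.5, min_disp = 0.7,
                       cap = 10) {
  ds |>
    filter_low_coverage(min_genes = min_genes) |>
    normalize_total(target_sum = target_sum) |>
    select_hvg(min_mean = min_mean, max_mean = max_mean, min_disp = min_disp) |>
    log1p_cap(cap = cap)
}

#' Split a dataset into one client per batch
#'
#' The cross-silo partition: each batch becomes one client holding only
#' its own cells. Concatenating the partitions reconstitutes the dataset
#' up to cell order.
#'
#' @param ds an `expression_dataset` with at least one batch.
#' @return A list of clients, each a list with `client_id` (integer),
#'   `batch` (the batch label), `dataset`, `n_cells`, and `type_counts`
#'   (named integer vector over cell types present).
#' @export
partition_by_batch <- function(ds) {
  if (n_cells(ds) == 0) stop_fsb("cannot partition an empty dataset", "fsb_empty")
  batches <- levels(droplevels(ds$batch))
  lapply(seq_along(batches), function(i) {
    idx <- which(ds$batch == batches[i])
    sub <- subset_dataset(ds, i = idx)
    tc <- table(sub$cell_type)
    list(
      client_id = i,
      batch = batches[i],
      dataset = sub,
      n_cells = length(idx),
      type_counts = stats::setNames(as.integer(tc), names(tc))
    )
  })
}

#' Per-client summary table
#'
#' @param clients result of [partition_by_batch()].
#' @return data.frame with one row per (client, cell type) giving counts;
#'   suitable for CSV export.
#' @export
client_summary <- function(clients) {
  do.call(rbind, lapply(clients, function(cl) {
    data.frame(client_id = cl$client_id, batch = cl$batch,
               n_cells = cl$n_cells,
               cell_type = names(cl$type_counts),
               count = unname(cl$type_counts),
               row.names = NULL)
  }))
}

#' Define a cell-type inclusion scenario
#'
#' @param mode `"All"` (keep everything), `"Combined"` (relabel minority
#'   and standalone types to `combined_label`), or `"Dropped"` (remove
#'   their cells).
#' @param minority_threshold a cell type with fewer than this many cells
#'   in the whole dataset counts as a minority type (default 10).
#' @param combined_label replacement label for `"Combined"` mode.
#' @return An `inclusion_scenario` object.
#' @export
inclusion_scenario <- function(mode = c("All", "Combined", "Dropped"),
                               minority_threshold = 10,
                               combined_label = "others") {
  mode <- match.arg(mode)
  if (minority_threshold < 0) stop_fsb("minority_threshold must be >= 0", "fsb_invalid")
  structure(list(mode = mode, minority_threshold = minority_threshold,
                 combined_label = combined_label),
            class = "inclusion_scenario")
}

# minority = global count < threshold; standalone = present in one batch only
flagged_types <- function(ds, scenario) {
  counts <- table(ds$cell_type)
  minority <- names(counts)[counts < scenario$minority_threshold & counts > 0]
  standalone <- identify_sharing(ds)$standalone
  union(minority, standalone)
}

#' Apply a cell-type inclusion scenario
#'
#' Minority cell types (global count below the scenario threshold) and
#' standalone types (present in a single batch) are either kept as-is
#' (`All`), relabelled to a common label (`Combined`, cell counts
#' unchanged), or removed (`Dropped`, batch sizes may shrink).
#'
#' @param ds an `expression_dataset`.
#' @param scenario an [inclusion_scenario()].
#' @return The transformed `expression_dataset`.
#' @export
apply_inclusion_scenario <- function(ds, scenario) {
  stopifnot(inherits(scenario, "inclusion_scenario"))
  if (scenario$mode == "All") return(ds)
  flagged <- flagged_types(ds, scenario)
  if (length(flagged) == 0) return(ds)
  if (scenario$mode == "Combined") {
    ct <- as.character(ds$cell_type)
    ct[ct %in% flagged] <- scenario$combined_label
    out <- ds
    out$cell_type <- factor(ct)
    return(out)
  }
  keep <- which(!(as.character(ds$cell_type) %in% flagged))
  subset_dataset(ds, i = keep)
}

#' Concatenate datasets by rows (cells)
#'
#' Inverse of [partition_by_batch()]: all inputs must share the same gene
#' panel and layer.
#'
#' @param ds_list list of `expression_dataset` objects.
#' @return A single `expression_dataset`.
#' @export
concat_datasets <- function(ds_list) {
  stopifnot(length(ds_list) >= 1)
  g <- ds_list[[1]]$gene_ids
  lay <- ds_list[[1]]$layer
  for (d in ds_list) {
    if (!identical(d$gene_ids, g)) stop_fsb("gene panels differ", "fsb_invalid")
    if (!identical(d$layer, lay)) stop_fsb("layers differ", "fsb_invalid")
  }
  expression_dataset(
    do.call(rbind, lapply(ds_list, function(d) d$matrix)),
    unlist(lapply(ds_list, function(d) as.character(d$batch))),
    unlist(lapply(ds_list, function(d) as.character(d$cell_type))),
    gene_ids = g,
    cell_ids = unlist(lapply(ds_list, function(d) d$cell_ids)),
    layer = lay
  )
}
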