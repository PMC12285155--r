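# AnnData-compatible h5ad I/O built on rhdf5. Files written here carry
# the AnnData >= 0.8 encoding attributes (dataframe / categorical /
# array) so they open in python anndata; the reader additionally accepts
# CSR/CSC-encoded X and plain string annotation columns as produced by
# scanpy exports.

h5_set_attrs <- function(path, obj, attrs) {
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  oid <- rhdf5::H5Oopen(fid, obj)
  on.exit(rhdf5::H5Oclose(oid), add = TRUE)
  for (nm in names(attrs)) {
    # column-order must stay an array attribute even at length 1
    scalar <- length(attrs[[nm]]) == 1 && nm != "column-order"
    rhdf5::h5writeAttribute(attrs[[nm]], oid, nm,
                            variableLengthString = TRUE, asScalar = scalar)
  }
}

write_categorical <- function(path, group, values) {
  f <- as.factor(values)
  rhdf5::h5createGroup(path, group)
  rhdf5::h5write(levels(f), path, paste0(group, "/categories"),
                 variableLengthString = TRUE)
  rhdf5::h5write(as.integer(f) - 1L, path, paste0(group, "/codes"))
  h5_set_attrs(path, group, list(`encoding-type` = "categorical",
                                 `encoding-version` = "0.2.0",
                                 ordered = 0L))  # rhdf5 lacks logical attrs; 0 reads as False
  h5_set_attrs(path, paste0(group, "/categories"),
               list(`encoding-type` = "string-array", `encoding-version` = "0.2.0"))
  h5_set_attrs(path, paste0(group, "/codes"),
               list(`encoding-type` = "array", `encoding-version` = "0.2.0"))
}

write_string_array <- function(path, name, values) {
  rhdf5::h5write(as.character(values), path, name, variableLengthString = TRUE)
  h5_set_attrs(path, name, list(`encoding-type` = "string-array",
                                `encoding-version` = "0.2.0"))
}

#' Write an expression dataset to h5ad
#'
#' Produces an AnnData-compatible file: dense `X` of shape
#' (cells, genes), `obs` with the batch and cell-type annotations as
#' categoricals, `var` with the gene index, and the pipeline layer tag
#' under `uns/layer_tag`.
#'
#' @param ds an `expression_dataset`.
#' @param path output file path (overwritten).
#' @param batch_col,type_col column names used for the annotations.
#' @return `path`, invisibly.
#' @export
write_h5ad <- function(ds, path, batch_col = "batch", type_col = "cell_type") {
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  # R matrix (genes x cells) so the file's C-order shape is (cells, genes)
  rhdf5::h5write(t(ds$matrix), path, "X")
  h5_set_attrs(path, "X", list(`encoding-type` = "array",
                               `encoding-version` = "0.2.0"))
  rhdf5::h5createGroup(path, "obs")
  write_string_array(path, "obs/_index", ds$cell_ids)
  write_categorical(path, paste0("obs/", batch_col), ds$batch)
  write_categorical(path, paste0("obs/", type_col), ds$cell_type)
  h5_set_attrs(path, "obs", list(`encoding-type` = "dataframe",
                                 `encoding-version` = "0.2.0",
                                 `_index` = "_index",
                                 `column-order` = c(batch_col, type_col)))
  rhdf5::h5createGroup(path, "var")
  write_string_array(path, "var/_index", ds$gene_ids)
  h5_set_attrs(path, "var", list(`encoding-type` = "dataframe",
                                 `encoding-version` = "0.2.0",
                                 `_index` = "_index",
                                 `column-order` = "_placeholder"))
  # anndata requires column-order entries to exist as columns
  write_string_array(path, "var/_placeholder", rep("", length(ds$gene_ids)))
  rhdf5::h5createGroup(path, "uns")
  rhdf5::h5write(ds$layer, path, "uns/layer_tag", variableLengthString = TRUE)
  h5_set_attrs(path, "uns", list(`encoding-type` = "dict",
                                 `encoding-version` = "0.1.0"))
  h5_set_attrs(path, "uns/layer_tag",
               list(`encoding-type` = "string", `encoding-version` = "0.2.0"))
  h5_set_attrs(path, "/", list(`encoding-type` = "anndata",
                               `encoding-version` = "0.1.0"))
  invisible(path)
}

read_obs_column <- function(path, contents, col) {
  grp <- paste0("obs/", col)
  hit <- contents$name == col & dirname(contents$full_name) == "/obs"
  if (!any(hit)) {
    stop_fsb(sprintf("h5ad file lacks the annotation column '%s' in obs", col),
             "fsb_config")
  }
  raw <- rhdf5::h5read(path, grp)
  if (is.list(raw) && all(c("categories", "codes") %in% names(raw))) {
    cats <- as.character(raw$categories)
    codes <- as.integer(raw$codes)
    vals <- rep(NA_character_, length(codes))
    vals[codes >= 0] <- cats[codes[codes >= 0] + 1L]
    vals
  } else {
    as.character(raw)
  }
}

read_x_matrix <- function(path) {
  info <- rhdf5::h5ls(path)
  xrow <- info[info$name == "X" & info$group == "/", , drop = FALSE]
  if (nrow(xrow) == 0) stop_fsb("h5ad file has no X", "fsb_config")
  if (xrow$otype == "H5I_GROUP") {
    # sparse encoding
    attrs <- rhdf5::h5readAttributes(path, "X")
    shape <- as.integer(attrs$shape)  # (n_obs, n_var)
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    enc <- attrs[["encoding-type"]]
    m <- matrix(0, nrow = shape[1], ncol = shape[2])
    if (identical(enc, "csr_matrix")) {
      for (i in seq_len(shape[1])) {
        rng <- if (indptr[i + 1] > indptr[i]) (indptr[i] + 1):indptr[i + 1] else integer(0)
        m[i, indices[rng] + 1L] <- data[rng]
      }
    } else if (identical(enc, "csc_matrix")) {
      for (j in seq_len(shape[2])) {
        rng <- if (indptr[j + 1] > indptr[j]) (indptr[j] + 1):indptr[j + 1] else integer(0)
        m[indices[rng] + 1L, j] <- data[rng]
      }
    } else {
      stop_fsb(sprintf("unsupported X encoding '%s'", enc), "fsb_config")
    }
    m
  } else {
    a <- rhdf5::h5read(path, "X")
    # file shape (n_obs, n_var) in C order arrives as an R matrix
    # (n_var, n_obs); transpose back
    t(as.matrix(a))
  }
}

infer_layer <- function(m, cap = 10) {
  if (length(m) == 0) return("raw_counts")
  if (all(m == round(m))) return("raw_counts")
  if (max(m) <= cap + 1e-9) "log_transformed" else "normalized"
}

#' Read an h5ad file into an expression dataset
#'
#' Accepts dense or CSR/CSC-encoded `X` and categorical or plain-string
#' annotation columns. The pipeline layer is taken from `uns/layer_tag`
#' when present, otherwise inferred (integral entries: raw counts;
#' otherwise log-transformed when bounded by the cap, else normalized).
#'
#' @param path h5ad file.
#' @param batch_col,type_col names of the obs columns holding batch and
#'   cell-type annotations.
#' @return An `expression_dataset`.
#' @export
read_h5ad <- function(path, batch_col = "batch", type_col = "cell_type") {
  if (!file.exists(path)) stop_fsb(sprintf("file not found: %s", path), "fsb_config")
  on.exit(rhdf5::h5closeAll(), add = TRUE)
  contents <- rhdf5::h5ls(path)
  contents$full_name <- file.path(contents$group, contents$name)
  m <- read_x_matrix(path)
  batch <- read_obs_column(path, contents, batch_col)
  ctype <- read_obs_column(path, contents, type_col)
  cell_ids <- if (any(contents$full_name == "/obs/_index")) {
    as.character(rhdf5::h5read(path, "obs/_index"))
  } else paste0("c", seq_len(nrow(m)))
  gene_ids <- if (any(contents$full_name == "/var/_index")) {
    as.character(rhdf5::h5read(path, "var/_index"))
  } else paste0("g", seq_len(ncol(m)))
  layer <- if (any(contents$full_name == "/uns/layer_tag")) {
    as.character(rhdf5::h5read(path, "uns/layer_tag"))
  } else infer_layer(m)
  expression_dataset(m, batch = batch, cell_type = ctype,
                     gene_ids = gene_ids, cell_ids = cell_ids, layer = layer)
}
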