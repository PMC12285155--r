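#' Fixed-point encoding for the secret-sharing ring
#'
#' Values are encoded as `round(x * 2^fractional_bits)` in two's
#' complement over the ring `Z_{2^64}`, so the encode/decode round trip
#' is exact to `2^-fractional_bits`.
#'
#' @param fractional_bits number of fractional bits (default 16).
#' @return A `fixed_point` object.
#' @export
fixed_point <- function(fractional_bits = 16) {
  stopifnot(fractional_bits >= 1, fractional_bits <= 32)
  structure(list(fractional_bits = as.integer(fractional_bits),
                 ring_bits = 64L),
            class = "fixed_point")
}

#' Split a tensor into additive secret shares
#'
#' All but one share are uniform ring elements from a seeded generator;
#' the final share is the encoded value minus their modular sum, so any
#' proper subset of shares is statistically independent of the plaintext.
#'
#' @param x numeric vector or matrix.
#' @param n_parties number of computational parties (>= 2, default 3).
#' @param encoding a [fixed_point()] encoding.
#' @param seed seed of the share-masking generator.
#' @return An `additive_shares` object.
#' @export
share_tensor <- function(x, n_parties = 3, encoding = fixed_point(),
                         seed = 1L) {
  if (n_parties < 2) stop_fsb("n_parties must be >= 2", "fsb_invalid")
  v <- as.numeric(x)
  packed <- .fsb_fp_encode(v, encoding$fractional_bits)
  shares <- .fsb_share_encoded(packed, n_parties, as.numeric(seed))
  structure(list(party_shares = shares, n = length(v), dim = dim(x),
                 encoding = encoding),
            class = "additive_shares")
}

#' Reconstruct the plaintext from additive shares
#'
#' Modular sum of all party shares followed by fixed-point decoding.
#'
#' @param shares an `additive_shares` object.
#' @return Numeric vector/matrix equal to the plaintext within
#'   `2^-fractional_bits` per element.
#' @export
reconstruct_tensor <- function(shares) {
  stopifnot(inherits(shares, "additive_shares"))
  acc <- shares$party_shares[[1]]
  for (p in seq_along(shares$party_shares)[-1]) {
    acc <- .fsb_ring_add(acc, shares$party_shares[[p]])
  }
  out <- .fsb_fp_decode(acc, shares$encoding$fractional_bits)
  if (!is.null(shares$dim)) dim(out) <- shares$dim
  out
}

#' Add two sharings elementwise (additive homomorphism)
#'
#' @param a,b `additive_shares` over the same encoding and shape.
#' @return An `additive_shares` of the summed plaintexts.
#' @export
add_shares <- function(a, b) {
  stopifnot(inherits(a, "additive_shares"), inherits(b, "additive_shares"))
  if (a$n != b$n ||
      a$encoding$fractional_bits != b$encoding$fractional_bits ||
      length(a$party_shares) != length(b$party_shares)) {
    stop_fsb("share encodings or shapes do not match", "fsb_invalid")
  }
  out <- a
  out$party_shares <- lapply(seq_along(a$party_shares), function(p) {
    .fsb_ring_add(a$party_shares[[p]], b$party_shares[[p]])
  })
  out
}

transcript_entry <- function(from, to, kind, digest = NA_character_) {
  list(from = from, to = to, kind = kind, digest = digest)
}

#' Secure sample-size-weighted parameter aggregation
#'
#' Each client secret-shares its weighted tensor `w_c * theta_c` and its
#' weight `w_c`; each party adds the shares it holds across clients; the
#' coordinator reconstructs only the two share-sums and divides. No
#' single party or the coordinator ever sees a client's plaintext tensor.
#'
#' @param client_tensors list of numeric vectors/matrices of one shape.
#' @param client_weights positive weights (cell counts).
#' @param n_parties number of computational parties.
#' @param encoding a [fixed_point()].
#' @param seed masking seed.
#' @return `list(value, transcript)`: the aggregate (matching plaintext
#'   weighted averaging within fixed-point tolerance) and the protocol
#'   transcript (share digests only).
#' @export
secure_weighted_sum <- function(client_tensors, client_weights,
                                n_parties = 3, encoding = fixed_point(),
                                seed = 1L) {
  stopifnot(length(client_tensors) == length(client_weights))
  if (any(client_weights <= 0)) stop_fsb("weights must be positive", "fsb_invalid")
  transcript <- list()
  sum_wt <- NULL
  sum_w <- NULL
  for (c in seq_along(client_tensors)) {
    wt <- client_tensors[[c]] * client_weights[c]
    s_wt <- share_tensor(wt, n_parties, encoding, seed = mix_seed(seed, c, 1L))
    s_w <- share_tensor(client_weights[c], n_parties, encoding,
                        seed = mix_seed(seed, c, 2L))
    for (p in seq_len(n_parties)) {
      transcript[[length(transcript) + 1]] <- transcript_entry(
        from = paste0("client", c), to = paste0("party", p), kind = "share",
        digest = tensor_digest(s_wt$party_shares[[p]]))
    }
    sum_wt <- if (is.null(sum_wt)) s_wt else add_shares(sum_wt, s_wt)
    sum_w <- if (is.null(sum_w)) s_w else add_shares(sum_w, s_w)
  }
  for (p in seq_len(n_parties)) {
    transcript[[length(transcript) + 1]] <- transcript_entry(
      from = paste0("party", p), to = "coordinator", kind = "share_sum",
      digest = tensor_digest(sum_wt$party_shares[[p]]))
  }
  total_wt <- reconstruct_tensor(sum_wt)
  total_w <- reconstruct_tensor(sum_w)
  value <- total_wt / total_w
  dim(value) <- dim(client_tensors[[1]])
  transcript[[length(transcript) + 1]] <- transcript_entry(
    from = "coordinator", to = "coordinator", kind = "aggregate",
    digest = tensor_digest(value))
  list(value = value, transcript = transcript)
}

#' Secure dominant-client detection (argmax over secret counts)
#'
#' Per-client counts are secret-shared; the parties evaluate pairwise
#' differences in share space and reveal only their signs, hence the
#' pairwise ordering, never the counts themselves. Ties go to the
#' smallest client id.
#'
#' @param counts named (or positional) nonnegative integer vector, one
#'   count per client.
#' @param n_parties number of computational parties.
#' @param seed masking seed.
#' @return `list(winner, transcript)` where `winner` is the client name
#'   (or index as character).
#' @export
secure_argmax <- function(counts, n_parties = 3, seed = 1L) {
  if (length(counts) < 1 || all(counts == 0)) {
    stop_fsb("secure_argmax needs at least one positive count", "fsb_contract")
  }
  ids <- names(counts)
  if (is.null(ids)) ids <- as.character(seq_along(counts))
  enc <- fixed_point()
  sh <- lapply(seq_along(counts), function(c) {
    share_tensor(counts[c], n_parties, enc, seed = mix_seed(seed, c))
  })
  transcript <- list()
  for (c in seq_along(counts)) for (p in seq_len(n_parties)) {
    transcript[[length(transcript) + 1]] <- transcript_entry(
      from = paste0("client", ids[c]), to = paste0("party", p),
      kind = "count_share", digest = tensor_digest(sh[[c]]$party_shares[[p]]))
  }
  n <- length(counts)
  beats <- matrix(TRUE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    diff <- sh[[i]]
    diff$party_shares <- lapply(seq_len(n_parties), function(p) {
      .fsb_ring_add(sh[[i]]$party_shares[[p]],
                    .fsb_ring_neg(sh[[j]]$party_shares[[p]]))
    })
    acc <- diff$party_shares[[1]]
    for (p in seq_len(n_parties)[-1]) acc <- .fsb_ring_add(acc, diff$party_shares[[p]])
    sgn <- .fsb_ring_sign(acc)
    transcript[[length(transcript) + 1]] <- transcript_entry(
      from = "parties", to = "coordinator", kind = "sign_bit",
      digest = as.character(sgn))
    beats[i, j] <- sgn > 0 || (sgn == 0 && i < j)
  }
  winner <- which(apply(beats, 1, all))[1]
  transcript[[length(transcript) + 1]] <- transcript_entry(
    from = "coordinator", to = "all", kind = "argmax_id", digest = ids[winner])
  list(winner = ids[winner], transcript = transcript)
}
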