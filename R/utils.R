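# Internal helpers shared across modules: seed derivation, digests,
# and a tiny condition constructor.

#' @useDynLib fedscbatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

stop_fsb <- function(msg, class) {
  stop(structure(
    class = c(class, "fedscbatch_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Derive a child seed from a base seed and one or more stream indices
#'
#' A splitmix-style integer mixer used everywhere randomness must be
#' reproducible per (seed, client, round/epoch) stream. Keeps results in
#' the positive 31-bit range accepted by [set.seed()].
#'
#' @param seed base integer seed.
#' @param ... additional integer stream indices (client id, round, epoch...).
#' @return A single integer in `[0, 2^31 - 1]`.
#' @export
mix_seed <- function(seed, ...) {
  idx <- c(seed, ...)
  h <- 0
  for (v in idx) {
    v <- as.numeric(v) %% 2147483647
    # 64-bit-safe LCG mixing done in doubles below 2^53
    h <- (h * 48271 + v * 16807 + 12345) %% 2147483647
    h <- (h * 69621) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' SHA-256 digest of a numeric object
#'
#' Used for parameter audit trails in federated round logs and manifests.
#'
#' @param x numeric vector, matrix, or a list of them (flattened in order).
#' @return Hex digest string.
#' @export
tensor_digest <- function(x) {
  v <- unlist(x, use.names = FALSE)
  d <- openssl::sha256(serialize(as.numeric(v), NULL, version = 2))
  paste(unclass(as.character(d)))
}

# round-half-away-from-zero, matching the fixed-point C++ encoder
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)
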