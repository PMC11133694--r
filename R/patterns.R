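#' Pattern index encoding
#'
#' Activity patterns of `N` binary networks are vectors in \{-1, +1\}^N.
#' Each pattern maps to an integer index in `[0, 2^N)`: bit `b` of the index
#' is 1 exactly when network `b + 1` is active (+1), so network 1 is the
#' least-significant bit. This convention is fixed package-wide; pattern
#' indices written to files or stored in landscape tables all use it.
#'
#' @param sigma numeric vector of -1/+1 values (length `N`), or an
#'   `N x T` matrix whose columns are patterns.
#' @return For a vector, a single integer index; for a matrix, an integer
#'   vector of length `T`.
#' @examples
#' pattern_encode(c(-1, -1, -1))        # 0
#' pattern_encode(c(1, -1, -1))         # 1 (network 1 = LSB)
#' pattern_decode(5, n_networks = 3)    # c(1, -1, 1)
#' @export
pattern_encode <- function(sigma) {
  if (is.matrix(sigma)) {
    if (!all(sigma == 1 | sigma == -1)) {
      stop("pattern entries must be -1 or +1", call. = FALSE)
    }
    n <- nrow(sigma)
    as.integer(colSums((sigma + 1) / 2 * 2^(seq_len(n) - 1)))
  } else {
    if (!all(sigma == 1 | sigma == -1)) {
      stop("pattern entries must be -1 or +1", call. = FALSE)
    }
    as.integer(sum(2^(which(sigma == 1) - 1)))
  }
}

#' @rdname pattern_encode
#' @param k integer pattern index (scalar or vector) in `[0, 2^N)`.
#' @param n_networks number of networks `N`.
#' @export
pattern_decode <- function(k, n_networks) {
  if (any(k < 0) || any(k >= 2^n_networks)) {
    stop("pattern index out of range [0, 2^N)", call. = FALSE)
  }
  bits <- vapply(seq_len(n_networks),
                 function(b) bitwAnd(as.integer(k), as.integer(2^(b - 1))) > 0,
                 logical(length(k)))
  if (length(k) == 1L) {
    as.numeric(ifelse(bits, 1, -1))
  } else {
    # rows = patterns, cols = networks
    matrix(ifelse(bits, 1, -1), nrow = length(k))
  }
}

#' Enumerate all activity patterns
#'
#' @param n_networks number of networks `N` (capped at 20; 2^N rows).
#' @return A `2^N x N` matrix of -1/+1; row `k + 1` is the pattern with
#'   index `k`.
#' @export
all_patterns <- function(n_networks) {
  if (n_networks > 20) {
    stop("2^N pattern enumeration capped at N = 20", call. = FALSE)
  }
  k <- 0:(2^n_networks - 1)
  pattern_decode(k, n_networks)
}

#' Single-flip neighbors of a pattern
#'
#' Two patterns are adjacent when they differ in exactly one network, so
#' each pattern has `N` neighbors on the hypercube.
#'
#' @param k pattern index in `[0, 2^N)`.
#' @param n_networks number of networks `N`.
#' @return Integer vector of the `N` neighboring pattern indices.
#' @export
pattern_neighbors <- function(k, n_networks) {
  if (any(k < 0) || any(k >= 2^n_networks)) {
    stop("pattern index out of range [0, 2^N)", call. = FALSE)
  }
  bitwXor(as.integer(k), as.integer(2^(seq_len(n_networks) - 1)))
}

# 2^N x N matrix; row k+1 holds the neighbor indices of pattern k (0-based).
neighbor_table <- function(n_networks) {
  k <- 0:(2^n_networks - 1)
  flips <- as.integer(2^(seq_len(n_networks) - 1))
  vapply(flips, function(f) bitwXor(k, f), integer(length(k)))
}

# Run code with a temporary RNG state seeded by `seed`; the caller's RNG
# stream is untouched. seed = NULL runs with the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}
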