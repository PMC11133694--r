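#' Concatenate per-subject network time series
#'
#' Stacks the subjects of one group side by side into the group data matrix
#' `Z` (`N x S*T`), subject-major with within-subject time order preserved.
#' Subject boundaries are carried along so later run-based statistics never
#' span two subjects.
#'
#' @param cohort list of `N x T` numeric matrices, one per subject; all
#'   must share the same dimensions.
#' @return An `N x (S*T)` matrix with attributes `n_subjects` and
#'   `t_per_subject`.
#' @export
concatenate_subjects <- function(cohort) {
  if (!is.list(cohort)) cohort <- list(cohort)
  dims <- vapply(cohort, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all subjects must share the same N x T dimensions", call. = FALSE)
  }
  if (dims[1, 1] < 2) stop("at least 2 networks required", call. = FALSE)
  Z <- do.call(cbind, cohort)
  attr(Z, "n_subjects") <- length(cohort)
  attr(Z, "t_per_subject") <- dims[2, 1]
  Z
}

#' Binarize a group data matrix at the network means
#'
#' Each network (row) of the concatenated matrix `Z` is thresholded at its
#' own mean `m_i` over all of the group's time points: entries strictly
#' above the mean become +1 (active), all others -1 (inactive); a value
#' exactly at the mean maps to -1. Thresholds are group-level, computed on
#' the concatenation, not per subject.
#'
#' @param Z an `N x (S*T)` matrix from [concatenate_subjects], or any
#'   finite `N x T` matrix (treated as one subject).
#' @return A `binary_pattern_data` object: `values` (array
#'   `N x T x S` of -1/+1), `pattern_index` (`T x S` integer matrix of
#'   codes in `[0, 2^N)`, network 1 = least-significant bit), `thresholds`
#'   (length-`N` means), `n_networks`, `n_time`, `n_subjects`.
#' @export
binarize_by_mean <- function(Z) {
  Z <- as.matrix(Z)
  if (!all(is.finite(Z))) stop("Z contains non-finite entries", call. = FALSE)
  S <- attr(Z, "n_subjects") %||% 1L
  Tn <- attr(Z, "t_per_subject") %||% ncol(Z)
  m <- rowMeans(Z)
  V <- ifelse(Z > m, 1, -1)
  k <- pattern_encode(V)
  structure(list(values = array(V, dim = c(nrow(Z), Tn, S)),
                 pattern_index = matrix(as.integer(k), nrow = Tn, ncol = S),
                 thresholds = m,
                 n_networks = nrow(Z), n_time = Tn, n_subjects = S),
            class = "binary_pattern_data")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.binary_pattern_data <- function(x, ...) {
  cat("Binarized activity patterns:", x$n_subjects, "subject(s) x",
      x$n_networks, "networks x", x$n_time, "time points\n")
  invisible(x)
}

#' Build binarized pattern data from pattern indices
#'
#' Constructs a `binary_pattern_data` object directly from a `T x S`
#' matrix (or length-`T` vector) of pattern indices, decoding the -1/+1
#' values under the package's bit order. Useful for working with
#' generator output or simulated trajectories without a binarization step;
#' `thresholds` are `NA` since no continuous data were thresholded.
#'
#' @param k integer matrix (`T x S`) or vector of pattern indices in
#'   `[0, 2^N)`.
#' @param n_networks number of networks `N`.
#' @return A `binary_pattern_data` object (see [binarize_by_mean]).
#' @export
binary_pattern_from_indices <- function(k, n_networks) {
  k <- as.matrix(k)
  kk <- as.integer(k)
  V <- if (length(kk) == 1L) {
    matrix(pattern_decode(kk, n_networks), ncol = 1)
  } else {
    t(pattern_decode(kk, n_networks))  # N x (T*S)
  }
  structure(list(values = array(V, dim = c(n_networks, nrow(k), ncol(k))),
                 pattern_index = matrix(as.integer(k), nrow = nrow(k)),
                 thresholds = rep(NA_real_, n_networks),
                 n_networks = n_networks, n_time = nrow(k),
                 n_subjects = ncol(k)),
            class = "binary_pattern_data")
}
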