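#' Pairwise maximum-entropy model parameters
#'
#' The pairwise maximum-entropy model (MEM) over N binary networks assigns
#' each activity pattern `sigma` the statistical energy
#' `E(sigma) = -sum_i h_i sigma_i - 1/2 sum_{i != j} J_ij sigma_i sigma_j`,
#' where `h_i` is the activation tendency (baseline activity) of network i
#' and `J_ij` the pairwise interaction between networks i and j. Pattern
#' probabilities follow the Boltzmann distribution
#' `P(sigma) = exp(-E(sigma)) / Z`.
#'
#' @param h numeric vector of baseline activities (length `N`).
#' @param J `N x N` symmetric numeric matrix of couplings with zero diagonal.
#' @return An object of class `mem_params`.
#' @export
mem_params <- function(h, J) {
  h <- as.numeric(h)
  J <- as.matrix(J)
  n <- length(h)
  if (!all(dim(J) == c(n, n))) {
    stop("J must be an N x N matrix matching length(h)", call. = FALSE)
  }
  if (!all(is.finite(h)) || !all(is.finite(J))) {
    stop("h and J must be finite", call. = FALSE)
  }
  if (max(abs(J - t(J))) > 1e-10) {
    stop("J must be symmetric", call. = FALSE)
  }
  if (any(diag(J) != 0)) {
    stop("diag(J) must be zero (no self-coupling)", call. = FALSE)
  }
  structure(list(h = h, J = (J + t(J)) / 2, n_networks = n),
            class = "mem_params")
}

#' @export
print.mem_params <- function(x, ...) {
  cat("Pairwise maximum-entropy model:", x$n_networks, "networks\n")
  cat("  h range: [", signif(min(x$h), 3), ",", signif(max(x$h), 3), "]\n")
  off <- x$J[upper.tri(x$J)]
  cat("  J off-diagonal range: [", signif(min(off), 3), ",",
      signif(max(off), 3), "]\n")
  invisible(x)
}

#' Energy of an activity pattern
#'
#' @param params a [mem_params] object.
#' @param sigma a -1/+1 vector of length `N`, or a matrix with patterns in
#'   rows (`n_patterns x N`).
#' @return Numeric energy (vector if `sigma` is a matrix). Each unordered
#'   network pair contributes once after the 1/2 factor.
#' @export
pattern_energy <- function(params, sigma) {
  stopifnot(inherits(params, "mem_params"))
  if (is.matrix(sigma)) {
    if (ncol(sigma) != params$n_networks) {
      stop("pattern length does not match the number of networks",
           call. = FALSE)
    }
    as.numeric(-sigma %*% params$h -
                 0.5 * rowSums((sigma %*% params$J) * sigma))
  } else {
    if (length(sigma) != params$n_networks) {
      stop("pattern length does not match the number of networks",
           call. = FALSE)
    }
    -sum(params$h * sigma) - 0.5 * sum(params$J * outer(sigma, sigma))
  }
}

#' Enumerate the Boltzmann distribution of a pairwise MEM
#'
#' Computes `E(V_k)` for all `2^N` activity patterns and the normalized
#' probabilities `P(V_k) = exp(-E) / sum exp(-E)`. The softmax uses a
#' max-shift so large energy ranges cannot overflow; adding a constant to
#' every energy leaves the probabilities unchanged.
#'
#' @param params a [mem_params] object; `N <= 20` (enumeration of `2^N`).
#' @return A `landscape` object: list with `energies`, `probabilities`
#'   (both length `2^N`, ordered by pattern index), `n_networks`, `params`.
#' @export
boltzmann_distribution <- function(params) {
  stopifnot(inherits(params, "mem_params"))
  n <- params$n_networks
  if (n > 20) stop("N above the 2^N enumeration cap (20)", call. = FALSE)
  S <- all_patterns(n)
  e <- pattern_energy(params, S)
  w <- exp(-(e - min(e)))
  structure(list(energies = e, probabilities = w / sum(w),
                 n_networks = n, params = params),
            class = "landscape")
}

#' Build a landscape table from explicit energies
#'
#' Mostly useful for constructing toy landscapes in examples and tests.
#'
#' @param energies numeric vector of length `2^N`.
#' @return A `landscape` object (see [boltzmann_distribution]).
#' @export
landscape_from_energies <- function(energies) {
  n <- log2(length(energies))
  if (n != round(n)) stop("length(energies) must be a power of 2",
                          call. = FALSE)
  w <- exp(-(energies - min(energies)))
  structure(list(energies = as.numeric(energies),
                 probabilities = w / sum(w),
                 n_networks = as.integer(n), params = NULL),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat("Energy landscape over", 2^x$n_networks, "patterns (",
      x$n_networks, "networks )\n")
  cat("  energy range: [", signif(min(x$energies), 4), ",",
      signif(max(x$energies), 4), "]\n")
  invisible(x)
}

#' Empirical first and second moments of binarized activity
#'
#' Averages over all concatenated time points of a group: mean network
#' activity `<sigma_i>` and mean pairwise product `<sigma_i sigma_j>`.
#'
#' @param data a `binary_pattern_data` object (see [binarize_by_mean]) or
#'   an `N x T` matrix of -1/+1 columns.
#' @return A `moment_set` list: `mean_activity` (length N), `pairwise`
#'   (`N x N`, diagonal 1), `source = "empirical"`.
#' @export
empirical_moments <- function(data) {
  M <- if (inherits(data, "binary_pattern_data")) {
    matrix(data$values, nrow = data$n_networks)
  } else {
    as.matrix(data)
  }
  if (length(M) == 0) stop("empty data", call. = FALSE)
  if (!all(M == 1 | M == -1)) {
    stop("data must be binarized to -1/+1", call. = FALSE)
  }
  structure(list(mean_activity = rowMeans(M),
                 pairwise = tcrossprod(M) / ncol(M),
                 source = "empirical"),
            class = "moment_set")
}

#' Model moments of an enumerated Boltzmann distribution
#'
#' Exact expectations `<sigma_i>_m` and `<sigma_i sigma_j>_m` under `P(V_k)`.
#'
#' @param table a `landscape` object.
#' @return A `moment_set` with `source = "model"`.
#' @export
model_moments <- function(table) {
  stopifnot(inherits(table, "landscape"))
  S <- all_patterns(table$n_networks)
  p <- table$probabilities
  structure(list(mean_activity = as.numeric(crossprod(S, p)),
                 pairwise = crossprod(S, p * S),
                 source = "model"),
            class = "moment_set")
}

#' Closed-form fit of the independent (J = 0) MEM
#'
#' With no couplings the networks are independent and
#' `h_i = atanh(<sigma_i>)` reproduces the empirical means exactly. Means
#' at exactly +/-1 are clamped to `1 - 1e-9` in magnitude (with a warning)
#' so the field stays finite.
#'
#' @param mean_activity numeric vector of empirical means in `[-1, 1]`.
#' @return A [mem_params] object with `J = 0`.
#' @export
fit_independent_mem <- function(mean_activity) {
  m <- as.numeric(mean_activity)
  if (any(abs(m) >= 1)) {
    warning("mean activity at +/-1 clamped to magnitude 1 - 1e-9")
    m <- pmin(pmax(m, -1 + 1e-9), 1 - 1e-9)
  }
  n <- length(m)
  mem_params(atanh(m), matrix(0, n, n))
}

#' Fit the pairwise MEM by gradient ascent on the likelihood
#'
#' Iterates `h_i <- h_i + lr (<sigma_i> - <sigma_i>_m)` and
#' `J_ij <- J_ij + lr (<sigma_i sigma_j> - <sigma_i sigma_j>_m)`, with the
#' model moments recomputed exactly by enumeration at every step; this is
#' maximum-likelihood gradient ascent, whose fixed point matches the
#' empirical moments. Starts from the independent closed form (`J = 0`).
#'
#' @param empirical a `moment_set` from [empirical_moments], or a
#'   `binary_pattern_data` object (moments are computed first).
#' @param learning_rate initial step size (default 0.1); halved whenever
#'   the moment gap increases (overshoot), never increased.
#' @param tol convergence threshold on the maximum absolute moment gap
#'   (default 1e-5).
#' @param max_iter iteration cap (default 5e4).
#' @param adapt_lr halve the step size whenever the gap grows (default
#'   `TRUE`); with `FALSE` a too-large fixed step can oscillate, and a gap
#'   that grows tenfold between 100-iteration checkpoints raises a
#'   convergence error naming the learning rate.
#' @return List with `params` ([mem_params]) and `diagnostics`
#'   (`iterations`, `converged`, `max_moment_gap`, final `learning_rate`).
#' @export
fit_pairwise_mem <- function(empirical, learning_rate = 0.1, tol = 1e-5,
                             max_iter = 5e4, adapt_lr = TRUE) {
  if (inherits(empirical, "binary_pattern_data")) {
    empirical <- empirical_moments(empirical)
  }
  stopifnot(inherits(empirical, "moment_set"))
  if (learning_rate <= 0 || tol <= 0) {
    stop("learning_rate and tol must be positive", call. = FALSE)
  }
  m_emp <- empirical$mean_activity
  C_emp <- empirical$pairwise
  n <- length(m_emp)
  S <- all_patterns(n)
  offdiag <- upper.tri(C_emp) | lower.tri(C_emp)

  start <- fit_independent_mem(m_emp)
  h <- start$h
  J <- start$J
  lr <- learning_rate

  gap <- Inf
  gap_prev <- Inf
  gap_best <- Inf  # smallest gap seen, baseline for divergence detection
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    e <- -as.numeric(S %*% h) - 0.5 * rowSums((S %*% J) * S)
    w <- exp(-(e - min(e)))
    p <- w / sum(w)
    m_mod <- as.numeric(crossprod(S, p))
    C_mod <- crossprod(S, p * S)
    dh <- m_emp - m_mod
    dJ <- (C_emp - C_mod) * offdiag
    gap <- max(abs(dh), abs(dJ))
    if (!is.finite(gap)) {
      stop(sprintf("gradient ascent diverged (non-finite moment gap); reduce learning_rate = %g",
                   lr), call. = FALSE)
    }
    if (gap < tol) break
    gap_best <- min(gap_best, gap)
    if (iter %% 100L == 0L && gap > 10 * gap_best) {
      stop(sprintf(
        "gradient ascent diverging (moment gap grew 10x over 100 iterations); reduce learning_rate = %g",
        lr), call. = FALSE)
    }
    if (adapt_lr && gap > gap_prev) lr <- lr / 2  # overshoot: damp the step
    gap_prev <- gap
    h <- h + lr * dh
    J <- J + lr * dJ
  }
  list(params = mem_params(h, J),
       diagnostics = list(iterations = iter, converged = gap < tol,
                          max_moment_gap = gap, learning_rate = lr))
}

#' Empirical pattern-index frequency distribution
#'
#' @param data a `binary_pattern_data` object.
#' @return Numeric vector of length `2^N`; entry `k + 1` is the fraction of
#'   time points with pattern index `k`. Sums to 1.
#' @export
empirical_pattern_frequencies <- function(data) {
  stopifnot(inherits(data, "binary_pattern_data"))
  k <- as.integer(data$pattern_index)
  tabulate(k + 1L, nbins = 2^data$n_networks) / length(k)
}

#' Goodness of fit of the pairwise MEM
#'
#' `D1` is the Kullback-Leibler divergence (base-2 logarithms, in bits)
#' from the empirical pattern distribution to the independent model
#' (`J = 0`); `D2` is the divergence to the pairwise model. The accuracy
#' `R = (D1 - D2) / D1` is 1 when the pairwise model reproduces the
#' empirical distribution exactly and 0 when the couplings add nothing
#' over the independent model. Patterns with zero empirical frequency
#' contribute 0 to both sums (`0 log 0 = 0`).
#'
#' @param empirical_freq length-`2^N` frequency vector summing to 1 (see
#'   [empirical_pattern_frequencies]).
#' @param independent `landscape` of the independent model.
#' @param pairwise `landscape` of the fitted pairwise model.
#' @return List of class `fit_accuracy`: `R`, `D1`, `D2`, `pearson_r`
#'   (correlation between pairwise-model probabilities and empirical
#'   frequencies over all `2^N` patterns).
#' @export
fit_accuracy <- function(empirical_freq, independent, pairwise) {
  stopifnot(inherits(independent, "landscape"),
            inherits(pairwise, "landscape"))
  f <- as.numeric(empirical_freq)
  if (abs(sum(f) - 1) > 1e-8) {
    stop("empirical frequencies must sum to 1", call. = FALSE)
  }
  kl2 <- function(f, q) {
    nz <- f > 0
    sum(f[nz] * log2(f[nz] / q[nz]))
  }
  D1 <- kl2(f, independent$probabilities)
  D2 <- kl2(f, pairwise$probabilities)
  R <- if (D1 > 0) (D1 - D2) / D1 else {
    warning("D1 = 0: accuracy R undefined (empirical data match the independent model)")
    NA_real_
  }
  pr <- if (stats::sd(pairwise$probabilities) == 0 || stats::sd(f) == 0) {
    NA_real_  # degenerate flat distribution: correlation undefined
  } else {
    stats::cor(pairwise$probabilities, f)
  }
  structure(list(R = R, D1 = D1, D2 = D2, pearson_r = pr),
            class = "fit_accuracy")
}

#' @export
print.fit_accuracy <- function(x, ...) {
  cat(sprintf("MEM fit accuracy: R = %.3f (D1 = %.4f, D2 = %.4f bits), Pearson r = %.3f\n",
              x$R, x$D1, x$D2, x$pearson_r))
  invisible(x)
}
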