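#' Metropolis-Hastings random walk on an energy landscape
#'
#' Starting from a uniformly drawn pattern (or `init`), each step proposes
#' one of the `N` single-flip neighbors with probability `1/N` and accepts
#' it with probability `min(1, exp(E(current) - E(proposed)))`; a rejected
#' proposal keeps the current pattern and still consumes one step. The
#' stationary distribution of this kernel is the Boltzmann distribution of
#' the landscape.
#'
#' @param table a `landscape` object.
#' @param n_steps number of steps (default `1e5`).
#' @param seed integer seed; the walk is deterministic given the seed and
#'   the caller's RNG stream is left untouched.
#' @param init optional 0-based starting pattern index.
#' @param persistence probability in `[0, 1)` of repeating the current
#'   pattern before a Metropolis step is attempted (default 0, the plain
#'   chain); the lazy chain has the same stationary law.
#' @return A `sim_trajectory` object: `steps` (0-based pattern indices,
#'   length `n_steps`), `seed`, `n_networks`.
#' @export
metropolis_walk <- function(table, n_steps = 1e5, seed = NULL, init = NULL,
                            persistence = 0) {
  stopifnot(inherits(table, "landscape"))
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (persistence < 0 || persistence >= 1) {
    stop("persistence must be in [0, 1)", call. = FALSE)
  }
  n <- table$n_networks
  steps <- with_seed(seed, {
    start <- if (is.null(init)) sample.int(2^n, 1) - 1L else as.integer(init)
    metropolis_chain(table$energies, n, n_steps, start, persistence)
  })
  structure(list(steps = steps, seed = seed, n_networks = n),
            class = "sim_trajectory")
}

# core chain on 0-based pattern indices; uses the caller's RNG stream
metropolis_chain <- function(energies, n_networks, n_steps, start,
                             persistence = 0) {
  nbr <- neighbor_table(n_networks) + 1L                       # 1-based
  acc <- pmin(exp(energies - matrix(energies[nbr], nrow = nrow(nbr))), 1)
  choice <- sample.int(n_networks, n_steps, replace = TRUE)
  u <- stats::runif(n_steps)
  keep <- if (persistence > 0) stats::runif(n_steps) < persistence
          else rep(FALSE, n_steps)
  out <- integer(n_steps)
  cur <- start + 1L
  for (i in seq_len(n_steps)) {
    if (!keep[i]) {
      cc <- choice[i]
      if (u[i] < acc[cur, cc]) cur <- nbr[cur, cc]
    }
    out[i] <- cur
  }
  out - 1L
}

#' Explicit Metropolis transition matrix
#'
#' The `2^N x 2^N` one-step kernel: off-diagonal entries
#' `T_ij = (1/N) min(1, exp(E_i - E_j))` for single-flip neighbors, zero
#' otherwise; diagonal entries absorb the rejection mass. Satisfies
#' detailed balance with the Boltzmann distribution. Intended for small
#' `N` (dense matrix).
#'
#' @param table a `landscape` object with `N <= 12`.
#' @return A dense `2^N x 2^N` row-stochastic matrix.
#' @export
transition_matrix <- function(table) {
  stopifnot(inherits(table, "landscape"))
  n <- table$n_networks
  if (n > 12) stop("dense transition matrix limited to N <= 12",
                   call. = FALSE)
  e <- table$energies
  npat <- length(e)
  nbr <- neighbor_table(n) + 1L
  Tm <- matrix(0, npat, npat)
  for (cc in seq_len(n)) {
    j <- nbr[, cc]
    Tm[cbind(seq_len(npat), j)] <- pmin(1, exp(e - e[j])) / n
  }
  diag(Tm) <- 1 - rowSums(Tm)
  Tm
}

#' Dynamics measures of a simulated trajectory
#'
#' Maps the trajectory through the same basin/state labeling as empirical
#' data (one "subject" of length `n_steps`) and reuses
#' [occupancy_statistics] and [transition_statistics] verbatim.
#'
#' @param traj a `sim_trajectory` from [metropolis_walk].
#' @param table,basins,states the landscape, basin map, and state
#'   definition the trajectory was simulated on.
#' @param d_max indirect-transition dwell cap (see
#'   [transition_statistics]).
#' @param discard number of initial steps to drop as burn-in (default 0).
#' @return List with `occupancy`, `transitions` (with `inout` attribute),
#'   and the wide one-row `measures` table.
#' @export
simulated_measures <- function(traj, table, basins, states, d_max = 1L,
                               discard = 0L) {
  stopifnot(inherits(traj, "sim_trajectory"))
  if (traj$n_networks != basins$n_networks) {
    stop("trajectory and basin map use different numbers of networks",
         call. = FALSE)
  }
  k <- traj$steps
  if (discard > 0) k <- k[-seq_len(discard)]
  lab <- states$state_of_minimum[basins$basin_of[k + 1L]]
  seq1 <- state_sequence_from_labels(lab, table$energies[k + 1L],
                                     states$n_states)
  list(occupancy = occupancy_statistics(seq1),
       transitions = transition_statistics(seq1, d_max = d_max),
       measures = dynamics_measures(seq1, d_max = d_max))
}

#' State dwell-time and transition count tables from a trajectory
#'
#' Count-based summaries of a simulated trajectory for contingency-table
#' comparison between groups: time points per state, transition counts per
#' unordered state pair (direct/indirect/total), and in/out transition
#' counts per state.
#'
#' @inheritParams simulated_measures
#' @return List of integer vectors/matrices: `occupancy_counts`,
#'   `transition_counts`, `direct_counts`, `indirect_counts`,
#'   `inout_counts`.
#' @export
simulated_counts <- function(traj, table, basins, states, d_max = 1L,
                             discard = 0L) {
  stopifnot(inherits(traj, "sim_trajectory"))
  k <- traj$steps
  if (discard > 0) k <- k[-seq_len(discard)]
  lab <- states$state_of_minimum[basins$basin_of[k + 1L]]
  cnt <- transition_counts_one(lab, states$n_states, d_max)
  idx <- which(upper.tri(cnt$direct), arr.ind = TRUE)
  und <- function(M) (M + t(M))[idx]
  tot <- cnt$direct + t(cnt$direct) + cnt$indirect + t(cnt$indirect)
  pair_names <- if (nrow(idx)) paste0(idx[, 1], "-", idx[, 2]) else character(0)
  list(occupancy_counts = stats::setNames(tabulate(lab, states$n_states),
                                          seq_len(states$n_states)),
       transition_counts = stats::setNames(und(cnt$direct) + und(cnt$indirect),
                                           pair_names),
       direct_counts = stats::setNames(und(cnt$direct), pair_names),
       indirect_counts = stats::setNames(und(cnt$indirect), pair_names),
       inout_counts = stats::setNames(rowSums(tot) - diag(tot),
                                      seq_len(states$n_states)),
       total_transitions = sum(cnt$direct) + sum(cnt$indirect))
}
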