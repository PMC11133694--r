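# shared fixtures and independent oracles used across the suite

# random landscape with i.i.d. Gaussian energies (no MEM structure)
rand_energy_landscape <- function(n_networks, seed, sd = 1) {
  withr::with_seed(seed,
    landscape_from_energies(rnorm(2^n_networks, sd = sd)))
}

# random MEM landscape at generator-default scales
rand_mem_landscape <- function(n_networks, seed, field = 0.3, coupling = 0.3) {
  boltzmann_distribution(
    make_ground_truth_mem(n_networks, field, coupling, seed = seed))
}

# Independent minimax-path oracle: exhaustive depth-first search over simple
# paths between two patterns, returning the minimal possible value of the
# maximum node energy along a connecting path. Branch-and-bound pruning
# (abandon a branch once its running maximum reaches the best path found)
# preserves exactness.
minimax_saddle_oracle <- function(energies, n_networks, from, to) {
  nbr <- t(vapply(0:(2^n_networks - 1),
                  function(k) pattern_neighbors(k, n_networks),
                  integer(n_networks))) + 1L
  best <- Inf
  visited <- logical(length(energies))
  dfs <- function(node, cur_max) {
    if (cur_max >= best) return(invisible())
    if (node == to + 1L) {
      best <<- cur_max
      return(invisible())
    }
    visited[node] <<- TRUE
    for (nx in nbr[node, ]) {
      if (!visited[nx]) dfs(nx, max(cur_max, energies[nx]))
    }
    visited[node] <<- FALSE
    invisible()
  }
  dfs(from + 1L, energies[from + 1L])
  best
}

# pairwise saddle (branch) energies read off a disconnectivity tree:
# the merge height of the smallest cluster containing both leaves
tree_saddle_matrix <- function(tree) {
  M <- nrow(tree$minima)
  out <- matrix(NA_real_, M, M)
  members <- as.list(seq_len(M) * -1L)  # node id -> leaf set
  sets <- lapply(seq_len(M), function(i) i)
  for (r in seq_len(nrow(tree$merge))) {
    grab <- function(id) if (id < 0) -id else sets[[id + M]]
    a <- grab(tree$merge[r, 1]); b <- grab(tree$merge[r, 2])
    out[a, b] <- out[b, a] <- tree$height[r]
    sets[[r + M]] <- c(a, b)
  }
  out
}

# pooled-variance Student t computed from first principles (oracle for
# two_sample_t, which goes through stats::t.test)
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = tt, df = n1 + n2 - 2,
       p = 2 * pt(-abs(tt), n1 + n2 - 2))
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# frequency of each pattern index in a trajectory / sample
pattern_freq <- function(k, n_networks) {
  tabulate(k + 1L, nbins = 2^n_networks) / length(k)
}
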