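#' Label every time point with its brain state
#'
#' Each time point's activity pattern is sent to its basin's local minimum
#' by steepest descent (precomputed in the [assign_basins] map) and then to
#' that minimum's state. Runs of identical labels never cross subject
#' boundaries.
#'
#' @param data a `binary_pattern_data` object.
#' @param table the `landscape` the basins were built on (supplies the
#'   per-time-point energies).
#' @param basins a `basin_map` from [assign_basins].
#' @param states a `state_definition` from [group_minima_into_states].
#' @return A `state_sequence` object: `labels` and `energies` (`T x S`
#'   matrices), `pattern_index`, `n_states`.
#' @export
label_state_sequence <- function(data, table, basins, states) {
  stopifnot(inherits(data, "binary_pattern_data"),
            inherits(table, "landscape"),
            inherits(basins, "basin_map"),
            inherits(states, "state_definition"))
  if (data$n_networks != basins$n_networks) {
    stop("data and basin map use different numbers of networks",
         call. = FALSE)
  }
  k <- data$pattern_index
  if (any(k < 0) || any(k >= 2^data$n_networks)) {
    stop("pattern index out of range", call. = FALSE)
  }
  lab <- matrix(states$state_of_minimum[basins$basin_of[k + 1L]],
                nrow = nrow(k))
  en <- matrix(table$energies[k + 1L], nrow = nrow(k))
  structure(list(labels = lab, energies = en, pattern_index = k,
                 n_states = states$n_states),
            class = "state_sequence")
}

# sequence object for a single label vector (one subject / one trajectory)
state_sequence_from_labels <- function(labels, energies, n_states) {
  structure(list(labels = cbind(as.integer(labels)),
                 energies = cbind(as.numeric(energies)),
                 pattern_index = NULL, n_states = n_states),
            class = "state_sequence")
}

#' Occupancy statistics per subject and state
#'
#' For each subject: appearance frequency (time points in the state divided
#' by `T`), mean duration (average length of that state's maximal runs, in
#' time points), and mean energy (average energy of the visited patterns
#' over the state's time points). Unvisited states get frequency 0 and
#' missing duration/energy.
#'
#' @param seq a `state_sequence`.
#' @return Data frame with columns `subject`, `state`,
#'   `appearance_frequency`, `mean_duration`, `mean_energy`.
#' @export
occupancy_statistics <- function(seq) {
  stopifnot(inherits(seq, "state_sequence"))
  res <- lapply(seq_len(ncol(seq$labels)), function(s) {
    occupancy_one(seq$labels[, s], seq$energies[, s], seq$n_states, s)
  })
  do.call(rbind, res)
}

occupancy_one <- function(labels, energies, n_states, subject = 1L) {
  Tn <- length(labels)
  r <- rle(labels)
  freq <- tabulate(labels, nbins = n_states) / Tn
  dur <- vapply(seq_len(n_states), function(st) {
    len <- r$lengths[r$values == st]
    if (length(len)) mean(len) else NA_real_
  }, numeric(1))
  en <- vapply(seq_len(n_states), function(st) {
    if (freq[st] > 0) mean(energies[labels == st]) else NA_real_
  }, numeric(1))
  data.frame(subject = subject, state = seq_len(n_states),
             appearance_frequency = freq, mean_duration = dur,
             mean_energy = en)
}

#' Transition statistics per subject
#'
#' State changes are read off the run-length-compressed label sequence.
#' Scanning left to right, a run triple (A, C, B) with `A != B`, `C` a
#' third state, and the dwell of C at most `d_max` time points counts as
#' one indirect transition A -> B (a brief excursion through C) and
#' replaces the two constituent direct steps; every remaining adjacent run
#' pair counts as one direct transition. Frequencies are counts divided by
#' the total number of transitions (direct + indirect), summed over the two
#' directions of each unordered state pair. The in/out frequency of a state
#' is the fraction of all transitions with that state as source or target.
#'
#' @param seq a `state_sequence`.
#' @param d_max maximum dwell (time points) of the intermediate state for a
#'   transition to count as indirect (default 1).
#' @return Data frame with columns `subject`, `pair` (e.g. `"1-2"`),
#'   `state_a`, `state_b`, `transition_frequency`,
#'   `direct_transition_frequency`, `indirect_transition_frequency`, plus
#'   attribute `inout`: data frame `subject`, `state`, `inout_frequency`.
#' @export
transition_statistics <- function(seq, d_max = 1L) {
  stopifnot(inherits(seq, "state_sequence"))
  if (d_max < 1) stop("d_max must be >= 1", call. = FALSE)
  per <- lapply(seq_len(ncol(seq$labels)), function(s) {
    transitions_one(seq$labels[, s], seq$n_states, d_max, s)
  })
  pairs <- do.call(rbind, lapply(per, `[[`, "pairs"))
  inout <- do.call(rbind, lapply(per, `[[`, "inout"))
  attr(pairs, "inout") <- inout
  pairs
}

# greedy left-to-right count of direct and indirect (short-excursion)
# transitions on the run-length-compressed label sequence
transition_counts_one <- function(labels, n_states, d_max) {
  r <- rle(as.integer(labels))
  v <- r$values
  len <- r$lengths
  direct <- matrix(0, n_states, n_states)
  indirect <- matrix(0, n_states, n_states)
  i <- 1L
  nr <- length(v)
  while (i < nr) {
    if (i + 2L <= nr && v[i] != v[i + 2L] && v[i + 1L] != v[i] &&
        v[i + 1L] != v[i + 2L] && len[i + 1L] <= d_max) {
      indirect[v[i], v[i + 2L]] <- indirect[v[i], v[i + 2L]] + 1
      i <- i + 2L
    } else {
      direct[v[i], v[i + 1L]] <- direct[v[i], v[i + 1L]] + 1
      i <- i + 1L
    }
  }
  list(direct = direct, indirect = indirect)
}

transitions_one <- function(labels, n_states, d_max, subject = 1L) {
  cnt <- transition_counts_one(labels, n_states, d_max)
  direct <- cnt$direct
  indirect <- cnt$indirect
  total <- sum(direct) + sum(indirect)
  if (total == 0) {
    warning("no state transitions observed; transition frequencies set to 0")
  }
  div <- max(total, 1)
  ud <- (direct + t(direct)) / div
  ui <- (indirect + t(indirect)) / div
  idx <- which(upper.tri(ud), arr.ind = TRUE)
  pair_lab <- if (nrow(idx)) paste0(idx[, 1], "-", idx[, 2]) else character(0)
  pairs <- data.frame(subject = if (nrow(idx)) subject else integer(0),
                      pair = pair_lab,
                      state_a = idx[, 1], state_b = idx[, 2],
                      transition_frequency = ud[idx] + ui[idx],
                      direct_transition_frequency = ud[idx],
                      indirect_transition_frequency = ui[idx])
  both <- direct + t(direct) + indirect + t(indirect)
  inout <- data.frame(subject = subject, state = seq_len(n_states),
                      inout_frequency = (rowSums(both) - diag(both)) / div)
  list(pairs = pairs, inout = inout)
}

#' All seven dynamics measures, one row per subject
#'
#' Convenience wrapper combining [occupancy_statistics] and
#' [transition_statistics] into the wide per-subject table consumed by the
#' group-comparison stage: columns
#' `appearance_frequency_<state>`, `mean_duration_<state>`,
#' `mean_energy_<state>`, `transition_frequency_<a>_<b>`,
#' `direct_transition_frequency_<a>_<b>`,
#' `indirect_transition_frequency_<a>_<b>`, `inout_frequency_<state>`.
#'
#' @param seq a `state_sequence`.
#' @param d_max indirect-transition dwell cap (see [transition_statistics]).
#' @return Data frame, one row per subject.
#' @export
dynamics_measures <- function(seq, d_max = 1L) {
  occ <- occupancy_statistics(seq)
  tr <- transition_statistics(seq, d_max = d_max)
  io <- attr(tr, "inout")
  wide_occ <- stats::reshape(
    occ, idvar = "subject", timevar = "state", direction = "wide", sep = "_")
  names(wide_occ) <- sub("^(appearance_frequency|mean_duration|mean_energy)\\_",
                         "\\1_", names(wide_occ))
  pieces <- list(wide_occ)
  if (nrow(tr) > 0) {   # with a single state there are no pairs
    tr2 <- tr
    tr2$pair <- gsub("-", "_", tr2$pair)
    pieces <- c(pieces, list(stats::reshape(
      tr2[, c("subject", "pair", "transition_frequency",
              "direct_transition_frequency",
              "indirect_transition_frequency")],
      idvar = "subject", timevar = "pair", direction = "wide", sep = "_")))
  }
  pieces <- c(pieces, list(stats::reshape(
    io, idvar = "subject", timevar = "state", direction = "wide",
    sep = "_")))
  out <- Reduce(function(a, b) merge(a, b, by = "subject"), pieces)
  rownames(out) <- NULL
  out
}
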