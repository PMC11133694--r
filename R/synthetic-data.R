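#' Draw a random ground-truth pairwise MEM
#'
#' Baseline activities are i.i.d. Gaussian with standard deviation
#' `field_scale`; couplings are symmetric with zero diagonal and i.i.d.
#' Gaussian off-diagonal entries with standard deviation `coupling_scale`.
#' Deterministic given `seed`.
#'
#' @param n_networks number of networks, in `[2, 14]` (2^N must stay
#'   enumerable).
#' @param field_scale,coupling_scale standard deviations of `h` and of the
#'   off-diagonal `J` entries; 0 gives exact zeros.
#' @param seed integer seed.
#' @return A [mem_params] object.
#' @export
make_ground_truth_mem <- function(n_networks, field_scale = 0.3,
                                  coupling_scale = 0.3, seed = 1) {
  if (n_networks < 2 || n_networks > 14) {
    stop("n_networks must be in [2, 14]", call. = FALSE)
  }
  if (!is.finite(field_scale) || !is.finite(coupling_scale)) {
    stop("scales must be finite", call. = FALSE)
  }
  with_seed(seed, {
    h <- if (field_scale > 0) stats::rnorm(n_networks, 0, field_scale)
         else numeric(n_networks)
    J <- matrix(0, n_networks, n_networks)
    up <- upper.tri(J)
    J[up] <- if (coupling_scale > 0)
      stats::rnorm(sum(up), 0, coupling_scale) else 0
    mem_params(h, J + t(J))
  })
}

#' Perturb a subset of couplings
#'
#' Adds `delta` to the couplings of the given network pairs (symmetrically),
#' the mechanism used to plant group differences in synthetic cohorts:
#' altered pairwise interactions between networks.
#'
#' @param params a [mem_params] object.
#' @param pairs two-column matrix (or length-2 vector) of network index
#'   pairs.
#' @param delta additive change (scalar or one value per pair).
#' @return A new [mem_params] object.
#' @export
perturb_couplings <- function(params, pairs, delta) {
  stopifnot(inherits(params, "mem_params"))
  pairs <- matrix(as.integer(pairs), ncol = 2)
  J <- params$J
  delta <- rep_len(delta, nrow(pairs))
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    if (i == j) stop("cannot perturb a diagonal entry", call. = FALSE)
    J[i, j] <- J[i, j] + delta[r]
    J[j, i] <- J[i, j]
  }
  mem_params(params$h, J)
}

#' Ground truth for a synthetic two-group study
#'
#' Bundles the per-group generating models, the temporal persistence of the
#' pattern dynamics, and the linear behavior model that couples a named
#' dynamics measure to a synthetic behavior score.
#'
#' @param params_per_group named list of [mem_params], one per group label
#'   (e.g. `list(HC = ..., AD = ...)`).
#' @param persistence probability in `[0, 1)` that a time point repeats the
#'   previous pattern before a Metropolis step is attempted (default 0.7,
#'   giving dwell times of a few volumes at TR = 3 s).
#' @param behavior_model list with `measure` (a column name of the
#'   [dynamics_measures] table), `slope`, `intercept`, `noise_sd`; the
#'   behavior score of a subject is
#'   `intercept + slope * measure + N(0, noise_sd)`.
#' @param planted_transition optional planted transition-rate difference:
#'   list with `group` (label of the affected group), `pair` (two state
#'   ids), `reroute` (probability that a natural exit from a paired state
#'   toward a third state is redirected to the other paired state's deepest
#'   minimum), and `jump` (per-time-point probability of a spontaneous
#'   switch between the paired states). Rerouting changes transition
#'   destinations, not dwell lengths, so the planted effect is specific to
#'   the pair's transition rate. States refer to the reference (first
#'   group) landscape.
#' @param seed integer seed; identical seeds give bit-identical cohorts.
#' @return A `ground_truth` object.
#' @export
ground_truth <- function(params_per_group,
                         persistence = 0.7,
                         behavior_model = list(
                           measure = "transition_frequency_1_2",
                           slope = 40, intercept = 20, noise_sd = 5),
                         planted_transition = NULL,
                         seed = 1) {
  if (is.null(names(params_per_group)) ||
      any(names(params_per_group) == "")) {
    stop("params_per_group must be a named list (group labels)",
         call. = FALSE)
  }
  lapply(params_per_group, function(p) stopifnot(inherits(p, "mem_params")))
  if (persistence < 0 || persistence >= 1) {
    stop("persistence must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(planted_transition)) {
    stopifnot(is.list(planted_transition),
              all(c("group", "pair") %in% names(planted_transition)),
              planted_transition$group %in% names(params_per_group),
              length(planted_transition$pair) == 2)
    planted_transition$reroute <- planted_transition$reroute %||% 0
    planted_transition$jump <- planted_transition$jump %||% 0
  }
  structure(list(params_per_group = params_per_group,
                 persistence = persistence,
                 behavior_model = behavior_model,
                 planted_transition = planted_transition, seed = seed),
            class = "ground_truth")
}

#' Sample activity patterns from a pairwise MEM
#'
#' `iid` mode draws patterns directly from the exactly enumerated
#' Boltzmann distribution. `markov` mode runs the Metropolis kernel of
#' [metropolis_walk] started from a stationary draw, optionally mixed with
#' a self-repeat probability `persistence`; the marginal distribution of
#' every sample is still the Boltzmann law, but consecutive samples are
#' temporally correlated, emulating the dwell structure of slow network
#' dynamics.
#'
#' @param params a [mem_params] object.
#' @param n_samples number of time points to draw.
#' @param mode `"iid"` or `"markov"`.
#' @param persistence self-repeat probability in `[0, 1)` (markov mode).
#' @param seed integer seed.
#' @return A `binary_pattern_data` object with one subject
#'   (`T = n_samples`).
#' @export
sample_patterns <- function(params, n_samples, mode = c("iid", "markov"),
                            persistence = 0, seed = NULL) {
  stopifnot(inherits(params, "mem_params"))
  mode <- match.arg(mode)
  if (n_samples < 1) stop("n_samples must be >= 1", call. = FALSE)
  if (persistence < 0 || persistence >= 1) {
    stop("persistence must be in [0, 1)", call. = FALSE)
  }
  table <- boltzmann_distribution(params)
  k <- with_seed(seed, {
    if (mode == "iid") {
      sample.int(2^params$n_networks, n_samples, replace = TRUE,
                 prob = table$probabilities) - 1L
    } else {
      start <- sample.int(2^params$n_networks, 1,
                          prob = table$probabilities) - 1L
      metropolis_chain(table$energies, params$n_networks, n_samples,
                       start, persistence)
    }
  })
  binary_pattern_from_indices(cbind(k), params$n_networks)
}

# Metropolis chain with planted transition events between two states:
# `jump` switches a paired state to the other member's deepest minimum with
# a small per-time-point probability; `reroute` redirects a natural exit
# from a paired state toward a third state back to the other paired state.
# Uses the caller's RNG stream.
planted_chain <- function(energies, n_networks, n_steps, start, persistence,
                          state_of_pattern, deep_pattern, pair, reroute,
                          jump) {
  nbr <- neighbor_table(n_networks) + 1L
  acc <- pmin(exp(energies - matrix(energies[nbr], nrow = nrow(nbr))), 1)
  out <- integer(n_steps)
  cur <- start + 1L
  for (i in seq_len(n_steps)) {
    s0 <- state_of_pattern[cur]
    if (jump > 0 && s0 %in% pair && stats::runif(1) < jump) {
      cur <- deep_pattern[setdiff(pair, s0)[1]] + 1L
    } else if (stats::runif(1) >= persistence) {
      cc <- sample.int(n_networks, 1)
      if (stats::runif(1) < acc[cur, cc]) {
        prop <- nbr[cur, cc]
        s1 <- state_of_pattern[prop]
        if (reroute > 0 && s0 %in% pair && s1 != s0 && !(s1 %in% pair) &&
            stats::runif(1) < reroute) {
          prop <- deep_pattern[setdiff(pair, s0)[1]] + 1L
        }
        cur <- prop
      }
    }
    out[i] <- cur
  }
  out - 1L
}

#' Generate a synthetic two-group cohort
#'
#' Per subject, a markov-mode pattern sequence is drawn from the subject's
#' group model and mapped to continuous network signals
#' `pattern value * snr + N(0, 1)` (per network and time point, zero
#' baseline), so that mean-thresholding in [binarize_by_mean] approximately
#' recovers the generating patterns. The behavior score is
#' `intercept + slope * planted measure + N(0, noise_sd)`, where the
#' planted measure is the subject's value of the ground truth's named
#' dynamics measure, computed from the generating (noise-free) state
#' sequence under the first group's landscape.
#'
#' @param truth a [ground_truth] object.
#' @param n_subjects_per_group subjects per group (default 30).
#' @param t_per_subject time points per subject (default 140).
#' @param snr signal amplitude relative to unit noise (default 2).
#' @param seed integer seed (defaults to `truth$seed`).
#' @param n_states number of brain states used when computing the planted
#'   measure (default 3, capped at the number of minima).
#' @return A `cohort` object: `series` (named list of `N x T` continuous
#'   matrices), `manifest` (data frame: `subject_id`, `group`, `behavior`,
#'   `planted_measure`), `true_patterns` (named list of generating
#'   pattern-index vectors), `truth`, `snr`.
#' @export
make_cohort <- function(truth, n_subjects_per_group = 30,
                        t_per_subject = 140, snr = 2, seed = truth$seed,
                        n_states = 3) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_subjects_per_group < 1 || t_per_subject < 1) {
    stop("counts must be >= 1", call. = FALSE)
  }
  if (snr <= 0) stop("snr must be positive", call. = FALSE)
  groups <- names(truth$params_per_group)
  n_net <- truth$params_per_group[[1]]$n_networks

  # reference landscape (first group) defines states for the planted measure
  ref_table <- boltzmann_distribution(truth$params_per_group[[1]])
  ref_basins <- assign_basins(ref_table)
  ref_tree <- build_disconnectivity_tree(ref_table, ref_basins$minima)
  k_states <- min(n_states, nrow(ref_basins$minima))
  ref_states <- group_minima_into_states(ref_tree, k = k_states)

  # intervention targets for a planted transition difference
  pt <- truth$planted_transition
  state_of_pattern <- ref_states$state_of_minimum[ref_basins$basin_of]
  deep_pattern <- vapply(seq_len(ref_states$n_states), function(s) {
    ref_basins$minima$pattern[which(ref_states$state_of_minimum == s)[1]]
  }, integer(1))
  if (!is.null(pt) && any(pt$pair > ref_states$n_states)) {
    stop("planted_transition$pair refers to a state the reference landscape does not have",
         call. = FALSE)
  }

  bm <- truth$behavior_model
  with_seed(seed, {
    series <- list()
    patterns <- list()
    rows <- list()
    for (g in groups) {
      table_g <- boltzmann_distribution(truth$params_per_group[[g]])
      for (s in seq_len(n_subjects_per_group)) {
        id <- sprintf("%s_%02d", g, s)
        start <- sample.int(2^n_net, 1, prob = table_g$probabilities) - 1L
        k <- if (!is.null(pt) && identical(g, pt$group)) {
          planted_chain(table_g$energies, n_net, t_per_subject, start,
                        truth$persistence, state_of_pattern, deep_pattern,
                        pt$pair, pt$reroute, pt$jump)
        } else {
          metropolis_chain(table_g$energies, n_net, t_per_subject,
                           start, truth$persistence)
        }
        sigma <- if (t_per_subject == 1L) {
          matrix(pattern_decode(k, n_net), ncol = 1)
        } else {
          t(pattern_decode(k, n_net))
        }
        series[[id]] <- sigma * snr +
          matrix(stats::rnorm(n_net * t_per_subject), n_net)
        patterns[[id]] <- k

        lab <- ref_states$state_of_minimum[ref_basins$basin_of[k + 1L]]
        seq1 <- state_sequence_from_labels(lab, ref_table$energies[k + 1L],
                                           ref_states$n_states)
        meas <- suppressWarnings(dynamics_measures(seq1))
        planted <- meas[[bm$measure]]
        if (is.null(planted)) {
          stop("behavior_model$measure '", bm$measure,
               "' is not a dynamics-measures column", call. = FALSE)
        }
        rows[[id]] <- data.frame(
          subject_id = id, group = g, planted_measure = planted,
          behavior = bm$intercept + bm$slope * planted +
            stats::rnorm(1, 0, bm$noise_sd))
      }
    }
    manifest <- do.call(rbind, rows)
    rownames(manifest) <- NULL
    structure(list(series = series,
                   manifest = manifest[, c("subject_id", "group",
                                           "behavior", "planted_measure")],
                   true_patterns = patterns, truth = truth, snr = snr),
              class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  tab <- table(x$manifest$group)
  cat("Synthetic cohort:", sum(tab), "subjects (",
      paste(names(tab), tab, sep = " = ", collapse = ", "), ")\n")
  d <- dim(x$series[[1]])
  cat("  ", d[1], "networks x", d[2], "time points per subject\n")
  invisible(x)
}

#' Write / read a cohort as delimited text
#'
#' `write_cohort()` writes one tab-delimited `N x T` matrix per subject
#' (`<subject_id>.tsv`), a `manifest.tsv` with subject id, group, and
#' behavior columns, and a `truth.json` sidecar recording the generating
#' `h`, `J`, persistence, behavior model, and seed. `read_cohort()` reads
#' them back.
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if missing).
#' @return `write_cohort()`: `dir`, invisibly. `read_cohort()`: a `cohort`
#'   object (without `true_patterns`; `truth` only when the sidecar is
#'   present).
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (id in names(cohort$series)) {
    utils::write.table(cohort$series[[id]], file.path(dir, paste0(id, ".tsv")),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(cohort$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  truth <- cohort$truth
  sidecar <- list(
    groups = lapply(truth$params_per_group,
                    function(p) list(h = p$h, J = p$J)),
    persistence = truth$persistence,
    behavior_model = truth$behavior_model,
    planted_transition = truth$planted_transition,
    seed = truth$seed, snr = cohort$snr)
  jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"),
                                sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
  series <- lapply(manifest$subject_id, function(id) {
    as.matrix(utils::read.table(file.path(dir, paste0(id, ".tsv")),
                                sep = "\t", header = FALSE))
  })
  names(series) <- manifest$subject_id
  series <- lapply(series, unname)
  truth <- NULL
  tj <- file.path(dir, "truth.json")
  if (file.exists(tj)) {
    raw <- jsonlite::read_json(tj, simplifyVector = TRUE)
    params <- lapply(raw$groups, function(g) {
      mem_params(as.numeric(g$h), matrix(unlist(g$J), length(g$h)))
    })
    pt <- raw$planted_transition
    if (!length(pt)) pt <- NULL          # absent -> {} in JSON
    if (!is.null(pt)) pt$pair <- as.integer(unlist(pt$pair))
    truth <- ground_truth(params, persistence = raw$persistence,
                          behavior_model = raw$behavior_model,
                          planted_transition = pt, seed = raw$seed)
  }
  structure(list(series = series, manifest = manifest,
                 true_patterns = NULL, truth = truth),
            class = "cohort")
}
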