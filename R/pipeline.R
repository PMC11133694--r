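#' Default analysis configuration
#'
#' Returns the full configuration list for [run_group_analysis] with
#' package defaults; supplied values override defaults by name. A YAML
#' file with the same keys can be loaded with [load_run_config].
#'
#' @param ... named overrides (e.g. `n_states = 3`, `mcmc_steps = 2e5`).
#' @return Named list of configuration values.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    cohort_dir = NULL,        # read_cohort() source when no object is given
    output_dir = NULL,        # artifacts written only when set
    learning_rate = 0.1,      # gradient-ascent step size
    tol = 1e-5,               # max moment gap at convergence
    max_iter = 5e4,
    n_states = 3,             # tree cut when no explicit mapping is given
    state_mapping = NULL,     # explicit minima -> state mapping, per group
    d_max = 1,                # indirect-transition dwell cap (time points)
    tr_seconds = 3,           # repetition time, for duration conversion
    mcmc_steps = 1e5,
    mcmc_seed = 1,
    alpha = 0.05,             # significance level on corrected p values
    behavior_scores = "behavior")
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) {
    over <- over[[1]]
  }
  cfg[names(over)] <- over
  cfg
}

#' @rdname default_run_config
#' @param path YAML file of configuration keys.
#' @export
load_run_config <- function(path) {
  default_run_config(yaml::read_yaml(path))
}

#' Run the full two-group energy-landscape analysis
#'
#' Per group: concatenate subjects, binarize at the group means, fit the
#' pairwise MEM by gradient ascent, compute fit diagnostics, enumerate the
#' energy landscape, find minima and basins, build the disconnectivity
#' tree, and define brain states. Then per subject: label the state
#' sequence and compute the seven dynamics measures. Finally: group
#' comparisons (t tests with Bonferroni families, basin-size chi-square),
#' behavior correlations restricted to significant measures, and a
#' Metropolis-Hastings simulation per group with count-based chi-square
#' comparison. When `output_dir` is set, all artifacts are written as
#' delimited text / Newick / JSON along with a plain-text log.
#'
#' @param cohort a `cohort` object, or `NULL` to read
#'   `config$cohort_dir`.
#' @param config configuration list from [default_run_config].
#' @return A result bundle (list): `per_group` (fit, landscape, basins,
#'   tree, states, accuracy per group), `measures` (per-subject table),
#'   `comparisons`, `basin_chisq`, `correlations`, `simulation`
#'   (per-group measures, counts, chi-square tables), `config`.
#' @export
run_group_analysis <- function(cohort = NULL, config = default_run_config()) {
  if (is.null(cohort)) {
    if (is.null(config$cohort_dir)) {
      stop("supply a cohort object or config$cohort_dir", call. = FALSE)
    }
    cohort <- read_cohort(config$cohort_dir)
  }
  manifest <- cohort$manifest
  groups <- unique(manifest$group)
  out_dir <- config$output_dir
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  per_group <- list()
  measure_rows <- list()
  for (g in groups) {
    ids <- manifest$subject_id[manifest$group == g]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e) {
        stop(sprintf("group %s, stage %s: %s", g, what, conditionMessage(e)),
             call. = FALSE)
      })
    }
    Z <- stage("concatenate", concatenate_subjects(cohort$series[ids]))
    bin <- stage("binarize", binarize_by_mean(Z))
    emp <- empirical_moments(bin)
    fit <- stage("fit", fit_pairwise_mem(
      emp, learning_rate = config$learning_rate, tol = config$tol,
      max_iter = config$max_iter))
    say("group %s: MEM fit %s after %d iterations (max moment gap %.2e)",
        g, if (fit$diagnostics$converged) "converged" else "NOT converged",
        fit$diagnostics$iterations, fit$diagnostics$max_moment_gap)
    table <- boltzmann_distribution(fit$params)
    indep <- boltzmann_distribution(fit_independent_mem(emp$mean_activity))
    freq <- empirical_pattern_frequencies(bin)
    acc <- fit_accuracy(freq, indep, table)
    say("group %s: accuracy R = %.3f, Pearson r = %.3f", g, acc$R,
        acc$pearson_r)
    basins <- stage("landscape", assign_basins(table))
    tree <- stage("tree", build_disconnectivity_tree(table, basins$minima))
    states <- stage("states", {
      map_g <- config$state_mapping[[g]] %||% config$state_mapping
      if (!is.null(map_g)) {
        group_minima_into_states(tree, mapping = map_g)
      } else {
        group_minima_into_states(
          tree, k = min(config$n_states, nrow(basins$minima)))
      }
    })
    say("group %s: %d local minima grouped into %d states", g,
        nrow(basins$minima), states$n_states)

    seqs <- stage("label", label_state_sequence(bin, table, basins, states))
    meas <- stage("measures", suppressWarnings(
      dynamics_measures(seqs, d_max = config$d_max)))
    meas$subject_id <- ids[meas$subject]
    meas$group <- g
    measure_rows[[g]] <- meas

    per_group[[g]] <- list(binary = bin, fit = fit, landscape = table,
                           accuracy = acc, basins = basins, tree = tree,
                           states = states, empirical_frequencies = freq)
  }

  measures <- rbind_fill(measure_rows)
  rownames(measures) <- NULL
  comparisons <- compare_dynamics(measures)
  sig <- comparisons$measure[!is.na(comparisons$p_bonferroni) &
                               comparisons$p_bonferroni < config$alpha]
  say("group comparison: %d of %d measures significant at corrected %.2f",
      length(sig), nrow(comparisons), config$alpha)

  # basin-size comparison: counts of patterns per state, out of 2^N per group
  n_states_max <- max(vapply(per_group, function(x) x$states$n_states,
                             integer(1)))
  basin_counts <- do.call(rbind, lapply(groups, function(g) {
    pg <- per_group[[g]]
    tabulate(pg$states$state_of_minimum[pg$basins$basin_of],
             nbins = n_states_max)
  }))
  rownames(basin_counts) <- groups
  basin_chisq <- chi_square_posthoc(basin_counts)

  correlations <- NULL
  scores <- intersect(config$behavior_scores, names(manifest))
  if (length(scores) > 0 && length(sig) > 0) {
    ord <- match(measures$subject_id, manifest$subject_id)
    correlations <- suppressWarnings(behavior_correlations(
      measures, manifest[ord, , drop = FALSE], scores = scores,
      selection = unique(sig)))
  }

  simulation <- list()
  for (g in groups) {
    pg <- per_group[[g]]
    traj <- metropolis_walk(pg$landscape, n_steps = config$mcmc_steps,
                            seed = config$mcmc_seed)
    simulation[[g]] <- list(
      measures = suppressWarnings(
        simulated_measures(traj, pg$landscape, pg$basins, pg$states,
                           d_max = config$d_max)),
      counts = suppressWarnings(
        simulated_counts(traj, pg$landscape, pg$basins, pg$states,
                         d_max = config$d_max)))
  }
  if (length(groups) == 2) {
    ct <- lapply(c("occupancy_counts", "transition_counts", "direct_counts",
                   "indirect_counts", "inout_counts"), function(what) {
      a <- simulation[[groups[1]]]$counts[[what]]
      b <- simulation[[groups[2]]]$counts[[what]]
      # comparable only when both groups share the same states/pairs
      if (length(a) != length(b) || !identical(names(a), names(b))) {
        return(NULL)
      }
      tab <- rbind(a, b)
      rownames(tab) <- groups
      if (ncol(tab) >= 2 && all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
        chi_square_posthoc(round(tab))
      } else NULL
    })
    names(ct) <- c("occupancy", "transition", "direct", "indirect", "inout")
    simulation$chisq <- ct
  }

  result <- list(per_group = per_group, measures = measures,
                 comparisons = comparisons, basin_chisq = basin_chisq,
                 basin_counts = basin_counts, correlations = correlations,
                 simulation = simulation, significant = sig,
                 config = config, log = log_lines)
  if (!is.null(out_dir)) write_result_bundle(result, cohort, out_dir)
  result
}

# rbind data frames whose column sets may differ (e.g. groups with a
# different number of states); absent columns become NA
rbind_fill <- function(dfs) {
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (cl in setdiff(cols, names(d))) d[[cl]] <- NA
    d[, cols, drop = FALSE]
  }))
}

# persist every artifact of a pipeline run as plain text
write_result_bundle <- function(result, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(result$config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  for (g in names(result$per_group)) {
    pg <- result$per_group[[g]]
    pdir <- file.path(out_dir, g)
    dir.create(pdir, showWarnings = FALSE)
    utils::write.table(
      data.frame(network = seq_along(pg$fit$params$h), h = pg$fit$params$h),
      file.path(pdir, "h.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(pg$fit$params$J, file.path(pdir, "J.tsv"),
                       sep = "\t", row.names = FALSE, col.names = FALSE)
    n <- pg$landscape$n_networks
    k <- 0:(2^n - 1)
    pat <- apply(all_patterns(n), 1, function(s)
      paste(ifelse(s > 0, "1", "0"), collapse = ""))
    lt <- data.frame(
      pattern_index = k, pattern = pat,
      energy = pg$landscape$energies,
      probability = pg$landscape$probabilities,
      empirical_frequency = pg$empirical_frequencies,
      minimum = pg$basins$basin_of,
      state = pg$states$state_of_minimum[pg$basins$basin_of])
    utils::write.table(lt, file.path(pdir, "landscape.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    write_newick(pg$tree, file.path(pdir, "tree.nwk"))
    utils::write.table(
      data.frame(network = seq_len(n), threshold = pg$binary$thresholds),
      file.path(pdir, "thresholds.tsv"), sep = "\t", row.names = FALSE,
      quote = FALSE)
  }
  utils::write.table(result$measures, file.path(out_dir, "measures.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(result$comparisons, file.path(out_dir, "comparisons.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(result$correlations)) {
    utils::write.table(result$correlations,
                       file.path(out_dir, "correlations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  summary <- list(
    config_md5 = cfg_hash,
    seeds = list(mcmc = result$config$mcmc_seed,
                 cohort = cohort$truth$seed %||% NA),
    groups = lapply(result$per_group, function(pg) list(
      accuracy_R = pg$accuracy$R,
      pearson_r = pg$accuracy$pearson_r,
      n_minima = nrow(pg$basins$minima),
      converged = pg$fit$diagnostics$converged,
      iterations = pg$fit$diagnostics$iterations)),
    basin_chisq = list(statistic = result$basin_chisq$statistic,
                       p = result$basin_chisq$p),
    significant_measures = result$significant)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}
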