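#' Two-sample Student t test (pooled variance)
#'
#' Equal-variance two-sample t with `df = n1 + n2 - 2` and a two-sided p
#' value; the form under which the demographic-table t values of a 30 + 30
#' cohort recompute from printed summaries. Welch's form is available with
#' `var_equal = FALSE`.
#'
#' @param group1,group2 numeric vectors (each of length >= 2; missing
#'   values dropped).
#' @param var_equal pool the variances (default `TRUE`).
#' @return A `comparison_result` list: `statistic`, `p`, `df`, `means`,
#'   `sds`, `ns`, `overflow` (TRUE when variances are zero but means
#'   differ).
#' @export
two_sample_t <- function(group1, group2, var_equal = TRUE) {
  g1 <- group1[is.finite(group1)]
  g2 <- group2[is.finite(group2)]
  if (length(g1) < 2 || length(g2) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  res <- list(means = c(mean(g1), mean(g2)),
              sds = c(stats::sd(g1), stats::sd(g2)),
              ns = c(length(g1), length(g2)), overflow = FALSE)
  if (all(res$sds == 0)) {
    # degenerate: no within-group variance
    res$df <- sum(res$ns) - 2
    if (res$means[1] == res$means[2]) {
      res$statistic <- 0; res$p <- 1
    } else {
      res$statistic <- sign(res$means[1] - res$means[2]) * Inf
      res$p <- 0; res$overflow <- TRUE
    }
  } else {
    tt <- stats::t.test(g1, g2, var.equal = var_equal)
    res$statistic <- unname(tt$statistic)
    res$p <- tt$p.value
    res$df <- unname(tt$parameter)
  }
  structure(res, class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %.1f, p = %.4g\n", x$statistic, x$df, x$p))
  cat(sprintf("  group means %.3f +/- %.3f (n=%d) vs %.3f +/- %.3f (n=%d)\n",
              x$means[1], x$sds[1], x$ns[1], x$means[2], x$sds[2], x$ns[2]))
  invisible(x)
}

#' Pooled-variance t statistic from printed summaries
#'
#' `t = (m1 - m2) / sqrt(s_p^2 (1/n1 + 1/n2))` with
#' `s_p^2 = ((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2)`. Lets published
#' mean +/- SD tables be checked without the raw data.
#'
#' @param mean1,sd1,n1 summary of group 1.
#' @param mean2,sd2,n2 summary of group 2.
#' @return The t statistic (0 when both SDs are zero and the means agree).
#' @examples
#' t_from_summary(28.7, 1.3, 30, 22.5, 2.5, 30)  # ~12.05
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("n1 and n2 must be >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("sds must be >= 0", call. = FALSE)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  if (sp2 == 0) {
    if (mean1 == mean2) return(0)
    return(sign(mean1 - mean2) * Inf)
  }
  (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Bonferroni correction within a declared family
#'
#' Multiplies each raw p value by the family size and caps at 1. Families
#' are declared per measure type (e.g. 3 states for occupancy measures,
#' 3 pairs for transition measures) rather than pooled across all tests.
#'
#' @param p_values numeric vector of raw p values in `[0, 1]`.
#' @param family_size number of tests in the family (defaults to
#'   `length(p_values)`).
#' @return Corrected p values.
#' @export
bonferroni_adjust <- function(p_values, family_size = length(p_values)) {
  if (length(p_values) == 0 || family_size < 1) {
    stop("empty Bonferroni family", call. = FALSE)
  }
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  pmin(1, p_values * family_size)
}

#' Chi-square test with post-hoc adjusted residuals
#'
#' Pearson chi-square on an `r x c` count table with
#' `(r - 1)(c - 1)` degrees of freedom, followed by per-cell adjusted
#' standardized residuals
#' `(O - E) / sqrt(E (1 - row_total/n) (1 - col_total/n))`, each compared
#' against a standard normal (two-sided) and Bonferroni-corrected across
#' the cells.
#'
#' @param table an `r x c` matrix of nonnegative counts with positive row
#'   and column sums.
#' @param correct_cells Bonferroni-correct the per-cell p values across all
#'   cells (default `TRUE`).
#' @return List of class `chisq_posthoc`: `statistic`, `df`, `p`,
#'   `expected`, `residuals` (adjusted standardized), `cell_p` (two-sided
#'   normal p per cell, corrected when requested).
#' @export
chi_square_posthoc <- function(table, correct_cells = TRUE) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("row and column sums must be positive", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  z <- ct$stdres
  bad <- ct$expected == 0
  if (any(bad)) {
    warning("cells with zero expected count excluded from post-hoc residuals")
    z[bad] <- NA
  }
  cell_p <- 2 * stats::pnorm(-abs(z))
  if (correct_cells) cell_p[] <- pmin(1, cell_p * sum(!bad))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter), p = ct$p.value,
                 expected = ct$expected, residuals = z, cell_p = cell_p),
            class = "chisq_posthoc")
}

#' @export
print.chisq_posthoc <- function(x, ...) {
  cat(sprintf("chi-square = %.3f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p))
  cat("adjusted standardized residuals:\n")
  print(round(x$residuals, 2))
  invisible(x)
}

#' Compare all dynamics measures between two groups
#'
#' Runs a two-sample t test per measure column and Bonferroni-corrects
#' within declared families. By default each measure type is its own
#' family (appearance frequency across states, mean duration across
#' states, ..., transition frequency across pairs), matching the way the
#' seven measure types are reported separately.
#'
#' @param measures per-subject wide table from [dynamics_measures], plus a
#'   `group` column (exactly two levels).
#' @param families named list mapping family names to character vectors of
#'   measure columns; defaults to grouping columns by their measure-type
#'   prefix.
#' @param var_equal pooled-variance t (default `TRUE`).
#' @return Tidy data frame: `measure`, `family`, group means and SDs, `t`,
#'   `df`, `p`, `p_bonferroni`, `family_size`.
#' @export
compare_dynamics <- function(measures, families = NULL, var_equal = TRUE) {
  if (!"group" %in% names(measures)) {
    stop("measures must contain a `group` column", call. = FALSE)
  }
  groups <- unique(measures$group)
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  cols <- setdiff(names(measures), c("subject", "subject_id", "group"))
  if (is.null(families)) {
    prefix <- sub("_[0-9]+(_[0-9]+)?$", "", cols)
    families <- split(cols, prefix)
  }
  rows <- lapply(names(families), function(fam) {
    fam_cols <- intersect(families[[fam]], cols)
    do.call(rbind, lapply(fam_cols, function(cl) {
      g1 <- measures[measures$group == groups[1], cl]
      g2 <- measures[measures$group == groups[2], cl]
      if (sum(is.finite(g1)) < 2 || sum(is.finite(g2)) < 2) {
        # e.g. a state almost never visited: too few finite observations
        return(data.frame(measure = cl, family = fam,
                          mean1 = mean(g1, na.rm = TRUE), sd1 = NA_real_,
                          mean2 = mean(g2, na.rm = TRUE), sd2 = NA_real_,
                          t = NA_real_, df = NA_real_, p = NA_real_,
                          family_size = length(fam_cols)))
      }
      r <- two_sample_t(g1, g2, var_equal = var_equal)
      data.frame(measure = cl, family = fam,
                 mean1 = r$means[1], sd1 = r$sds[1],
                 mean2 = r$means[2], sd2 = r$sds[2],
                 t = r$statistic, df = r$df, p = r$p,
                 family_size = length(fam_cols))
    }))
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- stats::ave(out$p, out$family,
                                 FUN = function(p) bonferroni_adjust(p))
  attr(out, "groups") <- groups
  rownames(out) <- NULL
  out
}

#' Behavior correlations within groups
#'
#' Pearson correlation (two-sided p) between each selected dynamics
#' measure and each behavior score, computed separately per group;
#' restricted to the measures flagged as showing a significant group
#' difference when a `selection` is supplied.
#'
#' @param measures per-subject wide table with `group` column and measure
#'   columns.
#' @param behavior data frame with one row per subject (same order) holding
#'   the score columns.
#' @param scores character vector of behavior column names.
#' @param selection character vector of measure columns to correlate
#'   (e.g. significant rows of [compare_dynamics]); must be nonempty.
#' @return Tidy data frame: `group`, `measure`, `score`, `n`, `r`, `p`
#'   (`r` missing when either variable has zero variance).
#' @export
behavior_correlations <- function(measures, behavior, scores, selection) {
  if (length(selection) == 0) stop("selection must be nonempty",
                                   call. = FALSE)
  if (nrow(behavior) != nrow(measures)) {
    stop("measures and behavior must have one row per subject",
         call. = FALSE)
  }
  out <- list()
  for (g in unique(measures$group)) {
    idx <- measures$group == g
    if (sum(idx) < 3) stop("each group needs n >= 3", call. = FALSE)
    for (m in selection) {
      for (sc in scores) {
        x <- measures[idx, m]
        y <- behavior[idx, sc]
        ok <- is.finite(x) & is.finite(y)
        if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
          warning("zero variance or too few observations: correlation of ",
                  m, " with ", sc, " in group ", g, " reported missing")
          out[[length(out) + 1]] <- data.frame(
            group = g, measure = m, score = sc, n = sum(ok),
            r = NA_real_, p = NA_real_)
        } else {
          ct <- stats::cor.test(x[ok], y[ok])
          out[[length(out) + 1]] <- data.frame(
            group = g, measure = m, score = sc, n = sum(ok),
            r = unname(ct$estimate), p = ct$p.value)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
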