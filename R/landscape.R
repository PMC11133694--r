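#' Find local energy minima (attractors)
#'
#' Exhaustively scans all `2^N` patterns; a pattern is a local minimum when
#' its energy is strictly smaller than the energies of all `N` single-flip
#' neighbors.
#'
#' @param table a `landscape` object.
#' @return Data frame with columns `label` (1, 2, ... in ascending energy,
#'   matching the numbering convention used for brain states), `pattern`
#'   (0-based index), `energy`. Zero rows (with a warning) when the
#'   landscape is flat enough that no strict minimum exists.
#' @export
find_local_minima <- function(table) {
  stopifnot(inherits(table, "landscape"))
  e <- table$energies
  nbr <- neighbor_table(table$n_networks)
  nbr_min <- matrix(e[nbr + 1L], nrow = nrow(nbr))
  is_min <- e < do.call(pmin, as.data.frame(nbr_min))
  if (!any(is_min)) {
    warning("no strict local minimum found (degenerate flat landscape)")
    return(data.frame(label = integer(0), pattern = integer(0),
                      energy = numeric(0)))
  }
  k <- which(is_min) - 1L
  ord <- order(e[k + 1L], k)
  data.frame(label = seq_along(k), pattern = k[ord], energy = e[k[ord] + 1L])
}

#' Assign every pattern to a basin by steepest descent
#'
#' From each pattern, repeatedly move to the lowest-energy neighbor as long
#' as one is strictly lower; the fixed point reached is the pattern's
#' attractor. Exact ties among equally lowest strictly-lower neighbors
#' (a measure-zero event for generic parameters) are broken
#' deterministically by flipping the highest-index network, which keeps the
#' descent equivariant under a global activity flip — a symmetric double
#' well splits its basins exactly 0.5/0.5. Basin size is the fraction of
#' the `2^N` patterns ending at each minimum.
#'
#' @param table a `landscape` object with at least one strict local minimum.
#' @return A `basin_map` object: `minima` (as [find_local_minima]),
#'   `basin_of` (length-`2^N` integer vector of minimum labels, indexed by
#'   pattern index + 1), `basin_sizes` (named per label; sums to 1).
#' @export
assign_basins <- function(table) {
  stopifnot(inherits(table, "landscape"))
  minima <- find_local_minima(table)
  if (nrow(minima) == 0) {
    stop("cannot assign basins: landscape has no strict local minimum",
         call. = FALSE)
  }
  e <- table$energies
  npat <- length(e)
  nbr <- neighbor_table(table$n_networks) + 1L  # 1-based
  nbrE <- matrix(e[nbr], nrow = npat)
  low <- do.call(pmin, as.data.frame(nbrE))
  # among neighbors attaining the lowest energy, take the one reached by
  # flipping the highest-index network (deterministic, flip-symmetric)
  best <- integer(npat)
  for (cc in seq_len(ncol(nbr))) {
    hit <- nbrE[, cc] == low
    best[hit] <- nbr[hit, cc]
  }
  nxt <- ifelse(low < e, best, seq_len(npat))
  # pointer jumping to the descent fixed points
  repeat {
    nxt2 <- nxt[nxt]
    if (identical(nxt2, nxt)) break
    nxt <- nxt2
  }
  lab_of_pattern <- rep(NA_integer_, npat)
  lab_of_pattern[minima$pattern + 1L] <- minima$label
  basin_of <- lab_of_pattern[nxt]
  if (anyNA(basin_of)) {
    stop("steepest descent reached a non-minimum fixed point", call. = FALSE)
  }
  sizes <- tabulate(basin_of, nbins = nrow(minima)) / npat
  names(sizes) <- minima$label
  structure(list(minima = minima, basin_of = basin_of, basin_sizes = sizes,
                 n_networks = table$n_networks),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  cat("Basin map:", nrow(x$minima), "local minima\n")
  df <- x$minima
  df$basin_size <- x$basin_sizes[as.character(df$label)]
  print(df, row.names = FALSE)
  invisible(x)
}

#' Build the disconnectivity tree of the local minima
#'
#' Sweeps the energy threshold `E_th` downward through the sorted unique
#' energy values; at each threshold, all patterns with energy `>= E_th` are
#' removed and connectivity between minima is checked on the surviving
#' single-flip graph. Two minima separate at the highest threshold at which
#' no surviving path joins them; that threshold is recorded as their branch
#' (separation) energy, which equals the minimax over connecting paths of
#' the maximum pattern energy along the path. Implemented by union-find
#' over patterns processed in ascending energy order, which visits the same
#' thresholds in reverse.
#'
#' @param table a `landscape` object.
#' @param minima optional minima data frame (recomputed when missing).
#' @return A `disconnectivity_tree` object: `minima`; `merge` and `height`
#'   in [stats::hclust] format (`height` = branch energies, nondecreasing);
#'   `labels` (`"min<label>"`). A single minimum yields a tree with no
#'   internal node.
#' @export
build_disconnectivity_tree <- function(table, minima = NULL) {
  stopifnot(inherits(table, "landscape"))
  if (is.null(minima)) minima <- find_local_minima(table)
  M <- nrow(minima)
  if (M == 0) stop("no local minima: no tree to build", call. = FALSE)
  labels <- paste0("min", minima$label)
  if (M == 1) {
    return(structure(list(minima = minima,
                          merge = matrix(integer(0), 0, 2),
                          height = numeric(0), labels = labels),
                     class = "disconnectivity_tree"))
  }
  e <- table$energies
  npat <- length(e)
  nbr <- neighbor_table(table$n_networks) + 1L

  parent <- seq_len(npat)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  # minimum label carried by each component root (0 = none);
  # tree node id per root: negative = leaf row in `minima`, positive = merge row
  comp_min <- integer(npat)
  comp_node <- integer(npat)
  comp_min[minima$pattern + 1L] <- minima$label
  comp_node[minima$pattern + 1L] <- -minima$label
  active <- logical(npat)

  ord <- order(e, seq_len(npat))
  lev_id <- cumsum(!duplicated(e[ord]))
  merges <- matrix(0L, M - 1, 2)
  heights <- numeric(M - 1)
  nm <- 0L
  for (lev in seq_len(max(lev_id))) {
    batch <- ord[lev_id == lev]
    active[batch] <- TRUE
    for (i in batch) {
      for (j in nbr[i, ]) {
        if (!active[j]) next
        ri <- find(i); rj <- find(j)
        if (ri == rj) next
        if (comp_min[ri] > 0L && comp_min[rj] > 0L) {
          nm <- nm + 1L
          merges[nm, ] <- c(comp_node[ri], comp_node[rj])
          heights[nm] <- e[i]  # current threshold level
          node <- nm
        } else {
          node <- if (comp_min[ri] > 0L) comp_node[ri] else comp_node[rj]
        }
        parent[rj] <- ri
        comp_min[ri] <- max(comp_min[ri], comp_min[rj])
        comp_node[ri] <- node
        if (nm == M - 1L) break
      }
      if (nm == M - 1L) break
    }
    if (nm == M - 1L) break
  }
  if (nm != M - 1L) {
    stop("disconnectivity sweep failed to join all minima", call. = FALSE)
  }
  structure(list(minima = minima, merge = merges, height = heights,
                 labels = labels),
            class = "disconnectivity_tree")
}

#' @export
print.disconnectivity_tree <- function(x, ...) {
  cat("Disconnectivity tree:", nrow(x$minima), "local minima,",
      length(x$height), "branch point(s)\n")
  if (length(x$height)) {
    cat("  branch energies:", paste(signif(x$height, 4), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# hclust view of the tree, for cutree(); heights are branch energies and
# may be negative, which cutree() accepts.
as_hclust <- function(tree) {
  stopifnot(inherits(tree, "disconnectivity_tree"))
  if (length(tree$height) == 0) {
    stop("tree with a single leaf has no hclust representation",
         call. = FALSE)
  }
  structure(list(merge = tree$merge, height = tree$height,
                 order = tree_leaf_order(tree), labels = tree$labels,
                 method = "disconnectivity", call = match.call(),
                 dist.method = "saddle energy"),
            class = "hclust")
}

# left-to-right leaf order by recursive traversal of the merge matrix
tree_leaf_order <- function(tree) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(tree$merge[node, 1]), walk(tree$merge[node, 2]))
  }
  walk(nrow(tree$merge))
}

#' Export a disconnectivity tree in Newick format
#'
#' Leaves are the local minima (`min1`, `min2`, ...); each branch length is
#' the parent's separation-threshold energy minus the child's energy (leaf
#' energy for terminal branches, branch energy for internal ones), so leaf
#' depth below the root reflects well depth.
#'
#' @param tree a `disconnectivity_tree`.
#' @param file optional path; when given the string is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
write_newick <- function(tree, file = NULL) {
  stopifnot(inherits(tree, "disconnectivity_tree"))
  node_str <- function(node, parent_h) {
    if (node < 0) {
      lab <- tree$labels[-node]
      h <- tree$minima$energy[-node]
    } else {
      h <- tree$height[node]
      lab <- paste0("(", node_str(tree$merge[node, 1], h), ",",
                    node_str(tree$merge[node, 2], h), ")")
    }
    if (is.na(parent_h)) lab else paste0(lab, ":", format(parent_h - h))
  }
  root <- if (length(tree$height) == 0) -1L else nrow(tree$merge)
  s <- paste0(node_str(root, NA_real_), ";")
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Plot a disconnectivity tree
#'
#' Simple base-graphics rendering: vertical leaf positions at the minima
#' energies, branch points at their separation-threshold energies.
#'
#' @param x a `disconnectivity_tree`.
#' @param ... passed to [graphics::plot.default].
#' @export
plot.disconnectivity_tree <- function(x, ...) {
  M <- nrow(x$minima)
  ord <- if (M > 1) tree_leaf_order(x) else 1L
  xpos_leaf <- order(ord)
  pos <- function(node) {
    if (node < 0) {
      c(xpos_leaf[-node], x$minima$energy[-node])
    } else {
      a <- pos(x$merge[node, 1]); b <- pos(x$merge[node, 2])
      c((a[1] + b[1]) / 2, x$height[node])
    }
  }
  ylim <- range(x$minima$energy, x$height)
  graphics::plot(NA, xlim = c(0.5, M + 0.5), ylim = ylim, xaxt = "n",
                 xlab = "local minimum", ylab = "energy", ...)
  graphics::axis(1, at = xpos_leaf, labels = x$labels)
  draw <- function(node) {
    if (node < 0) return(pos(node))
    a <- draw(x$merge[node, 1]); b <- draw(x$merge[node, 2])
    h <- x$height[node]
    graphics::segments(a[1], a[2], a[1], h)
    graphics::segments(b[1], b[2], b[1], h)
    graphics::segments(a[1], h, b[1], h)
    c((a[1] + b[1]) / 2, h)
  }
  if (M > 1) draw(nrow(x$merge))
  graphics::points(xpos_leaf, x$minima$energy, pch = 19)
  invisible(x)
}

#' Group local minima into brain states
#'
#' Either honors an explicit mapping from minima to states, or cuts the
#' disconnectivity tree into `k` subtrees by removing its `k - 1` highest
#' branch points and labels each subtree a state. States are numbered by
#' the label of the lowest-energy minimum they contain, so state 1 always
#' holds minimum 1.
#'
#' @param tree a `disconnectivity_tree`.
#' @param mapping integer vector of state ids, one per minimum (in minima
#'   label order), or a named vector/list keyed by `"min<label>"`.
#' @param k number of states for the automatic tree cut (used when
#'   `mapping` is missing).
#' @return A `state_definition` object: `state_of_minimum` (integer per
#'   minimum label), `n_states`.
#' @export
group_minima_into_states <- function(tree, mapping = NULL, k = NULL) {
  stopifnot(inherits(tree, "disconnectivity_tree"))
  M <- nrow(tree$minima)
  if (!is.null(mapping)) {
    if (!is.null(names(mapping))) {
      if (!setequal(names(mapping), tree$labels)) {
        stop("mapping must cover every local minimum exactly once",
             call. = FALSE)
      }
      mapping <- unlist(mapping)[tree$labels]
    }
    mapping <- as.integer(factor(unlist(mapping)))
    if (length(mapping) != M || anyNA(mapping)) {
      stop("mapping must assign a state to every local minimum",
           call. = FALSE)
    }
    s <- mapping
  } else {
    if (is.null(k)) stop("supply either `mapping` or `k`", call. = FALSE)
    if (k < 1 || k > M) stop("k must be in [1, number of minima]",
                             call. = FALSE)
    s <- if (M == 1 || k == 1) rep(1L, M) else
      unname(stats::cutree(as_hclust(tree), k = k))
  }
  # renumber states by their deepest (lowest-label) minimum
  first <- vapply(split(seq_len(M), s), min, integer(1))
  relab <- integer(max(s))
  relab[as.integer(names(first))[order(first)]] <- seq_along(first)
  s <- relab[s]
  structure(list(state_of_minimum = s, n_states = max(s)),
            class = "state_definition")
}

#' @export
print.state_definition <- function(x, ...) {
  cat("State definition:", x$n_states, "states\n")
  for (st in seq_len(x$n_states)) {
    cat("  state", st, ": minima",
        paste(which(x$state_of_minimum == st), collapse = ", "), "\n")
  }
  invisible(x)
}
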