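#' Descending multiplicity grid for the threshold sweep
#'
#' The mutative threshold is T_c = c * max_ij a_ij with the multiplicity c
#' swept over a descending grid, by default 1.00 down to 0.10 in steps of
#' 0.01 (matching the two-decimal reporting of merge multiplicities).
#'
#' @param c_max,c_min Grid end points in (0, 1], `c_max > c_min`.
#' @param step Grid spacing.
#' @return Strictly descending numeric vector of multiplicities.
#' @export
threshold_grid <- function(c_max = 1, c_min = 0.1, step = 0.01) {
  stopifnot(c_max > c_min, c_min > 0, c_max <= 1, step > 0)
  g <- round(seq(c_max, c_min, by = -step), 10)
  g[g > 0]
}

#' Exact multiplicity grid induced by the data
#'
#' The component partition can only change where the threshold T_c = c *
#' max(a) crosses a distinct positive weight, so the finest meaningful grid
#' is the descending set of ratios a_ij / max(a). Sweeping this grid
#' exposes every level of the merge hierarchy, whereas any fixed step can
#' alias two nearby levels into one. A small relative backoff keeps each
#' grid value's threshold from floating just above its own defining weight.
#'
#' @param adj A normalized `mi_adjacency`.
#' @param c_min Smallest multiplicity retained (default 0, i.e. all levels;
#'   use 0.1 to match the default reporting range).
#' @return Strictly descending numeric vector of multiplicities in (0, 1].
#' @export
exact_threshold_grid <- function(adj, c_min = 0) {
  stopifnot(inherits(adj, "mi_adjacency"))
  if (!isTRUE(adj$normalized)) abort("adjacency must be normalized first")
  w <- adj$weights[upper.tri(adj$weights)]
  w <- w[w > 0]
  if (length(w) == 0L) abort("no edges to threshold: all-zero adjacency")
  r <- sort(unique(w / max(w)), decreasing = TRUE) * (1 - 1e-9)
  r <- round(pmin(r, 1), 12)
  r[r >= c_min & r > 0]
}

#' Filter an adjacency matrix at a threshold multiplicity
#'
#' Sets to zero every entry below the mutative threshold
#' T_c = c * max_ij a_ij (entries equal to the threshold survive); other
#' entries are unchanged. Filtering is idempotent at a fixed c.
#'
#' @param adj A normalized `mi_adjacency`.
#' @param c Threshold multiplicity in (0, 1].
#' @return A filtered `mi_adjacency` carrying `c` and the absolute
#'   `threshold`.
#' @export
filter_adjacency <- function(adj, c) {
  stopifnot(inherits(adj, "mi_adjacency"), c > 0, c <= 1)
  if (!isTRUE(adj$normalized)) abort("adjacency must be normalized first")
  amax <- max_offdiag(adj$weights)
  if (amax <= 0) abort("no edges to threshold: all-zero adjacency")
  tc <- c * amax
  w <- adj$weights
  w[w < tc] <- 0
  diag(w) <- 0
  new_mi_adjacency(w, adj$ids, entropy = adj$entropy, base = adj$base,
                   normalized = TRUE, filtered = TRUE, c = c, threshold = tc,
                   n_clipped = adj$n_clipped)
}

max_offdiag <- function(w) {
  d <- diag(w)
  diag(w) <- -Inf
  m <- max(w)
  if (!is.finite(m)) m <- 0
  m
}

#' Connected components of a (filtered) adjacency matrix
#'
#' Partitions the nodes into maximal sets mutually reachable through
#' strictly positive entries. Blocks are numbered deterministically by their
#' smallest member index.
#'
#' @param adj An `mi_adjacency`; typically already filtered. If `c` is given
#'   the matrix is filtered at that multiplicity first.
#' @param c Optional threshold multiplicity (see [filter_adjacency()]).
#' @return A tibble with columns `id` and `block` (class `mi_partition`),
#'   with attributes `c`, `threshold` and `n_blocks`.
#' @export
connected_components <- function(adj, c = NULL) {
  stopifnot(inherits(adj, "mi_adjacency"))
  if (!is.null(c)) adj <- filter_adjacency(adj, c)
  g <- igraph::graph_from_adjacency_matrix(adj$weights > 0,
                                           mode = "undirected", diag = FALSE)
  member <- igraph::components(g)$membership
  new_mi_partition(canonical_blocks(member), adj)
}

new_mi_partition <- function(block, adj) {
  out <- tibble(id = adj$ids, block = block)
  class(out) <- c("mi_partition", class(out))
  attr(out, "c") <- adj$c
  attr(out, "threshold") <- adj$threshold
  attr(out, "n_blocks") <- max(block)
  out
}

# renumber membership so block 1 contains node 1, block 2 the smallest
# node not in block 1, etc. (deterministic ordering)
canonical_blocks <- function(member) {
  as.integer(match(member, unique(member)))
}

#' Connected components via summed adjacency-matrix powers
#'
#' The matrix formulation of component extraction: powers of the filtered
#' adjacency matrix A detect paths, and the sum over powers s = 1..N-1 is
#' positive exactly where two distinct nodes are connected; components are
#' the maximal index sets whose pairwise summed entries are all positive
#' (the block-diagonal reading of the summed matrix). The identity (path
#' length 0) is included in the sum so that singleton blocks are
#' well-defined; connected pairs are unaffected. Agrees with
#' [connected_components()] on every input and serves as its cross-check.
#'
#' @param adj A filtered `mi_adjacency`.
#' @return An `mi_partition` tibble (see [connected_components()]).
#' @export
components_by_matrix_power <- function(adj) {
  stopifnot(inherits(adj, "mi_adjacency"))
  w <- adj$weights
  n <- nrow(w)
  acc <- diag(n)
  p <- diag(n)
  for (s in seq_len(n - 1L)) {
    p <- p %*% w
    acc <- acc + p
  }
  reach <- acc > 0
  member <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    if (member[i] == 0L) {
      nb <- nb + 1L
      member[reach[i, ]] <- nb
    }
  }
  new_mi_partition(canonical_blocks(member), adj)
}

resolve_node <- function(adj, node) {
  if (is.character(node)) {
    i <- match(node, adj$ids)
    if (is.na(i)) abort(paste0("unknown id: ", node))
    return(i)
  }
  i <- as.integer(node)
  if (i < 1L || i > length(adj$ids)) abort("node index out of range")
  i
}

#' Connectivity profile of a node pair across the threshold grid
#'
#' For each multiplicity c the adjacency matrix is filtered and the
#' connectivity value
#' abar(i, j) = (1 / (N - 1)) * sum_{n = 1..N-1} (A^n)_ij ^ (1/n)
#' is computed from the powers of the filtered matrix. The two nodes lie in
#' one connected component at c exactly when abar(i, j) > 0, so the profile
#' traces how a relationship survives as the threshold rises.
#'
#' @param adj A normalized `mi_adjacency`.
#' @param i,j Node ids (character) or indices; must differ.
#' @param grid Descending multiplicity grid (see [threshold_grid()]).
#' @return A tibble with columns `c`, `threshold`, `connectivity`.
#' @export
connectivity_profile <- function(adj, i, j, grid = threshold_grid()) {
  stopifnot(inherits(adj, "mi_adjacency"))
  if (!isTRUE(adj$normalized)) abort("adjacency must be normalized first")
  ii <- resolve_node(adj, i)
  jj <- resolve_node(adj, j)
  if (ii == jj) abort("i and j must be different nodes")
  n <- length(adj$ids)
  res <- purrr::map_dfr(grid, function(cc) {
    f <- filter_adjacency(adj, cc)
    fw <- unname(f$weights)
    p <- diag(n)
    val <- 0
    for (s in seq_len(n - 1L)) {
      p <- p %*% fw
      val <- val + p[ii, jj]^(1 / s)
    }
    tibble(c = cc, threshold = f$threshold, connectivity = val / (n - 1L))
  })
  class(res) <- c("mi_profile", class(res))
  attr(res, "ids") <- adj$ids[c(ii, jj)]
  res
}

#' Line plot of a connectivity profile
#'
#' @param object A tibble from [connectivity_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_profile <- function(object, ...) {
  ids <- attr(object, "ids")
  ggplot2::ggplot(object, ggplot2::aes(.data$c, .data$connectivity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "threshold multiplicity c",
                  y = "connectivity value",
                  title = if (!is.null(ids)) paste(ids, collapse = " - ")) +
    ggplot2::theme_minimal()
}

#' Largest multiplicity at which two nodes share a component
#'
#' The merge multiplicity of a pair: the largest grid c at which i and j lie
#' in one connected component of the filtered matrix. It equals the
#' bottleneck similarity of the pair (the best worst edge over all
#' connecting paths, computed here via a maximum spanning tree) divided by
#' the maximum adjacency entry, floored to the grid; `NA` if the pair is
#' never connected on the grid.
#'
#' @param adj A normalized `mi_adjacency`.
#' @param i,j Node ids or indices; must differ.
#' @param grid Descending multiplicity grid.
#' @return A single grid multiplicity, or `NA_real_`.
#' @export
merge_multiplicity <- function(adj, i, j, grid = threshold_grid()) {
  stopifnot(inherits(adj, "mi_adjacency"))
  if (!isTRUE(adj$normalized)) abort("adjacency must be normalized first")
  ii <- resolve_node(adj, i)
  jj <- resolve_node(adj, j)
  if (ii == jj) abort("i and j must be different nodes")
  amax <- max_offdiag(adj$weights)
  if (amax <= 0) return(NA_real_)
  g <- igraph::graph_from_adjacency_matrix(adj$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  memb <- igraph::components(g)$membership
  if (memb[ii] != memb[jj]) return(NA_real_)
  # bottleneck path lives on the maximum spanning tree
  mst <- igraph::mst(g, weights = -igraph::E(g)$weight)
  path <- igraph::shortest_paths(mst, from = ii, to = jj,
                                 output = "epath")$epath[[1]]
  b <- min(igraph::E(mst)$weight[as.integer(path)])
  ok <- grid[grid * amax <= b + 1e-12]
  if (length(ok) == 0L) return(NA_real_)
  max(ok)
}
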