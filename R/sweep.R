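#' Sweep the threshold grid and build the nested merge hierarchy
#'
#' Computes the connected components at every grid multiplicity from high to
#' low. Because raising the threshold can only remove edges, the partition
#' at a higher c refines the partition at any lower c, so the component sets
#' nest into a tree: each internal node records the first (largest) grid c
#' at which two or more blocks unite. Ties (three or more blocks uniting at
#' one c) are kept as a single multi-way merge rather than an arbitrary
#' binary order. The merge structure is that of single-linkage clustering on
#' dissimilarity max(a) - a, with heights floored to the grid.
#'
#' @param adj A normalized `mi_adjacency`.
#' @param grid Descending multiplicity grid (see [threshold_grid()]).
#' @return An object of class `mi_merge_tree`: fields `leaves`, `grid`,
#'   `root` (nested list with `c`, `members`, `children`; `c` is `NA` for
#'   leaves and for a virtual root joining a forest), `events` (tibble of
#'   merge events) and `memberships` (long tibble `c`, `id`, `block`).
#' @export
sweep_components <- function(adj, grid = threshold_grid()) {
  stopifnot(inherits(adj, "mi_adjacency"))
  if (!isTRUE(adj$normalized)) abort("adjacency must be normalized first")
  ids <- adj$ids
  n <- length(ids)
  # current subtree roots, one per open block; start as leaves
  roots <- lapply(seq_len(n), function(i) {
    list(c = NA_real_, members = i, children = NULL)
  })
  root_of <- seq_len(n)  # block index of each node's current root
  events <- list()
  memberships <- vector("list", length(grid))
  for (k in seq_along(grid)) {
    cc <- grid[k]
    part <- connected_components(adj, c = cc)
    memberships[[k]] <- tibble(c = cc, id = ids, block = part$block)
    groups <- split(seq_len(n), part$block)
    for (grp in groups) {
      rs <- unique(root_of[grp])
      if (length(rs) >= 2L) {
        node <- list(c = cc, members = sort(unlist(
          lapply(roots[rs], `[[`, "members"))),
          children = roots[rs])
        new_idx <- min(rs)
        roots[[new_idx]] <- node
        roots[rs[rs != new_idx]] <- list(NULL)
        root_of[node$members] <- new_idx
        events[[length(events) + 1L]] <- tibble(
          c = cc, size = length(node$members), n_children = length(rs),
          members = list(ids[node$members]))
      }
    }
  }
  open <- unique(root_of)
  root <- if (length(open) == 1L) {
    roots[[open]]
  } else {
    list(c = NA_real_, members = seq_len(n), children = roots[open])
  }
  structure(
    list(leaves = ids, grid = grid, root = root,
         events = if (length(events)) dplyr::bind_rows(events) else
           tibble(c = numeric(), size = integer(), n_children = integer(),
                  members = list()),
         memberships = dplyr::bind_rows(memberships)),
    class = "mi_merge_tree")
}

#' @export
print.mi_merge_tree <- function(x, ...) {
  nb <- dplyr::n_distinct(x$memberships$block[
    x$memberships$c == min(x$grid)])
  cat(sprintf(
    "<mi_merge_tree> %d leaves, %d merge events on grid [%g, %g], %d block(s) at c = %g\n",
    length(x$leaves), nrow(x$events), min(x$grid), max(x$grid), nb,
    min(x$grid)))
  invisible(x)
}

#' Tidy a merge tree into its merge events
#'
#' @param x An `mi_merge_tree`.
#' @param ... Unused.
#' @return A tibble with one row per merge event: `c` (grid multiplicity at
#'   which blocks united), `size`, `n_children`, and a `members` list-column
#'   of ids.
#' @export
tidy.mi_merge_tree <- function(x, ...) x$events

#' One-row summary of a merge tree
#'
#' @param x An `mi_merge_tree`.
#' @param ... Unused.
#' @return A one-row tibble: `n_leaves`, `n_merges`, `c_max_grid`,
#'   `c_min_grid`, `n_blocks_final`, and `c_fully_connected` (largest grid c
#'   with a single component, `NA` if never).
#' @export
glance.mi_merge_tree <- function(x, ...) {
  per_c <- dplyr::summarise(dplyr::group_by(x$memberships, .data$c),
                            n_blocks = dplyr::n_distinct(.data$block))
  full <- per_c$c[per_c$n_blocks == 1L]
  tibble(n_leaves = length(x$leaves), n_merges = nrow(x$events),
         c_max_grid = max(x$grid), c_min_grid = min(x$grid),
         n_blocks_final = per_c$n_blocks[which.min(per_c$c)],
         c_fully_connected = if (length(full)) max(full) else NA_real_)
}

#' Component-count profile of a merge tree
#'
#' Plots the number of connected components against the threshold
#' multiplicity; each step down is a merge event.
#'
#' @param object An `mi_merge_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_merge_tree <- function(object, ...) {
  per_c <- dplyr::summarise(
    dplyr::group_by(object$memberships, .data$c),
    n_blocks = dplyr::n_distinct(.data$block), .groups = "drop")
  ggplot2::ggplot(per_c, ggplot2::aes(.data$c, .data$n_blocks)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "threshold multiplicity c",
                  y = "number of connected components") +
    ggplot2::theme_minimal()
}

#' Partition of a merge tree at one grid multiplicity
#'
#' @param tree An `mi_merge_tree`.
#' @param c A multiplicity present in the tree's grid.
#' @return A tibble `id`, `block`.
#' @export
cut_merge_tree <- function(tree, c) {
  stopifnot(inherits(tree, "mi_merge_tree"))
  hit <- abs(tree$grid - c) < 1e-9
  if (!any(hit)) abort("c is not on the sweep grid")
  out <- tree$memberships[abs(tree$memberships$c - tree$grid[which(hit)[1]]) <
                            1e-12, c("id", "block")]
  as_tibble(out)
}

#' Export a merge tree as Newick
#'
#' Internal nodes are labelled with the merge multiplicity c at which their
#' children united; a virtual unlabelled root joins a forest. Leaf ids have
#' Newick-unsafe characters replaced by `_`.
#'
#' @param tree An `mi_merge_tree`.
#' @return A single Newick string (terminated by `;`).
#' @export
merge_tree_newick <- function(tree) {
  stopifnot(inherits(tree, "mi_merge_tree"))
  safe <- function(s) gsub("[^A-Za-z0-9_.|-]", "_", s)
  rec <- function(node) {
    if (is.null(node$children)) return(safe(tree$leaves[node$members]))
    lab <- if (is.na(node$c)) "" else formatC(node$c, format = "g")
    paste0("(", paste(vapply(node$children, rec, character(1)),
                      collapse = ","), ")", lab)
  }
  paste0(rec(tree$root), ";")
}

#' Export a merge tree as nested JSON
#'
#' Writes (or returns) the nested `{c, members, children}` representation of
#' the hierarchy.
#'
#' @param tree An `mi_merge_tree`.
#' @param path Optional output path; if `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
merge_tree_json <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "mi_merge_tree"))
  rec <- function(node) {
    out <- list(c = if (is.na(node$c)) NULL else node$c,
                members = as.list(tree$leaves[node$members]))
    if (!is.null(node$children)) out$children <- lapply(node$children, rec)
    out
  }
  js <- jsonlite::toJSON(rec(tree$root), auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(path)
}
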