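#' Shannon entropy of a discrete series
#'
#' Plug-in entropy H = -sum_a p(a) log p(a) over the empirical state
#' frequencies of the series, with 0 log 0 = 0.
#'
#' @param series Integer vector of states >= 1 (length >= 1).
#' @param base Logarithm base; default 2 (bits).
#' @return Nonnegative entropy; 0 iff the series is constant.
#' @examples
#' shannon_entropy(c(1L, 2L, 3L, 4L))  # 2 bits
#' @export
shannon_entropy <- function(series, base = 2) {
  series <- check_series(series)
  p <- tabulate(series)
  p <- p[p > 0] / length(series)
  -sum(p * log(p)) / log(base)
}

#' Mutual information between two equal-length discrete series
#'
#' Plug-in mutual information
#' I = sum_{a,b} p(a,b) log\[p(a,b) / (p(a) p(b))\], where p(a,b) is the
#' empirical frequency of the position-paired states (x_t, y_t) and the
#' marginals are the per-series empirical frequencies. The summation runs
#' over state combinations, not positions, so the quantity depends only on
#' the state distributions.
#'
#' @param x,y Integer state series of equal length.
#' @param base Logarithm base; default 2 (bits).
#' @return Nonnegative mutual information, bounded by min(H(x), H(y)).
#' @examples
#' mutual_information(c(1L, 2L, 1L, 2L), c(1L, 2L, 1L, 2L))  # = H(x) = 1 bit
#' @export
mutual_information <- function(x, y, base = 2) {
  x <- check_series(x); y <- check_series(y)
  if (length(x) != length(y)) abort("series must have equal length")
  K <- max(x, y)
  cpp_mutual_information(x, y, K) / log(base)
}

#' Maximum sliding-window mutual information between two series
#'
#' The pairwise similarity of the method: the shorter series (length M) is
#' slid along the longer (length N) and the mutual information with each of
#' the N - M + 1 length-M windows is computed; the maximum is returned. This
#' makes the comparison alignment-free and total for unequal lengths, and it
#' is symmetric in its arguments. Among equally maximal offsets the smallest
#' is reported.
#'
#' @param x,y Integer state series (length >= 1 each).
#' @param base Logarithm base; default 2 (bits).
#' @return A list with `value` (the maximum MI) and `offset` (smallest
#'   1-based window start in the longer series attaining it).
#' @examples
#' max_mutual_information(c(1L, 2L, 3L), c(4L, 1L, 2L, 3L, 4L))$value  # log2(3)
#' @export
max_mutual_information <- function(x, y, base = 2) {
  x <- check_series(x); y <- check_series(y)
  if (length(x) <= length(y)) { s <- x; l <- y } else { s <- y; l <- x }
  K <- max(x, y)
  res <- cpp_max_mutual_information(s, l, K)
  list(value = res$value / log(base), offset = res$offset)
}

check_series <- function(series) {
  if (is.numeric(series) && !is.integer(series)) {
    stopifnot(all(series == as.integer(series)))
    series <- as.integer(series)
  }
  if (length(series) < 1L) abort("series must have length >= 1")
  if (anyNA(series) || any(series < 1L)) {
    abort("series must contain positive integer states only")
  }
  series
}

#' Build the maximum mutual-information adjacency matrix
#'
#' Computes the pairwise maximum sliding-window mutual information for every
#' unordered pair of series (computed once and mirrored, so the matrix is
#' exactly symmetric), with diagonal fixed to 0 by convention so that the
#' thresholding step is driven by inter-protein relations only. Also returns
#' the per-series entropies used later for normalization.
#'
#' @param data A tibble with an `id` column and either a `series` list-column
#'   of integer state vectors or a `residues` character column (encoded on
#'   the fly), or a named list of integer state vectors.
#' @param base Logarithm base; default 2 (bits).
#' @return An object of class `mi_adjacency`: unnormalized weights, ids,
#'   entropy vector, log base.
#' @export
build_adjacency <- function(data, base = 2) {
  if (is.data.frame(data)) {
    if (!"series" %in% names(data)) data <- encode_proteins(data)
    ids <- data$id
    series <- data$series
  } else if (is.list(data)) {
    ids <- names(data)
    if (is.null(ids)) ids <- paste0("s", seq_along(data))
    series <- data
  } else {
    abort("data must be a tibble of records or a list of series")
  }
  series <- lapply(series, check_series)
  n <- length(series)
  if (n < 2L) abort("at least 2 series are required")
  if (anyDuplicated(ids)) abort("duplicate series ids")
  h <- vapply(series, shannon_entropy, numeric(1), base = base)
  names(h) <- ids
  if (all(h == 0)) abort("degenerate dataset: all series have zero entropy")
  w <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- max_mutual_information(series[[i]], series[[j]], base = base)$value
      w[i, j] <- v
      w[j, i] <- v
    }
  }
  new_mi_adjacency(w, ids, entropy = h, base = base, normalized = FALSE)
}

#' Wrap a precomputed similarity matrix as an adjacency object
#'
#' Entry point for externally computed symmetric similarity matrices, and
#' the constructor used when a matrix is read back from CSV. The diagonal is
#' forced to 0 (the package convention: thresholds are driven by
#' inter-protein relations only).
#'
#' @param weights Square symmetric numeric matrix; dimnames, if present,
#'   supply the ids.
#' @param ids Record identifiers; defaults to dimnames or `s1..sN`.
#' @param normalized Whether entries are already on the \[0, 1\] scale.
#' @param base Log base recorded on the object.
#' @param entropy Optional named per-record entropy vector.
#' @return An `mi_adjacency`.
#' @export
as_mi_adjacency <- function(weights, ids = NULL, normalized = TRUE,
                            base = 2, entropy = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == ncol(weights))
  if (max(abs(weights - t(weights))) > 1e-9) {
    abort("weights must be symmetric")
  }
  if (is.null(ids)) ids <- rownames(weights)
  if (is.null(ids)) ids <- paste0("s", seq_len(nrow(weights)))
  weights <- (weights + t(weights)) / 2
  diag(weights) <- 0
  dimnames(weights) <- list(ids, ids)
  new_mi_adjacency(weights, ids, entropy = entropy, base = base,
                   normalized = normalized)
}

new_mi_adjacency <- function(weights, ids, entropy = NULL, base = 2,
                             normalized = FALSE, filtered = FALSE,
                             c = NULL, threshold = NULL, n_clipped = 0L) {
  structure(
    list(weights = weights, ids = ids, entropy = entropy, base = base,
         normalized = normalized, filtered = filtered, c = c,
         threshold = threshold, n_clipped = n_clipped),
    class = "mi_adjacency")
}

#' Normalize an adjacency matrix by the maximum entropy
#'
#' Divides every off-diagonal entry by max_q H_q, the largest per-series
#' entropy in the dataset. Because each windowed MI is bounded by the entropy
#' of the (full) shorter series, all normalized entries lie in \[0, 1\]; any
#' float residue above 1 would be clipped with a warning (the `n_clipped`
#' counter records how often, expected 0).
#'
#' @param adj An unnormalized `mi_adjacency` from [build_adjacency()].
#' @return The normalized `mi_adjacency`.
#' @export
normalize_adjacency <- function(adj) {
  stopifnot(inherits(adj, "mi_adjacency"))
  if (isTRUE(adj$normalized)) abort("adjacency is already normalized")
  if (is.null(adj$entropy)) abort("entropy vector is required to normalize")
  hmax <- max(adj$entropy)
  if (hmax <= 0) abort("zero maximum entropy: cannot normalize")
  w <- adj$weights / hmax
  diag(w) <- 0
  n_clipped <- sum(w > 1)
  if (n_clipped > 0L) {
    warn(sprintf("clipped %d entries above 1 after normalization", n_clipped))
    w[w > 1] <- 1
  }
  new_mi_adjacency(w, adj$ids, entropy = adj$entropy, base = adj$base,
                   normalized = TRUE, n_clipped = n_clipped)
}

#' @export
print.mi_adjacency <- function(x, ...) {
  cat(sprintf("<mi_adjacency> %d proteins, %s%s\n", length(x$ids),
              if (x$normalized) "normalized" else "unnormalized",
              if (x$filtered)
                sprintf(", filtered at c = %g (T = %.6g)", x$c, x$threshold)
              else ""))
  off <- x$weights[upper.tri(x$weights)]
  if (length(off)) {
    cat(sprintf("  weights: min %.6g, max %.6g (log base %g)\n",
                min(off), max(off), x$base))
  }
  invisible(x)
}

#' Tidy an adjacency matrix into an edge tibble
#'
#' @param x An `mi_adjacency`.
#' @param ... Unused.
#' @return A tibble with one row per unordered pair: `id_i`, `id_j`,
#'   `weight`.
#' @export
tidy.mi_adjacency <- function(x, ...) {
  n <- length(x$ids)
  idx <- which(upper.tri(x$weights), arr.ind = TRUE)
  tibble(id_i = x$ids[idx[, 1]], id_j = x$ids[idx[, 2]],
         weight = x$weights[idx]) |>
    dplyr::arrange(match(.data$id_i, x$ids), match(.data$id_j, x$ids))
}

#' One-row summary of an adjacency matrix
#'
#' @param x An `mi_adjacency`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `normalized`, `base`, `max_weight`,
#'   `max_entropy`, `n_clipped`.
#' @export
glance.mi_adjacency <- function(x, ...) {
  off <- x$weights[upper.tri(x$weights)]
  tibble(n = length(x$ids), normalized = x$normalized, base = x$base,
         max_weight = if (length(off)) max(off) else NA_real_,
         max_entropy = if (is.null(x$entropy)) NA_real_ else max(x$entropy),
         n_clipped = x$n_clipped)
}

#' Heatmap of an adjacency matrix
#'
#' A color-mapped view of the similarity matrix:
#' weights from minimum (dark) to maximum (bright), ids in dataset order.
#'
#' @param object An `mi_adjacency`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mi_adjacency <- function(object, ...) {
  df <- expand.grid(id_i = object$ids, id_j = object$ids,
                    stringsAsFactors = FALSE)
  df$weight <- as.vector(object$weights)
  df$id_i <- factor(df$id_i, levels = object$ids)
  df$id_j <- factor(df$id_j, levels = rev(object$ids))
  ggplot2::ggplot(df, ggplot2::aes(.data$id_i, .data$id_j,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "similarity") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}

#' Write / read an adjacency matrix as CSV
#'
#' The CSV carries a header row of ids, then the full symmetric matrix at 12
#' significant digits with the ids as a leading column, so it round-trips
#' through [read_adjacency()] and loads cleanly in external tools.
#'
#' @param adj An `mi_adjacency`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adj, path) {
  stopifnot(inherits(adj, "mi_adjacency"))
  m <- format_sig(adj$weights)
  df <- data.frame(id = adj$ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", adj$ids)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjacency
#' @param normalized Whether the stored matrix is on the normalized \[0, 1\]
#'   scale (default `TRUE`, the scale the pipeline writes).
#' @param base Log base recorded on the returned object.
#' @return `read_adjacency()` returns an `mi_adjacency` (without entropies).
#' @export
read_adjacency <- function(path, normalized = TRUE, base = 2) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  w <- as.matrix(df[, -1, drop = FALSE])
  mode(w) <- "numeric"
  dimnames(w) <- list(ids, ids)
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-9))) {
    abort("adjacency CSV is not symmetric")
  }
  w <- (w + t(w)) / 2  # restore exact symmetry after text round-trip
  new_mi_adjacency(w, ids, entropy = NULL, base = base,
                   normalized = normalized)
}

#' Write per-series entropies as a two-column CSV
#'
#' @param adj An `mi_adjacency` carrying entropies.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_entropy <- function(adj, path) {
  stopifnot(inherits(adj, "mi_adjacency"), !is.null(adj$entropy))
  df <- data.frame(id = adj$ids, H = format_sig(unname(adj$entropy)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

format_sig <- function(x, digits = 12) {
  y <- formatC(x, digits = digits, format = "g")
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}
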