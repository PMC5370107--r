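# Independent brute-force oracles. These deliberately avoid the package's
# code paths (no Rcpp, no igraph): plain loops over state combinations,
# breadth-first search over matrices, and the closed-form dihedral via
# normal vectors, so implementation and oracle can only agree by being
# right.

oracle_entropy <- function(x, base = 2) {
  p <- as.vector(table(x)) / length(x)
  -sum(p * log(p)) / log(base)
}

oracle_mi <- function(x, y, base = 2) {
  stopifnot(length(x) == length(y))
  L <- length(x)
  mi <- 0
  for (a in unique(x)) {
    for (b in unique(y)) {
      pab <- sum(x == a & y == b) / L
      if (pab > 0) {
        mi <- mi + pab * log(pab / ((sum(x == a) / L) * (sum(y == b) / L)))
      }
    }
  }
  mi / log(base)
}

oracle_max_mi <- function(x, y, base = 2) {
  if (length(x) > length(y)) { tmp <- x; x <- y; y <- tmp }
  m <- length(x)
  vals <- vapply(seq_len(length(y) - m + 1),
                 function(i) oracle_mi(x, y[i:(i + m - 1)], base),
                 numeric(1))
  list(value = max(vals), offset = which.max(vals))
}

oracle_adjacency <- function(series, base = 2) {
  n <- length(series)
  w <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      w[i, j] <- w[j, i] <- oracle_max_mi(series[[i]], series[[j]],
                                          base)$value
    }
  }
  w
}

# dihedral via normal-vector cosine with an explicit sign term
oracle_dihedral <- function(p1, p2, p3, p4) {
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  cosang <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (sum(cr(n1, n2) * b2) < 0) ang <- -ang
  if (ang >= 180) ang <- ang - 360
  ang
}

# connected components by breadth-first search over positive entries
bfs_components <- function(w) {
  n <- nrow(w)
  member <- integer(n)
  blk <- 0L
  for (s in seq_len(n)) {
    if (member[s] > 0L) next
    blk <- blk + 1L
    queue <- s
    member[s] <- blk
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(w[v, ] > 0 & member == 0L)
      member[nb] <- blk
      queue <- c(queue, nb)
    }
  }
  match(member, unique(member))
}

random_series <- function(len, K = 20) sample.int(K, len, replace = TRUE)

# random symmetric weight matrix on [0, 1] with zero diagonal and a share
# of absent edges; max entry scaled to `wmax`
random_norm_adjacency <- function(n, p_edge = 0.6, wmax = 1) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  on <- up[stats::runif(length(up)) < p_edge]
  w[on] <- stats::runif(length(on))
  w <- w + t(w)
  if (max(w) > 0) w <- w * (wmax / max(w))
  ids <- paste0("s", seq_len(n))
  dimnames(w) <- list(ids, ids)
  as_mi_adjacency(w, normalized = TRUE)
}

partition_same <- function(b1, b2) {
  identical(match(b1, unique(b1)), match(b2, unique(b2)))
}

# is there a grid level whose blocks coincide exactly with `truth`?
recovers_families <- function(tree, ids, truth) {
  truth <- truth[match(ids, ids)]
  for (cc in tree$grid) {
    p <- cut_merge_tree(tree, cc)
    b <- p$block[match(ids, p$id)]
    if (partition_same(b, match(truth, unique(truth)))) return(TRUE)
  }
  FALSE
}

random_rigid_transform <- function() {
  m <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(m)
  rot <- qr.Q(qr_)
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- stats::rnorm(3, sd = 10)
  function(p) as.numeric(rot %*% p + shift)
}

make_fasta <- function(entries, path = tempfile(fileext = ".fasta")) {
  writeLines(unlist(lapply(names(entries), function(h) {
    c(paste0(">", h), entries[[h]])
  })), path)
  path
}
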