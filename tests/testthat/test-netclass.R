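test_that("threshold grid is strictly descending over (0, 1]", {
  g <- threshold_grid()
  expect_equal(length(g), 91)
  expect_equal(g[1], 1)
  expect_equal(g[length(g)], 0.1)
  expect_true(all(diff(g) < 0))
  expect_true(all(g > 0 & g <= 1))
  expect_error(threshold_grid(c_min = 0), "c_min")
})

test_that("filtering zeroes entries below T_c and keeps ties at T_c", {
  w <- matrix(c(0, .9, .2, .9, 0, .5, .2, .5, 0), 3, 3)
  adj <- as_mi_adjacency(w)
  f <- filter_adjacency(adj, 0.5)
  expect_equal(f$threshold, 0.45)
  expect_equal(unname(f$weights[1, 3]), 0)
  expect_equal(unname(f$weights[2, 3]), 0.5)
  expect_equal(unname(f$weights[1, 2]), 0.9)
  # c = 1 keeps only the maximal entry (and exact ties)
  top <- filter_adjacency(adj, 1)
  expect_equal(sum(top$weights > 0), 2)  # the symmetric pair .9
  # ties at the maximum all survive
  wt <- matrix(c(0, .7, .7, .7, 0, .2, .7, .2, 0), 3, 3)
  expect_equal(sum(filter_adjacency(as_mi_adjacency(wt), 1)$weights > 0), 4)
  # idempotence at fixed c
  f2 <- filter_adjacency(f, 0.5)
  expect_equal(f2$weights, f$weights)
  expect_error(filter_adjacency(as_mi_adjacency(matrix(0, 2, 2)), 0.5),
               "no edges")
})

test_that("connected components partition nodes deterministically", {
  # no edges: four singletons
  none <- as_mi_adjacency(matrix(0, 4, 4))
  p <- connected_components(none)
  expect_equal(p$block, 1:4)
  # complete graph: one block
  full <- as_mi_adjacency(matrix(1, 4, 4) - diag(4))
  expect_equal(connected_components(full)$block, rep(1L, 4))
  # path 1-2-3 plus isolated 4
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- .8
  w[2, 3] <- w[3, 2] <- .6
  p <- connected_components(as_mi_adjacency(w))
  expect_equal(p$block, c(1L, 1L, 1L, 2L))
  expect_equal(attr(p, "n_blocks"), 2L)
})

test_that("matrix-power component extraction reproduces explicit cases", {
  # path graph 1-2-3: summed powers positive on the full block
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- .5
  w[2, 3] <- w[3, 2] <- .4
  p <- components_by_matrix_power(as_mi_adjacency(w))
  expect_equal(p$block, rep(1L, 3))
  # two disjoint edges: block-diagonal two-block structure
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- .9
  w[3, 4] <- w[4, 3] <- .7
  p <- components_by_matrix_power(as_mi_adjacency(w))
  expect_equal(p$block, c(1L, 1L, 2L, 2L))
  # single pair with zero edge: two singletons
  p <- components_by_matrix_power(as_mi_adjacency(matrix(0, 2, 2)))
  expect_equal(p$block, 1:2)
})

test_that("union-find, matrix-power and BFS oracle agree on random graphs", {
  withr::with_seed(31, {
    for (k in 1:60) {
      adj <- random_norm_adjacency(sample(2:12, 1), p_edge = runif(1, .1, .9))
      a <- connected_components(adj)$block
      b <- components_by_matrix_power(adj)$block
      expect_identical(a, b)
      expect_true(partition_same(a, bfs_components(adj$weights)))
    }
  })
})

test_that("connectivity profile matches explicit matrix-power expansion", {
  # two nodes joined by one edge: profile equals the edge weight
  w2 <- matrix(c(0, .8, .8, 0), 2, 2)
  prof <- connectivity_profile(as_mi_adjacency(w2), 1, 2,
                               grid = threshold_grid(1, 0.5, 0.25))
  expect_equal(prof$connectivity, rep(.8, 3))
  # 3-node path 1-(.8)-2-(.6)-3 at a c keeping both edges
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- .8
  w[2, 3] <- w[3, 2] <- .6
  adj <- as_mi_adjacency(w)
  prof <- connectivity_profile(adj, 1, 3, grid = 0.5)
  f <- w  # T_c = .4: both edges survive
  expected <- (f[1, 3]^1 + (f %*% f)[1, 3]^(1 / 2)) / 2
  expect_equal(prof$connectivity, expected, tolerance = 1e-9)
  # nodes in different components: all powers vanish
  prof13 <- connectivity_profile(adj, 1, 3, grid = 0.9)
  expect_equal(prof13$connectivity, 0)
  expect_error(connectivity_profile(adj, 2, 2), "different nodes")
})

test_that("threshold sweep records merges at the right multiplicities", {
  # two nodes: the lone edge is the maximum, merge at c = 1
  w2 <- matrix(c(0, .4, .4, 0), 2, 2)
  tr <- sweep_components(as_mi_adjacency(w2))
  expect_equal(nrow(tr$events), 1)
  expect_equal(tr$events$c, 1)
  # triangle .9/.3: pair merges at 1, third node at c = 0.33
  w <- matrix(c(0, .9, .3, .9, 0, .3, .3, .3, 0), 3, 3)
  tr <- sweep_components(as_mi_adjacency(w))
  expect_equal(tr$events$c, c(1, 0.33))
  expect_equal(tr$events$size, c(2L, 3L))
  expect_equal(tr$root$c, 0.33)
  gl <- glance(tr)
  expect_equal(gl$c_fully_connected, 0.33)
  expect_equal(gl$n_blocks_final, 1L)
})

test_that("partitions nest: higher-c blocks lie inside lower-c blocks", {
  withr::with_seed(32, {
    for (k in 1:10) {
      adj <- random_norm_adjacency(sample(4:12, 1))
      tr <- sweep_components(adj)
      ms <- split(tr$memberships$block, tr$memberships$c)
      cs <- as.numeric(names(ms))
      ord <- order(cs, decreasing = TRUE)
      for (i in seq_len(length(ord) - 1)) {
        hi <- ms[[ord[i]]]
        lo <- ms[[ord[i + 1]]]
        # every higher-c block maps into exactly one lower-c block
        expect_true(all(tapply(lo, hi, function(z) length(unique(z))) == 1))
      }
    }
  })
})

test_that("merge tree equals single-linkage clustering modulo grid flooring", {
  withr::with_seed(33, {
    grid <- threshold_grid()
    for (k in 1:15) {
      n <- sample(4:15, 1)
      adj <- random_norm_adjacency(n, p_edge = runif(1, .4, 1))
      amax <- max(adj$weights)
      d <- amax - adj$weights
      diag(d) <- 0
      hc <- stats::hclust(stats::as.dist(d), method = "single")
      coph <- as.matrix(stats::cophenetic(hc))
      for (i in 1:(n - 1)) {
        for (j in (i + 1):n) {
          ratio <- (amax - coph[i, j]) / amax
          ok <- grid[grid <= ratio + 1e-9]
          want <- if (length(ok)) max(ok) else NA_real_
          expect_equal(merge_multiplicity(adj, i, j, grid), want)
        }
      }
    }
  })
})

test_that("merge multiplicity agrees with an exhaustive grid scan", {
  withr::with_seed(34, {
    grid <- threshold_grid()
    adj <- random_norm_adjacency(6, p_edge = 0.5)
    for (i in 1:5) {
      for (j in (i + 1):6) {
        # oracle: scan the grid with independent BFS components at each c
        found <- NA_real_
        for (cc in grid) {
          w <- adj$weights
          w[w < cc * max(w)] <- 0
          b <- bfs_components(w)
          if (b[i] == b[j]) { found <- cc; break }
        }
        expect_equal(merge_multiplicity(adj, i, j), found)
      }
    }
    # the globally maximal edge merges at c = 1
    mx <- which(adj$weights == max(adj$weights), arr.ind = TRUE)[1, ]
    expect_equal(merge_multiplicity(adj, mx[1], mx[2]), 1)
  })
})

test_that("connectivity profile is positive exactly when merged at c", {
  withr::with_seed(35, {
    adj <- random_norm_adjacency(7, p_edge = 0.4)
    grid <- threshold_grid(step = 0.05)
    for (pair in list(c(1, 4), c(2, 7), c(3, 5))) {
      mc <- merge_multiplicity(adj, pair[1], pair[2], grid)
      prof <- connectivity_profile(adj, pair[1], pair[2], grid)
      connected <- prof$connectivity > 0
      want <- if (is.na(mc)) rep(FALSE, length(grid)) else grid <= mc
      expect_equal(connected, want)
    }
  })
})

test_that("merge tree exports to parseable Newick and nested JSON", {
  w <- matrix(c(0, .9, .3, .9, 0, .3, .3, .3, 0), 3, 3,
              dimnames = list(c("a", "b", "c3"), c("a", "b", "c3")))
  tr <- sweep_components(as_mi_adjacency(w))
  nwk <- merge_tree_newick(tr)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, c("a", "b", "c3"))
  expect_equal(phy$node.label, c("0.33", "1"))
  js <- jsonlite::fromJSON(merge_tree_json(tr), simplifyVector = FALSE)
  expect_equal(js$c, 0.33)
  expect_setequal(unlist(js$members), c("a", "b", "c3"))
  # a forest (never fully connected on the grid) gets a virtual root
  w2 <- diag(0, 4)
  w2[1, 2] <- w2[2, 1] <- 1
  w2[3, 4] <- w2[4, 3] <- 0.05  # below the c = 0.1 floor
  tr2 <- sweep_components(as_mi_adjacency(w2))
  expect_true(is.na(tr2$root$c))
  phy2 <- ape::read.tree(text = merge_tree_newick(tr2))
  expect_equal(length(phy2$tip.label), 4)
})

test_that("the exact data-induced grid exposes every hierarchy level", {
  withr::with_seed(37, {
    adj <- random_norm_adjacency(9, p_edge = 0.7)
    g <- exact_threshold_grid(adj)
    expect_true(all(diff(g) < 0))
    expect_true(all(g > 0 & g <= 1))
    tr <- sweep_components(adj, grid = g)
    # every distinct partition reachable by thresholding appears in the sweep
    w <- adj$weights
    seen <- unique(split(tr$memberships$block, tr$memberships$c))
    for (t in sort(unique(w[w > 0]))) {
      b <- bfs_components((w >= t) * w)
      hit <- any(vapply(seen, function(s) partition_same(s, b), logical(1)))
      expect_true(hit)
    }
  })
})

test_that("cut_merge_tree returns the same partition as direct components", {
  withr::with_seed(36, {
    adj <- random_norm_adjacency(8)
    tr <- sweep_components(adj)
    for (cc in c(1, 0.62, 0.25, 0.1)) {
      expect_equal(cut_merge_tree(tr, cc)$block,
                   connected_components(adj, c = cc)$block)
    }
    expect_error(cut_merge_tree(tr, 0.555), "grid")
  })
})
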