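# Dynamic regional attention: projection, similarity measure, region
# partitioning in both search modes, region-mean fusion and the gate.

test_that("project_channels collapses channels per pixel", {
  x <- array(rnorm(3 * 4), c(3, 4, 1))
  expect_equal(project_channels(x, 1), x[, , 1])

  set.seed(1)
  x <- array(rnorm(2 * 2 * 3), c(2, 2, 3))
  y <- project_channels(x, c(1, 1, 1))
  expect_equal(y, apply(x, c(1, 2), sum))
  expect_identical(dim(y), c(2L, 2L))

  expect_error(project_channels(x, c(1, 1)), "channels")
})

test_that("similarity follows the normalized joint distance", {
  expect_equal(similarity(5, 3, 3, 5, 3, 3, m = 2, s = 2), 0)
  # d_f = 3, d_s = 4, m = 3, s = 4 -> sqrt(2)
  expect_equal(similarity(0, 0, 0, 3, 0, 4, m = 3, s = 4), sqrt(2))
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(similarity(a[1], a[2], a[3], b[1], b[2], b[3], 2, 3),
                 similarity(b[1], b[2], b[3], a[1], a[2], a[3], 2, 3))
  }
  expect_error(similarity(0, 0, 0, 1, 1, 1, m = 0, s = 1), "positive")
})

test_that("partition_regions covers degenerate and two-level cases", {
  set.seed(3)
  p <- matrix(rnorm(30), 5, 6)
  part <- partition_regions(p, dra_config(k = 1L))
  expect_true(all(part$labels == 0L))

  # left half 0, right half 10, k = 2, global: exact halves, and equal to the
  # brute-force 1-D k-means oracle
  p <- cbind(matrix(0, 6, 3), matrix(10, 6, 3))
  part <- partition_regions(p, dra_config(k = 2L, mode = "global"))
  expect_equal(length(unique(as.vector(part$labels[, 1:3]))), 1L)
  expect_equal(length(unique(as.vector(part$labels[, 4:6]))), 1L)
  expect_false(part$labels[1, 1] == part$labels[1, 6])
  ps <- (p - mean(p)) / sd(p)
  expect_equal(part$labels, naive_kmeans1d(ps, 2L, 5L))

  # constant map, local mode: labels are the nearest-grid-center Voronoi cells
  p <- matrix(1, 8, 8)
  cfg <- dra_config(k = 4L, mode = "local")
  part <- partition_regions(p, cfg)
  gr <- ceiling(sqrt(4)); H <- 8; W <- 8
  centers <- t(sapply(0:3, function(i) {
    r <- i %/% gr; cc <- i %% gr
    c(floor((r + 0.5) * H / gr), floor((cc + 0.5) * W / gr))
  }))
  for (h in 1:H) for (w in 1:W) {
    d <- sqrt((h - 1 - centers[, 1])^2 + (w - 1 - centers[, 2])^2)
    expect_lte(d[part$labels[h, w] + 1], min(d) + 1e-9)
  }

  expect_error(partition_regions(matrix(1, 2, 2), dra_config(k = 5L)), "exceeds")
})

test_that("partitions are exhaustive, disjoint and keep k regions", {
  set.seed(4)
  for (mode in c("local", "global")) {
    for (i in 1:10) {
      H <- sample(5:9, 1); W <- sample(5:9, 1)
      k <- sample(2:5, 1)
      p <- matrix(rnorm(H * W), H, W)
      part <- partition_regions(p, dra_config(k = k, mode = mode))
      expect_identical(dim(part$labels), c(H, W))
      expect_true(all(part$labels >= 0L & part$labels < k))
      expect_identical(sort(unique(as.vector(part$labels))), 0:(k - 1L))
    }
  }
})

test_that("local mode with a huge m reduces to spatial tiles; global mode recovers levels", {
  set.seed(5)
  p <- matrix(rnorm(64), 8, 8)
  # m -> infinity: the feature term is negligible, so regions become compact
  # spatial tiles: connected, non-trivial, and covering the map
  part_m <- partition_regions(p, dra_config(k = 4L, m = 1e9, mode = "local"))
  sizes <- tabulate(as.vector(part_m$labels) + 1L, nbins = 4L)
  expect_true(all(sizes >= 8))
  for (l in 0:3)
    expect_equal(count_components(matrix(as.integer(part_m$labels == l), 8, 8)), 1L)

  # two-level map: global mode recovers the levels exactly
  lv <- matrix(sample(c(-3, 3), 49, replace = TRUE), 7, 7)
  part <- partition_regions(lv, dra_config(k = 2L, mode = "global"))
  expect_equal(length(unique(part$labels[lv == -3])), 1L)
  expect_equal(length(unique(part$labels[lv == 3])), 1L)
})

test_that("fuse_regions replaces values by region means", {
  p <- matrix(5, 3, 3)
  part <- partition_regions(p, dra_config(k = 1L))
  expect_equal(fuse_regions(p, part), p)

  p <- matrix(c(1, 3, 2, 4), 2, 2)  # [[1,2],[3,4]] in row terms
  part <- structure(list(labels = matrix(c(0L, 1L, 0L, 1L), 2, 2), k = 2L),
                    class = "region_partition")
  expect_equal(fuse_regions(p, part),
               matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))

  set.seed(6)
  p <- matrix(rnorm(48), 6, 8)
  part <- partition_regions(p, dra_config(k = 3L, mode = "global"))
  f <- fuse_regions(p, part)
  expect_equal(sum(f), sum(p))                     # mean replacement conserves sums
  expect_equal(fuse_regions(f, part), f)           # idempotent
  expect_equal(f, naive_region_mean(p, part$labels))

  bad <- part; bad$labels[1, 1] <- 7L
  expect_error(fuse_regions(p, bad), "label")
})

test_that("dra_forward gates the branch with a sigmoid of fused regions", {
  set.seed(7)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  branch <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  wts <- list(w = rnorm(4), b = 0.1)
  cfg <- dra_config(k = 3L)
  y <- dra_forward(x, branch, cfg, wts)
  expect_identical(dim(y), dim(branch))

  # staged composition oracle
  p <- project_channels(x, wts)
  gate <- plogis(fuse_regions(p, partition_regions(p, cfg)))
  expect_true(all(gate > 0 & gate < 1))
  ref <- branch * as.vector(gate)
  expect_equal(y, ref, tolerance = 1e-12)

  expect_error(dra_forward(x, branch[1:4, , ], cfg, wts), "spatial")
})

test_that("gradients flow through projection and region means (labels fixed)", {
  set.seed(8)
  blk <- dra_block(2L, dra_config(k = 2L, iterations = 2L), hidden = NULL)
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  branch <- array(rnorm(4 * 4 * 2), c(4, 4, 2, 1))
  R <- array(rnorm(length(branch)), dim(branch))
  fw <- dranet:::dra_fwd(blk, x, branch)
  bk <- dranet:::dra_bwd(blk, fw$cache, R)
  loss_x <- function(xx) sum(dranet:::dra_fwd(blk, array(xx, dim(x)), branch)$y * R)
  idx <- sample(length(x), 16)
  fd <- fd_grad(loss_x, x, eps = 1e-6, idx = idx)
  expect_lt(rel_err(fd[idx], bk$gx[idx]), 1e-4)
  # and w.r.t. the projection weights
  w0 <- blk$proj$layers[[1]]$params$w
  loss_w <- function(ww) {
    b2 <- blk; b2$proj$layers[[1]]$params$w <- array(ww, dim(w0))
    sum(dranet:::dra_fwd(b2, x, branch)$y * R)
  }
  fdw <- fd_grad(loss_w, w0, eps = 1e-6)
  expect_lt(rel_err(as.vector(fdw), as.vector(bk$grads[["proj.layers.1.w"]])),
            1e-4)
  # the branch path is the gate itself
  expect_equal(bk$gbranch, R * fw$cache$gate[, , rep(1, 2), , drop = FALSE])
})
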