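# Ordered shift MLP block: ordering, reordering, grouped axial shifts,
# token MLPs and their composition.

test_that("channel ordering sorts by summed pooled scores with stable ties", {
  # constant map: all scores equal, stable tie-break gives the identity
  x <- array(1, c(4, 4, 5))
  co <- compute_channel_order(x)
  expect_identical(co$order, 1:5)

  # per-channel constants (1, 5, 3): avg-pool = max-pool, scores (2, 10, 6)
  x <- array(0, c(2, 2, 3))
  x[, , 1] <- 1; x[, , 2] <- 5; x[, , 3] <- 3
  co <- compute_channel_order(x, identity)
  expect_equal(co$scores, c(2, 10, 6))
  expect_identical(co$order, c(2L, 3L, 1L))

  # any map: a permutation, deterministically
  set.seed(1)
  for (i in 1:10) {
    x <- array(rnorm(3 * 5 * 8), c(3, 5, 8))
    co <- compute_channel_order(x, function(v) v^2)
    expect_setequal(co$order, 1:8)
    expect_identical(co$order, compute_channel_order(x, function(v) v^2)$order)
  }

  expect_error(compute_channel_order(array(c(1, NA), c(1, 1, 2))), "finite")
})

test_that("reorder_channels is pure index selection", {
  set.seed(2)
  x <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  expect_identical(reorder_channels(x, 1:4), x)

  ord <- c(3L, 1L, 4L, 2L)
  y <- reorder_channels(x, ord)
  # naive per-element copy oracle
  for (j in 1:4) expect_identical(y[, , j], x[, , ord[j]])
  # applying the inverse recovers the input exactly
  inv <- integer(4); inv[ord] <- 1:4
  expect_identical(reorder_channels(y, inv), x)
  # multiset of channel slices preserved
  expect_identical(sort(as.vector(y)), sort(as.vector(x)))

  expect_error(reorder_channels(x, c(1L, 1L, 2L, 3L)), "permutation")
})

test_that("axial_group_shift rolls groups with zero fill", {
  spec0 <- shift_spec(2L, c(0L, 0L), "height")
  set.seed(3)
  x <- array(rnorm(4 * 3 * 4), c(4, 3, 4))
  expect_equal(axial_group_shift(x, spec0), x)

  # worked case: H=4, W=1, C=2, g=2, offsets (+1, -1)
  x <- array(0, c(4, 1, 2))
  x[, 1, 1] <- 1:4; x[, 1, 2] <- c(10, 20, 30, 40)
  y <- axial_group_shift(x, shift_spec(2L, c(1L, -1L), "height"))
  expect_equal(y[, 1, 1], c(0, 1, 2, 3))
  expect_equal(y[, 1, 2], c(20, 30, 40, 0))

  # definition as property, both axes, against the naive roll oracle
  for (axis in c("height", "width")) {
    for (i in 1:5) {
      x <- array(rnorm(5 * 6 * 6), c(5, 6, 6))
      off <- sample(-3:3, 3L, replace = TRUE)
      sp <- shift_spec(3L, off, axis)
      expect_equal(axial_group_shift(x, sp), naive_shift(x, 3L, off, axis))
    }
  }

  # shifted-out values are replaced by zeros only; in-range values survive
  x <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  y <- axial_group_shift(x, shift_spec(1L, 2L, "width"))
  expect_true(all(y[, 1:2, ] == 0))
  expect_equal(y[, 3:4, ], x[, 1:2, ])

  expect_error(axial_group_shift(x, shift_spec(3L, c(0L, 0L, 0L), "height")),
               "not divisible")
})

test_that("positional_token_mlp preserves shape and matches a hand-evaluated chain", {
  set.seed(4)
  tm <- token_mlp(2L, 3L)
  x <- array(rnorm(5 * 4 * 2), c(5, 4, 2))
  y <- positional_token_mlp(x, tm)
  expect_identical(dim(y), dim(x))

  # zero input with zero biases stays zero (GELU(0) = 0)
  tm0 <- tm
  tm0$layers[[1]]$params$b[] <- 0
  tm0$layers[[3]]$params$b[] <- 0
  tm0$layers[[4]]$params$b[] <- 0
  expect_equal(positional_token_mlp(array(0, c(3, 3, 2)), tm0),
               array(0, c(3, 3, 2)))

  # 1x1 spatial input: the depthwise 3x3 sees only the center tap, so the
  # whole chain is hand-evaluable
  gelu_ref <- function(z) z * pnorm(z)
  x <- array(c(1, -1), c(1, 1, 2))
  w1 <- matrix(tm$layers[[1]]$params$w[1, 1, , ], 2, 3)
  b1 <- tm$layers[[1]]$params$b
  w2 <- matrix(tm$layers[[3]]$params$w[1, 1, , ], 3, 2)
  b2 <- tm$layers[[3]]$params$b
  h <- gelu_ref(as.vector(c(1, -1) %*% w1) + b1)
  m <- as.vector(h %*% w2) + b2
  dwc <- m * tm$layers[[4]]$params$w[2, 2, ] + tm$layers[[4]]$params$b
  expect_equal(as.vector(positional_token_mlp(x, tm)), gelu_ref(dwc),
               tolerance = 1e-12)
})

test_that("osmlp_forward composes the staged operations", {
  set.seed(5)
  blk <- osmlp_block(8L, g = 4L, hidden = 6L)
  x <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  y <- osmlp_forward(x, blk)
  expect_identical(dim(y), dim(x))
  # bit-identical across repeated calls
  expect_identical(y, osmlp_forward(x, blk))

  # equals the manual composition of the five staged ops with the same weights
  s1 <- function(v) as.vector(dranet:::seq_fwd(blk$score1, matrix(v))$y)
  s2 <- function(v) as.vector(dranet:::seq_fwd(blk$score2, matrix(v))$y)
  o1 <- compute_channel_order(x, s1)
  xs <- reorder_channels(x, o1)
  th <- axial_group_shift(xs, blk$spec_h)
  tt <- positional_token_mlp(th, blk$mlp4)
  o2 <- compute_channel_order(tt, s2)
  ts <- reorder_channels(tt, o2)
  tw <- axial_group_shift(ts, blk$spec_w)
  ref <- dranet:::seq_fwd(blk$mlp8, dranet:::as_map4(tw))$y
  expect_equal(y, array(ref, dim(x)), tolerance = 1e-12)
})

test_that("with zero offsets and tied scores the block reduces to its MLP stages", {
  set.seed(6)
  blk <- osmlp_block(6L, g = 3L, hidden = 4L)
  blk$spec_h$offsets[] <- 0L
  blk$spec_w$offsets[] <- 0L
  for (s in c("score1", "score2"))  # zero scores => ties => identity order
    for (i in c(1L, 3L)) {
      blk[[s]]$layers[[i]]$params$w[] <- 0
      blk[[s]]$layers[[i]]$params$b[] <- 0
    }
  x <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  y <- osmlp_forward(x, blk)
  ref <- dranet:::seq_fwd(blk$mlp8, dranet:::seq_fwd(blk$mlp4, dranet:::as_map4(x))$y)$y
  expect_equal(y, array(ref, dim(x)), tolerance = 1e-12)
})

test_that("osmlp backward matches finite differences on a 4x4x4 input", {
  set.seed(7)
  blk <- osmlp_block(4L, g = 2L, hidden = 4L)
  x <- array(rnorm(4 * 4 * 4), c(4, 4, 4, 1))
  R <- array(rnorm(length(x)), dim(x))
  loss <- function(xx) sum(dranet:::osmlp_fwd(blk, array(xx, dim(x)))$y * R)
  fw <- dranet:::osmlp_fwd(blk, x)
  gx <- dranet:::osmlp_bwd(blk, fw$cache, R)$gx
  idx <- sample(length(x), 24)
  fd <- fd_grad(loss, x, eps = 1e-5, idx = idx)
  expect_lt(rel_err(fd[idx], gx[idx]), 1e-4)
})
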