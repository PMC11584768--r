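# Encoder/decoder assembly, parameter accounting, FLOP accounting,
# checkpoints.

test_that("encoder produces the five pyramid resolutions", {
  cfg <- tiny_model_config()
  enc <- build_encoder(cfg)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  fe <- dranet:::encoder_fwd(enc, x)
  expect_equal(sapply(fe$feats, function(f) dim(f)[1]), c(32, 16, 8, 4, 2))
  expect_equal(sapply(fe$feats, function(f) dim(f)[3]), cfg$stage_widths)
})

test_that("a 64->64 basic block with affine group norm has 73,984 parameters", {
  set.seed(1)
  blk <- dranet:::basic_block(64L, 64L, 1L, 8L)
  expect_identical(sum(lengths(dranet:::flatten_params(blk))), 73984L)
})

test_that("zeroing the residual branch makes a basic block the identity (plus ReLU)", {
  set.seed(2)
  blk <- dranet:::basic_block(8L, 8L, 1L, 4L)
  blk$main$layers[[5]]$params$gamma[] <- 0  # second norm: kills the branch
  blk$main$layers[[5]]$params$beta[] <- 0
  x <- array(abs(rnorm(6 * 6 * 8)), c(6, 6, 8, 1))  # nonnegative input
  expect_equal(dranet:::block_fwd(blk, x)$y, x)
})

test_that("bilinear upsampling is half-pixel-centered", {
  # constants stay constant
  x <- array(3.5, c(4, 4, 2, 1))
  y <- dranet:::cpp_bilinear_fwd(x, 8L, 8L)
  expect_equal(as.vector(y), rep(3.5, 128))

  # 2x2 -> 4x4 against the closed-form half-pixel oracle
  x <- array(c(1, 3, 2, 4), c(2, 2, 1, 1))  # column-major: [[1,2],[3,4]]
  y <- dranet:::cpp_bilinear_fwd(x, 4L, 4L)[, , 1, 1]
  coeff <- function(i, Hin, Hout) {
    s <- min(max((i + 0.5) * Hin / Hout - 0.5, 0), Hin - 1)
    c(floor(s), min(floor(s) + 1, Hin - 1), s - floor(s))
  }
  ref <- matrix(0, 4, 4)
  xm <- matrix(c(1, 3, 2, 4), 2, 2)
  for (i in 0:3) for (j in 0:3) {
    ch <- coeff(i, 2, 4); cw <- coeff(j, 2, 4)
    ref[i + 1, j + 1] <-
      (1 - ch[3]) * (1 - cw[3]) * xm[ch[1] + 1, cw[1] + 1] +
      ch[3] * (1 - cw[3]) * xm[ch[2] + 1, cw[1] + 1] +
      (1 - ch[3]) * cw[3] * xm[ch[1] + 1, cw[2] + 1] +
      ch[3] * cw[3] * xm[ch[2] + 1, cw[2] + 1]
  }
  expect_equal(y, ref)
  # the specific half-pixel values for a 2x2 ramp
  expect_equal(y[1, ], c(1, 1.25, 1.75, 2))
})

test_that("the assembled model maps an image to a probability map of equal size", {
  set.seed(3)
  m <- assemble(model_config(input_size = 224L))
  x <- array(runif(224 * 224 * 3), c(224, 224, 3))
  y <- model_forward(m, x)
  expect_identical(dim(y), c(224L, 224L, 1L, 1L))
  expect_true(all(y > 0 & y < 1))
})

test_that("all four ablation variants build, run and profile monotonically", {
  set.seed(4)
  flags <- list(conv = c(FALSE, FALSE), mlp = c(TRUE, FALSE),
                dra = c(FALSE, TRUE), both = c(TRUE, TRUE))
  x <- array(runif(96 * 96 * 3), c(96, 96, 3, 1))
  params <- flops <- numeric(0)
  for (nm in names(flags)) {
    cfg <- model_config(input_size = 96L, use_mlp = flags[[nm]][1],
                        use_dra = flags[[nm]][2])
    m <- assemble(cfg)
    y <- model_forward(m, x)
    expect_identical(dim(y), c(96L, 96L, 1L, 1L))
    pp <- count_parameters(m)
    ff <- count_flops(m)
    expect_equal(sum(pp$breakdown$parameters), pp$total)  # accounting identity
    expect_equal(sum(ff$breakdown$macs), ff$total)
    params[nm] <- pp$total; flops[nm] <- ff$total
  }
  # adding a module never decreases parameters or FLOPs
  expect_true(params["mlp"] > params["conv"])
  expect_true(params["dra"] > params["conv"])
  expect_true(params["both"] > params["mlp"])
  expect_true(params["both"] > params["dra"])
  expect_true(flops["mlp"] > flops["conv"])
  expect_true(flops["dra"] > flops["conv"])
  expect_true(flops["both"] >= flops["mlp"])
})

test_that("FLOP closed forms match hand counts", {
  # 1x1 conv: H*W*Cin*Cout
  expect_equal(dranet:::conv_macs(c(7, 7), 1L, 16L, 8L), 7 * 7 * 16 * 8)
  # 3x3 conv 64->64 on 56x56 without bias
  expect_equal(dranet:::conv_macs(c(56, 56), 3L, 64L, 64L), 115605504)
  # a linear map Cin->Cout with bias has Cin*Cout + Cout parameters
  lin <- dranet:::nn_linear(13L, 7L)
  expect_identical(sum(lengths(dranet:::flatten_params(lin))), 13L * 7L + 7L)
})

test_that("forward is deterministic and checkpoints round-trip exactly", {
  set.seed(5)
  m <- assemble(tiny_model_config())
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  y1 <- model_forward(m, x)
  expect_identical(y1, model_forward(m, x))
  ck <- file.path(tempdir(), "ck.rds")
  save_checkpoint(m, ck, extra = list(note = "roundtrip"))
  lo <- load_checkpoint(ck)
  expect_identical(model_forward(lo$model, x), y1)
  expect_equal(lo$extra$note, "roundtrip")
  unlink(ck)
})

test_that("model backward agrees with finite differences through deep paths", {
  set.seed(6)
  cfg <- tiny_model_config()
  m <- assemble(cfg)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  y <- array(as.numeric(matrix(runif(64 * 64), 64, 64) > 0.5), c(64, 64, 1, 1))
  fw <- model_forward(m, x, training = TRUE)
  g <- model_backward(m, fw$cache, dranet:::total_loss_grad(fw$y, y))
  ps <- dranet:::flatten_params(m)
  for (pn in c("enc.stem.layers.1.w", "dec.head.w",
               "sites.1.osmlp.mlp8.layers.3.w",
               "sites.1.dra.proj.layers.3.w")) {
    a <- ps[[pn]]
    idx <- sample(length(a), 3)
    f <- function(av) {
      ps2 <- ps; ps2[[pn]] <- array(av, dim(a))
      m2 <- dranet:::set_params(m, ps2)
      total_loss(model_forward(m2, x), y)
    }
    fd <- fd_grad(f, a, eps = 1e-5, idx = idx)
    expect_lt(rel_err(fd[idx], g[[pn]][idx]), 1e-3)
  }
})
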