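# Compound BCE + Dice loss and the five overlap metrics.

test_that("bce_loss reproduces analytic values", {
  target <- array(c(1, 0, 1, 0), c(2, 2))
  expect_equal(bce_loss(array(0.5, c(2, 2)), target), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(c(0.9, 0.2), c(1, 0)), -(log(0.9) + log(0.8)) / 2,
               tolerance = 1e-12)
  # perfect prediction (clipped) drives the loss to ~0
  expect_lt(bce_loss(target, target), 1e-5)
  # manual per-element rescaling
  expect_equal(bce_loss(c(0.5, 0.5), c(1, 0), weights = 2), 2 * log(2))
  expect_error(bce_loss(c(0.5, 0.5), c(1, 0, 1)), "shapes")
  expect_error(bce_loss(c(0.5), c(0.3)), "binary")
})

test_that("dice_loss reproduces analytic values", {
  y <- array(c(1, 0, 1, 1, 0, 0), c(2, 3))
  expect_equal(dice_loss(y, y, eps = 1e-9), 0, tolerance = 1e-8)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0), eps = 0), 0.5)
  # disjoint supports
  expect_equal(dice_loss(c(1, 1, 0, 0), c(0, 0, 1, 1), eps = 1e-12), 1,
               tolerance = 1e-10)
})

test_that("total_loss is 0.5*BCE + Dice and vanishes at perfect predictions", {
  set.seed(1)
  for (i in 1:10) {
    pred <- array(runif(24), c(4, 6))
    targ <- array(as.numeric(runif(24) > 0.5), c(4, 6))
    expect_equal(total_loss(pred, targ),
                 0.5 * bce_loss(pred, targ) + dice_loss(pred, targ))
  }
  targ <- array(as.numeric(runif(24) > 0.5), c(4, 6))
  expect_lt(total_loss(targ, targ, dice_eps = 1e-9), 1e-4)
})

test_that("total_loss decreases monotonically from uniform 0.5 toward the target", {
  set.seed(2)
  targ <- array(as.numeric(runif(64) > 0.4), c(8, 8))
  alphas <- seq(0, 0.98, by = 0.07)
  losses <- sapply(alphas, function(a)
    total_loss(array(0.5, c(8, 8)) * (1 - a) + targ * a, targ))
  expect_true(all(diff(losses) < 0))
})

test_that("loss gradients agree with finite differences", {
  set.seed(3)
  pred <- array(runif(16, 0.05, 0.95), c(4, 4))
  targ <- array(as.numeric(runif(16) > 0.5), c(4, 4))
  g <- dranet:::total_loss_grad(pred, targ)
  fd <- fd_grad(function(p) total_loss(array(p, c(4, 4)), targ), pred)
  expect_lt(rel_err(as.vector(fd), as.vector(g)), 1e-6)
})

test_that("evaluate_metrics reproduces the worked confusion example", {
  # TP=3, FP=1, FN=2, TN=4
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  targ <- c(1, 1, 1, 0, 1, 1, 0, 0, 0, 0)
  m <- evaluate_metrics(pred, targ)
  expect_equal(m$counts, list(tp = 3L, tn = 4L, fp = 1L, fn = 2L))
  expect_equal(m$iou, 50)
  expect_equal(m$dice, 200 / 3, tolerance = 1e-12)
  expect_equal(m$recall, 60)
  expect_equal(m$specificity, 80)
  expect_equal(m$precision, 75)

  # perfect prediction: all five at 100
  mp <- evaluate_metrics(targ, targ)
  for (f in c("iou", "dice", "recall", "specificity", "precision"))
    expect_equal(mp[[f]], 100)

  expect_error(evaluate_metrics(pred, c(targ[-1], 0.5)), "binary")
})

test_that("Dice and IoU obey their algebraic identity on random masks", {
  set.seed(4)
  for (i in 1:200) {
    pred <- runif(30)
    targ <- as.numeric(runif(30) > runif(1, 0.2, 0.8))
    m <- evaluate_metrics(pred, targ)
    iou <- m$iou / 100
    expect_equal(m$dice, 100 * 2 * iou / (1 + iou), tolerance = 1e-10)
  }
})

test_that("soft dice on a binarized prediction matches the Dice metric", {
  set.seed(5)
  for (i in 1:20) {
    pred <- as.numeric(runif(40) > 0.5)
    targ <- as.numeric(runif(40) > 0.5)
    if (sum(pred) + sum(targ) == 0) next
    dl <- dice_loss(pred, targ, eps = 1e-12)
    m <- evaluate_metrics(pred, targ)
    expect_equal(dl, 1 - m$dice / 100, tolerance = 1e-8)
  }
})
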