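# Compound training objective: binary cross entropy guiding a soft Dice
# overlap term, Loss = 0.5 * BCE + Dice. Predictions are probabilities;
# BCE clips them to [eps, 1 - eps] for numerical safety.

BCE_EPS <- 1e-7

check_pair <- function(pred, target) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stop("pred and target shapes differ")
  if (any(!is.finite(pred)) || any(!is.finite(target)))
    stop("non-finite values in pred or target")
  if (!all(target %in% c(0, 1))) stop("target must be binary (0/1)")
}

#' Binary cross-entropy loss
#'
#' Mean over elements of `-w_n * (y log x + (1-y) log(1-x))`, with
#' probabilities clipped at `1e-7`.
#'
#' @param pred probability map (any shape); @param target binary map of the
#'   same shape; @param weights optional per-element rescaling `w_n`
#'   (default 1).
#' @return nonnegative scalar.
#' @export
bce_loss <- function(pred, target, weights = 1) {
  check_pair(pred, target)
  x <- pmin(pmax(pred, BCE_EPS), 1 - BCE_EPS)
  mean(-weights * (target * log(x) + (1 - target) * log(1 - x)))
}

bce_loss_grad <- function(pred, target, weights = 1) {
  x <- pmin(pmax(pred, BCE_EPS), 1 - BCE_EPS)
  g <- -weights * (target / x - (1 - target) / (1 - x)) / length(pred)
  g[pred < BCE_EPS | pred > 1 - BCE_EPS] <- 0  # clipped region is flat
  array(g, dim(pred) %||% length(pred))
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(x*y) + eps) / (sum(x) + sum(y) + eps)`, computed per sample
#' (4th dimension) and averaged. The smoothing `eps` keeps empty-mask
#' gradients stable.
#'
#' @param pred probability map; @param target binary map; @param eps
#'   smoothing constant (1 for training, use ~1e-7 for metric cross-checks).
#' @return scalar in `[0, 1]`.
#' @export
dice_loss <- function(pred, target, eps = 1) {
  check_pair(pred, target)
  p4 <- as_map4(pred); t4 <- as_map4(target)
  N <- dim(p4)[4]
  v <- vapply(seq_len(N), function(n) {
    x <- p4[, , , n]; y <- t4[, , , n]
    1 - (2 * sum(x * y) + eps) / (sum(x) + sum(y) + eps)
  }, numeric(1))
  mean(v)
}

dice_loss_grad <- function(pred, target, eps = 1) {
  p4 <- as_map4(pred); t4 <- as_map4(target)
  N <- dim(p4)[4]
  g <- array(0, dim(p4))
  for (n in seq_len(N)) {
    x <- p4[, , , n]; y <- t4[, , , n]
    den <- sum(x) + sum(y) + eps
    num <- 2 * sum(x * y) + eps
    g[, , , n] <- (-2 * y * den + num) / den^2 / N
  }
  array(g, dim(pred) %||% length(pred))
}

#' Compound loss: 0.5 * BCE + Dice
#'
#' @inheritParams bce_loss
#' @param dice_eps Dice smoothing constant.
#' @return nonnegative scalar.
#' @export
total_loss <- function(pred, target, weights = 1, dice_eps = 1) {
  0.5 * bce_loss(pred, target, weights) + dice_loss(pred, target, dice_eps)
}

total_loss_grad <- function(pred, target, weights = 1, dice_eps = 1) {
  0.5 * bce_loss_grad(pred, target, weights) +
    dice_loss_grad(pred, target, dice_eps)
}
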