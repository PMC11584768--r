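# Dynamic regional attention: project the feature map to one channel,
# partition it into k similarity-defined regions (superpixel-style local
# search, or a global feature-only search), replace each region by its mean and
# squash through a sigmoid to obtain an H x W attention gate.

#' DRA configuration
#'
#' @param k number of regions (`k <= H*W` at use time).
#' @param m feature-distance normalizer of the similarity measure; distances
#'   are computed on values standardized to unit variance, so `m` is in
#'   standard-deviation units.
#' @param mode `"local"` (joint feature/spatial distance, centers searched
#'   within a 2s x 2s window, s = sqrt(H*W/k)) or `"global"` (feature-only
#'   distance, all centers searched; 1-D k-means on pixel values).
#' @param iterations number of assign/update rounds.
#' @return a `dra_config` list.
#' @export
dra_config <- function(k = 5L, m = 10, mode = c("local", "global"),
                       iterations = 5L) {
  mode <- match.arg(mode)
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (m <= 0) stop("m must be positive")
  if (iterations < 1L) stop("iterations must be >= 1")
  structure(list(k = k, m = m, mode = mode, iterations = as.integer(iterations)),
            class = "dra_config")
}

#' Collapse the channels of a feature map to one channel
#'
#' Per-pixel linear fusion of the C channel values into a single value
#' (a 1x1 channel-collapsing map), returning an H x W map.
#'
#' @param x a (H, W, C) feature map.
#' @param weights a length-C numeric vector (or list with `w` and optional
#'   scalar `b`).
#' @return an H x W matrix.
#' @export
project_channels <- function(x, weights) {
  x4 <- as_map4(x)
  d <- dim(x4)
  if (d[4] != 1L) stop("project_channels expects a single map")
  if (is.list(weights)) { w <- weights$w; b <- weights$b %||% 0 }
  else { w <- weights; b <- 0 }
  if (length(w) != d[3])
    stop(sprintf("projection weights have length %d, map has %d channels",
                 length(w), d[3]))
  y <- matrix(matrix(x4, d[1] * d[2], d[3]) %*% as.numeric(w) + b, d[1], d[2])
  y
}

#' Similarity measure between two feature points
#'
#' `S = sqrt((d_f/m)^2 + (d_s/s)^2)` with `d_f` the absolute feature-value
#' difference and `d_s` the Euclidean pixel distance.
#'
#' @param value_i,h_i,w_i value and coordinates of the first point.
#' @param value_j,h_j,w_j value and coordinates of the second point.
#' @param m,s positive normalizers for feature and spatial proximity.
#' @return nonnegative similarity distance (0 = identical).
#' @export
similarity <- function(value_i, h_i, w_i, value_j, h_j, w_j, m, s) {
  if (m <= 0 || s <= 0) stop("m and s must be positive")
  df <- abs(value_i - value_j)
  ds <- sqrt((h_i - h_j)^2 + (w_i - w_j)^2)
  sqrt((df / m)^2 + (ds / s)^2)
}

#' Partition a one-channel map into k regions by similarity
#'
#' Local mode: centers start on a regular grid and each pixel joins the
#' center minimizing the joint feature/spatial similarity among centers
#' within a 2s x 2s window; centers move to region means for `iterations`
#' rounds (superpixel-style). Global mode: feature-only distance with all
#' centers searchable (1-D k-means on pixel values, grid-sampled init).
#' Values are standardized to unit variance before distance computation.
#' Empty regions are repaired by reseeding at the pixel farthest from the
#' region's current center.
#'
#' @param p an H x W numeric matrix (projected map).
#' @param cfg a [dra_config()].
#' @return a `region_partition`: `labels` (H x W integers in 0..k-1),
#'   `centers` (k x 3 matrix: value, h, w; 0-based coordinates on the
#'   standardized map), `k`.
#' @export
partition_regions <- function(p, cfg) {
  if (!is.matrix(p)) stop("p must be an H x W matrix")
  H <- nrow(p); W <- ncol(p)
  if (cfg$k > H * W) stop(sprintf("k = %d exceeds the %d pixels of the map", cfg$k, H * W))
  s <- sqrt(H * W / cfg$k)
  sdev <- stats::sd(as.vector(p))
  ps <- if (is.na(sdev) || sdev < 1e-12) p - mean(p) else (p - mean(p)) / sdev
  r <- cpp_partition(as.vector(ps), H, W, cfg$k, cfg$m, s,
                     if (cfg$mode == "global") 1L else 0L, cfg$iterations)
  structure(list(labels = r$labels, centers = r$centers, k = cfg$k),
            class = "region_partition")
}

#' Replace every pixel by the mean of its region
#'
#' @param p an H x W numeric matrix.
#' @param part a `region_partition` whose labels cover `p`.
#' @return an H x W matrix, piecewise constant per region.
#' @export
fuse_regions <- function(p, part) {
  lab <- as.vector(part$labels)
  if (any(lab < 0L) || any(lab >= part$k)) stop("invalid partition: label outside 0..k-1")
  if (length(lab) != length(p)) stop("partition does not cover the map")
  idx <- lab + 1L
  cnt <- tabulate(idx, nbins = part$k)
  present <- sort(unique(idx))
  means <- numeric(part$k)
  means[present] <- rowsum(as.vector(p), idx)[, 1] / cnt[present]
  matrix(means[idx], nrow(p), ncol(p))
}

# backward of fuse: the gradient of a region mean distributes 1/n to each
# member, i.e. fusing the upstream gradient with the same partition
fuse_regions_bwd <- function(g, part) fuse_regions(g, part)

#' Dynamic regional attention forward
#'
#' Computes the gate `sigmoid(fuse(partition(project(x))))` and returns its
#' element-wise product with `branch`, broadcast over channels.
#'
#' @param x a (H, W, C) feature map the gate is computed from.
#' @param branch a feature map of the same spatial size to be gated.
#' @param cfg a [dra_config()].
#' @param weights projection weights (length-C vector or list(w, b)).
#' @return the gated branch, same shape as `branch`.
#' @export
dra_forward <- function(x, branch, cfg, weights) {
  x4 <- as_map4(x); b4 <- as_map4(branch)
  if (!all(dim(x4)[c(1, 2, 4)] == dim(b4)[c(1, 2, 4)]))
    stop("x and branch must share spatial size and batch")
  p <- project_channels(x, weights)
  part <- partition_regions(p, cfg)
  gate <- plogis(fuse_regions(p, part))
  like_input(b4 * as.vector(gate), branch)
}

# --- trainable module -------------------------------------------------------

#' Dynamic regional attention block
#'
#' @param c channel count at the insertion site.
#' @param cfg a [dra_config()].
#' @param hidden hidden width of the bottleneck channel projection; `NULL`
#'   for a single linear collapse.
#' @return a `dra_block` module.
#' @export
dra_block <- function(c, cfg = dra_config(), hidden = 16L) {
  proj <- if (is.null(hidden))
    nn_seq(list(nn_conv(c, 1L, k = 1L, bias = TRUE)))
  else
    nn_seq(list(nn_conv(c, hidden, k = 1L, bias = TRUE), nn_act("relu"),
                nn_conv(hidden, 1L, k = 1L, bias = TRUE)))
  structure(list(type = "dra", c = c, cfg = cfg, proj = proj),
            class = "dra_block")
}

# forward producing the gate and the gated branch; x4 and branch4 are
# (H,W,C,N). Region labels are constants of differentiation: gradients flow
# through the projection weights and region means only.
dra_fwd <- function(mod, x4, branch4) {
  rp <- seq_fwd(mod$proj, x4)
  d <- dim(x4); N <- d[4]
  gate <- array(0, c(d[1], d[2], 1L, N))
  parts <- vector("list", N)
  for (n in seq_len(N)) {
    p <- matrix(rp$y[, , 1L, n], d[1], d[2])
    parts[[n]] <- partition_regions(p, mod$cfg)
    gate[, , 1L, n] <- plogis(fuse_regions(p, parts[[n]]))
  }
  y <- branch4 * gate[, , rep(1L, dim(branch4)[3]), , drop = FALSE]
  list(y = y, cache = list(cproj = rp$cache, parts = parts, gate = gate,
                           branch = branch4))
}

dra_bwd <- function(mod, cache, gy) {
  gate <- cache$gate
  C <- dim(cache$branch)[3]
  gatec <- gate[, , rep(1L, C), , drop = FALSE]
  gbranch <- gy * gatec
  ggate <- apply(gy * cache$branch, c(1, 2, 4), sum)   # sum over channels
  d <- dim(gate); N <- d[4]
  gp <- array(0, c(d[1], d[2], 1L, N))
  for (n in seq_len(N)) {
    gg <- matrix(ggate[, , n], d[1], d[2]) * gate[, , 1L, n] * (1 - gate[, , 1L, n])
    gp[, , 1L, n] <- fuse_regions_bwd(gg, cache$parts[[n]])
  }
  bp <- seq_bwd(mod$proj, cache$cproj, gp)
  list(gx = bp$gx, gbranch = gbranch,
       grads = prefix_grads(bp$grads, "proj."))
}
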