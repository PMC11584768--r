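# Ordered shift MLP block: channel-importance ordering, grouped axial shifts
# along height then width, and position-encoding token MLPs.
#
# The block (i) scores channels from spatially average- and max-pooled
# features, (ii) sorts channels by score and shifts contiguous channel groups
# along the height axis, (iii) applies a pointwise channel MLP with a
# depthwise 3x3 positional encoding, then (iv) repeats the order/shift in the
# width direction and finishes with a second channel MLP. Sorting and index
# selection are piecewise-constant in their inputs, so they carry zero
# gradient almost everywhere; the learning signal flows through the MLPs.

#' Shift specification for grouped axial shifts
#'
#' @param group_count number of contiguous channel groups `g`; the channel
#'   count must be divisible by it.
#' @param offsets integer displacement (pixels) per group; defaults to a
#'   symmetric window centred at zero, `i - floor(g/2)` for group
#'   `i = 0, ..., g-1`.
#' @param axis `"height"` or `"width"`.
#' @return a `shift_spec` list.
#' @export
shift_spec <- function(group_count = 5L, offsets = NULL,
                       axis = c("height", "width")) {
  axis <- match.arg(axis)
  group_count <- as.integer(group_count)
  if (group_count < 1L) stop("group_count must be a positive integer")
  if (is.null(offsets)) offsets <- seq_len(group_count) - 1L - group_count %/% 2L
  if (length(offsets) != group_count)
    stop("offsets must have length group_count")
  structure(list(group_count = group_count, offsets = as.integer(offsets),
                 axis = axis), class = "shift_spec")
}

#' Order channels by pooled importance scores
#'
#' Scores each channel as `score_mlp(avgpool(x)) + score_mlp(maxpool(x))`,
#' where the pools are over the spatial dimensions, and returns the channels
#' sorted by descending score (ties broken by ascending original index, so
#' the ordering is deterministic).
#'
#' @param x a (H, W, C) feature map.
#' @param score_mlp a function mapping a length-C numeric vector to a
#'   length-C numeric vector; defaults to the identity.
#' @return a `channel_order` list with `order` (1-based permutation of
#'   `1:C`) and `scores` (length C).
#' @export
compute_channel_order <- function(x, score_mlp = identity) {
  x <- as_map4(x)
  if (dim(x)[4] != 1L) stop("compute_channel_order expects a single map; see osmlp_forward for batches")
  avg <- apply(x[, , , 1, drop = FALSE], 3, mean)
  mx  <- apply(x[, , , 1, drop = FALSE], 3, max)
  scores <- as.numeric(score_mlp(avg)) + as.numeric(score_mlp(mx))
  if (length(scores) != dim(x)[3]) stop("score_mlp must map a C-vector to a C-vector")
  ord <- order(-scores, seq_along(scores))
  structure(list(order = ord, scores = scores), class = "channel_order")
}

#' Reorder the channels of a feature map
#'
#' Pure index selection: output channel `j` is input channel `order[j]`.
#'
#' @param x a (H, W, C) or (H, W, C, N) feature map.
#' @param order a 1-based permutation of `1:C` or a `channel_order`.
#' @return the reordered map, same shape as `x`.
#' @export
reorder_channels <- function(x, order) {
  if (inherits(order, "channel_order")) order <- order$order
  x4 <- as_map4(x)
  C <- dim(x4)[3]
  if (length(order) != C || !setequal(order, seq_len(C)))
    stop("order must be a permutation of 1:", C)
  like_input(x4[, , order, , drop = FALSE], x)
}

invert_order <- function(order) {
  inv <- integer(length(order))
  inv[order] <- seq_along(order)
  inv
}

#' Shift contiguous channel groups along an image axis
#'
#' Channels are split into `g` contiguous groups (following the current
#' channel order); group `i` is displaced by `offsets[i]` pixels along the
#' chosen axis. Pixels shifted in from outside the map are zero (zero-pad
#' then crop), so the output shape equals the input shape.
#'
#' @param x a (H, W, C) or (H, W, C, N) feature map.
#' @param spec a [shift_spec()].
#' @return the shifted map, same shape as `x`.
#' @export
axial_group_shift <- function(x, spec) {
  x4 <- as_map4(x)
  d <- dim(x4); C <- d[3]; g <- spec$group_count
  if (C %% g != 0L)
    stop(sprintf("channel count %d not divisible by group count %d", C, g))
  gs <- C %/% g
  y <- array(0, d)
  L <- if (spec$axis == "height") d[1] else d[2]
  for (i in seq_len(g)) {
    ch <- ((i - 1L) * gs + 1L):(i * gs)
    o <- spec$offsets[i]
    if (abs(o) >= L) next  # fully shifted out: group stays zero
    src <- if (o >= 0) 1L:(L - o) else (1L - o):L
    dst <- if (o >= 0) (1L + o):L else 1L:(L + o)
    if (spec$axis == "height") y[dst, , ch, ] <- x4[src, , ch, , drop = FALSE]
    else                       y[, dst, ch, ] <- x4[, src, ch, , drop = FALSE]
  }
  like_input(y, x)
}

negate_spec <- function(spec) {
  spec$offsets <- -spec$offsets
  spec
}

#' Positional token MLP
#'
#' Pointwise channel MLP followed by a depthwise 3x3 convolution (positional
#' encoding) and a GELU, preserving the (H, W, C) shape.
#'
#' @param x a (H, W, C) or (H, W, C, N) feature map.
#' @param weights an `nn_seq` of pointwise/depthwise layers as built by
#'   [osmlp_block()]; see `token_mlp()` for a standalone constructor.
#' @return the transformed map, same shape as `x`.
#' @export
positional_token_mlp <- function(x, weights) {
  x4 <- as_map4(x)
  like_input(seq_fwd(weights, x4)$y, x)
}

#' Construct the Eq-style token MLP stack: channel MLP -> depthwise 3x3 -> GELU
#'
#' @param c channel count; @param hidden hidden width of the channel MLP.
#' @return an `nn_seq`.
#' @export
token_mlp <- function(c, hidden) {
  nn_seq(list(nn_conv(c, hidden, k = 1L, bias = TRUE),
              nn_act("gelu"),
              nn_conv(hidden, c, k = 1L, bias = TRUE),
              nn_dw3(c),
              nn_act("gelu")))
}

channel_mlp <- function(c, hidden) {
  nn_seq(list(nn_conv(c, hidden, k = 1L, bias = TRUE),
              nn_act("gelu"),
              nn_conv(hidden, c, k = 1L, bias = TRUE)))
}

score_mlp_module <- function(c, reduction = 4L) {
  h <- max(1L, c %/% reduction)
  nn_seq(list(nn_linear(c, h), nn_act("relu"), nn_linear(h, c)))
}

#' Ordered shift MLP block
#'
#' @param c channel count at the insertion site.
#' @param g group count for the axial shifts (must divide `c`).
#' @param hidden hidden width of the two channel MLPs.
#' @param reduction bottleneck reduction of the channel-scoring MLPs.
#' @param order_source `"t"` (default) derives the second ordering from the
#'   intermediate feature `T`; `"x"` re-pools the block input instead.
#' @return an `osmlp_block` module usable with [osmlp_forward()].
#' @export
osmlp_block <- function(c, g = 5L, hidden = c, reduction = 4L,
                        order_source = c("t", "x")) {
  if (c %% g != 0L)
    stop(sprintf("channel count %d not divisible by group count %d", c, g))
  structure(list(
    type = "osmlp", c = c,
    spec_h = shift_spec(g, axis = "height"),
    spec_w = shift_spec(g, axis = "width"),
    order_source = match.arg(order_source),
    score1 = score_mlp_module(c, reduction),
    score2 = score_mlp_module(c, reduction),
    mlp4 = token_mlp(c, hidden),
    mlp8 = channel_mlp(c, hidden)
  ), class = "osmlp_block")
}

score_fun <- function(score_seq) {
  function(v) as.numeric(seq_fwd(score_seq, matrix(v, ncol = 1L))$y)
}

# per-sample channel orders for a batched map
batch_orders <- function(x4, score_seq) {
  N <- dim(x4)[4]
  lapply(seq_len(N), function(n)
    compute_channel_order(x4[, , , n, drop = FALSE], score_fun(score_seq))$order)
}

apply_orders <- function(x4, orders) {
  y <- x4
  for (n in seq_along(orders)) y[, , , n] <- x4[, , orders[[n]], n]
  y
}

osmlp_fwd <- function(mod, x4) {
  ord1 <- batch_orders(x4, mod$score1)
  xs <- apply_orders(x4, ord1)
  th <- axial_group_shift(xs, mod$spec_h)
  r4 <- seq_fwd(mod$mlp4, th)
  tt <- r4$y
  src <- if (mod$order_source == "t") tt else x4
  ord2 <- batch_orders(src, mod$score2)
  ts <- apply_orders(tt, ord2)
  tw <- axial_group_shift(ts, mod$spec_w)
  r8 <- seq_fwd(mod$mlp8, tw)
  list(y = r8$y,
       cache = list(ord1 = ord1, ord2 = ord2, c4 = r4$cache, c8 = r8$cache))
}

osmlp_bwd <- function(mod, cache, gy) {
  b8 <- seq_bwd(mod$mlp8, cache$c8, gy)
  gts <- axial_group_shift(b8$gx, negate_spec(mod$spec_w))
  gtt <- apply_orders(gts, lapply(cache$ord2, invert_order))
  b4 <- seq_bwd(mod$mlp4, cache$c4, gtt)
  gxs <- axial_group_shift(b4$gx, negate_spec(mod$spec_h))
  gx <- apply_orders(gxs, lapply(cache$ord1, invert_order))
  # hard sorts carry zero gradient: the scoring MLPs receive explicit zeros
  zeros <- function(seqm) {
    g <- flatten_params(seqm)
    lapply(g, function(a) array(0, dim(a) %||% length(a)))
  }
  g1 <- zeros(mod$score1); names(g1) <- paste0("score1.", names(g1))
  g2 <- zeros(mod$score2); names(g2) <- paste0("score2.", names(g2))
  grads <- c(prefix_grads(b4$grads, "mlp4."), prefix_grads(b8$grads, "mlp8."),
             g1, g2)
  list(gx = gx, grads = grads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full ordered shift MLP block
#'
#' Composition: order by pooled scores, shift groups along height, token MLP
#' with depthwise positional encoding, re-order (from the intermediate
#' feature by default), shift groups along width, final channel MLP. Output
#' shape equals input shape.
#'
#' @param x a (H, W, C) or (H, W, C, N) feature map.
#' @param params an [osmlp_block()].
#' @return the transformed map, same shape as `x`.
#' @export
osmlp_forward <- function(x, params) {
  x4 <- as_map4(x)
  like_input(osmlp_fwd(params, x4)$y, x)
}
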