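# Primitive differentiable layers. Every layer is a list with a `type`, its
# configuration, and a `params` list of numeric arrays. `nn_fwd()` returns
# list(y, cache); `nn_bwd()` returns list(gx, grads) with `grads` mirroring
# `params`. Feature maps are (H, W, C, N) double arrays.

as_map4 <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)   # plain vector: one column, one channel
  if (length(d) > 4L)
    stop("feature map must be a vector or a 2-d, 3-d (H,W,C) or 4-d (H,W,C,N) array")
  if (any(!is.finite(x))) stop("feature map contains non-finite values")
  dim(x) <- c(d, rep(1L, 4L - length(d)))
  x
}

# restore y to the dimensionality of the original input
like_input <- function(y, x_orig) {
  d <- dim(x_orig)
  if (is.null(d)) dim(y) <- NULL
  else if (length(d) < 4L) dim(y) <- dim(y)[seq_along(d)]
  y
}

rnorm_arr <- function(dims, sd) array(rnorm(prod(dims), sd = sd), dims)

nn_conv <- function(cin, cout, k = 3L, stride = 1L, pad = (k - 1L) %/% 2L,
                    bias = FALSE, first = FALSE) {
  p <- list(w = rnorm_arr(c(k, k, cin, cout), sd = sqrt(2 / (k * k * cin))))
  if (bias) p$b <- numeric(cout)
  # `first` marks the input layer: no gradient w.r.t. the image is needed
  list(type = "conv", k = k, stride = stride, pad = pad, bias = bias,
       cin = cin, cout = cout, first = first, params = p)
}

nn_gn <- function(c, groups = 8L, eps = 1e-5) {
  if (c %% groups != 0L)
    stop(sprintf("group norm: %d channels not divisible by %d groups", c, groups))
  list(type = "gn", groups = groups, eps = eps,
       params = list(gamma = rep(1, c), beta = rep(0, c)))
}

nn_dw3 <- function(c) {
  list(type = "dw3",
       params = list(w = rnorm_arr(c(3L, 3L, c), sd = sqrt(2 / 9)),
                     b = numeric(c)))
}

# dense map on channel vectors: x is (C, N), y = t(W) x + b
nn_linear <- function(cin, cout, bias = TRUE) {
  p <- list(w = rnorm_arr(c(cin, cout), sd = sqrt(2 / cin)))
  if (bias) p$b <- numeric(cout)
  list(type = "linear", bias = bias, params = p)
}

nn_act <- function(kind) list(type = kind, params = list())
nn_maxpool <- function() list(type = "maxpool", params = list())

gelu <- function(x) x * pnorm(x)
gelu_grad <- function(x) pnorm(x) + x * dnorm(x)

nn_fwd <- function(layer, x) {
  switch(layer$type,
    conv = {
      b <- if (layer$bias) layer$params$b else NULL
      if (isTRUE(getOption("dranet.fp32", FALSE))) {
        # fp32 path keeps the patch matrix so backward skips its rebuild
        r <- cpp_conv2d_fwd_ws(x, layer$params$w, b, layer$stride, layer$pad)
        list(y = r$y, cache = list(ws = r$ws, xdim = dim(x)))
      } else {
        y <- cpp_conv2d_fwd(x, layer$params$w, b, layer$stride, layer$pad,
                            FALSE)
        list(y = y, cache = x)
      }
    },
    gn = {
      r <- cpp_groupnorm_fwd(x, layer$params$gamma, layer$params$beta,
                             layer$groups, layer$eps)
      list(y = r$y, cache = list(x = x, mu = r$mu, istd = r$istd))
    },
    dw3 = list(y = cpp_dwconv3_fwd(x, layer$params$w, layer$params$b),
               cache = x),
    linear = {
      y <- crossprod(layer$params$w, x)
      if (layer$bias) y <- y + layer$params$b
      list(y = y, cache = x)
    },
    relu = list(y = pmax(x, 0), cache = x),
    gelu = list(y = gelu(x), cache = x),
    sigmoid = { y <- plogis(x); list(y = y, cache = y) },
    maxpool = {
      r <- cpp_maxpool_fwd(x)
      list(y = r$y, cache = list(argmax = r$argmax, xdim = dim(x)))
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_bwd <- function(layer, cache, gy) {
  switch(layer$type,
    conv = {
      need_gx <- !isTRUE(layer$first)
      r <- if (is.list(cache))
        cpp_conv2d_bwd(cache$ws, layer$params$w, gy, layer$stride, layer$pad,
                       layer$bias, TRUE, cache$xdim, need_gx)
      else
        cpp_conv2d_bwd(cache, layer$params$w, gy, layer$stride, layer$pad,
                       layer$bias, isTRUE(getOption("dranet.fp32", FALSE)),
                       NULL, need_gx)
      g <- list(w = r$gw); if (layer$bias) g$b <- r$gb
      list(gx = r$gx, grads = g)
    },
    gn = {
      r <- cpp_groupnorm_bwd(cache$x, layer$params$gamma, gy, cache$mu,
                             cache$istd, layer$groups)
      list(gx = r$gx, grads = list(gamma = r$ggamma, beta = r$gbeta))
    },
    dw3 = {
      r <- cpp_dwconv3_bwd(cache, layer$params$w, gy)
      list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
    },
    linear = {
      gx <- layer$params$w %*% gy
      g <- list(w = cache %*% t(gy))
      if (layer$bias) g$b <- rowSums(gy)
      list(gx = gx, grads = g)
    },
    relu = list(gx = gy * (cache > 0), grads = list()),
    gelu = list(gx = gy * gelu_grad(cache), grads = list()),
    sigmoid = list(gx = gy * cache * (1 - cache), grads = list()),
    maxpool = list(gx = cpp_maxpool_bwd(gy, cache$argmax, cache$xdim),
                   grads = list()),
    stop("unknown layer type: ", layer$type)
  )
}

# sequential container
nn_seq <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.null(layers[[1]]$type)) layers <- layers[[1]]
  list(type = "seq", layers = layers)
}

seq_fwd <- function(seqm, x) {
  caches <- vector("list", length(seqm$layers))
  for (i in seq_along(seqm$layers)) {
    r <- nn_fwd(seqm$layers[[i]], x)
    x <- r$y
    caches[[i]] <- r$cache
  }
  list(y = x, cache = caches)
}

# gradients come back as a flat named list whose names match the paths
# produced by flatten_params() on the same module, so the optimizer can pair
# them positionally by name
seq_bwd <- function(seqm, cache, gy) {
  grads <- list()
  for (i in rev(seq_along(seqm$layers))) {
    r <- nn_bwd(seqm$layers[[i]], cache[[i]], gy)
    gy <- r$gx
    if (length(r$grads))
      grads <- c(grads, prefix_grads(r$grads, paste0("layers.", i, ".")))
  }
  list(gx = gy, grads = grads)
}

prefix_grads <- function(g, prefix) {
  if (length(g)) names(g) <- paste0(prefix, names(g))
  g
}

# --- parameter plumbing -----------------------------------------------------

# depth-first collection of every parameter array in a module tree; names are
# dot-joined paths, order is the traversal order (stable, used by the
# optimizer to pair parameters with gradients)
flatten_params <- function(node, prefix = "") {
  out <- list()
  if (!is.list(node)) return(out)
  nms <- names(node)
  if (is.null(nms)) nms <- rep("", length(node))
  for (i in seq_along(node)) {
    nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
    child <- node[[i]]
    if (identical(nms[i], "params")) {
      for (pn in names(child)) out[[paste0(prefix, pn)]] <- child[[pn]]
    } else if (is.list(child)) {
      out <- c(out, flatten_params(child, paste0(prefix, nm, ".")))
    }
  }
  out
}
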