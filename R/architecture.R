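# Full network assembly: group-normalized residual encoder (ResNet34-style
# feature extraction with stage depths of 2), ordered-shift-MLP + DRA
# insertion sites, and a bilinear-upsampling decoder with long skip
# connections. Also houses the parameter/FLOP profiler.

#' Model configuration
#'
#' @param input_size spatial size (pixels) of the square network input.
#' @param stage_widths channel counts of the five encoder stages.
#' @param stage_depths residual block counts; stages 2-5 default to 2.
#' @param norm_groups group-norm group count (must divide every width).
#' @param block_sites encoder stages (by index, 1-5) at which the ordered
#'   shift MLP + DRA combination is inserted; default deepest stage only.
#' @param use_mlp,use_dra enable the ordered shift MLP branch / DRA gate
#'   (the four ablation variants: conv, +MLP, +DRA, +both).
#' @param dra a [dra_config()].
#' @param osmlp_g shift group count (must divide the site width).
#' @param osmlp_hidden hidden width of the two channel MLPs in the block;
#'   the default is chosen so the block's parameter cost matches the
#'   published budget of the architecture.
#' @param dra_hidden bottleneck width of the DRA channel projection (same
#'   budget consideration); `NULL` for a plain linear collapse.
#' @param decoder_widths output widths of the four decoder stages.
#' @param classes number of output channels (1, binary).
#' @return a `model_config` list.
#' @export
model_config <- function(input_size = 224L,
                         stage_widths = c(64L, 64L, 128L, 256L, 512L),
                         stage_depths = c(1L, 2L, 2L, 2L, 2L),
                         norm_groups = 8L,
                         block_sites = 5L,
                         use_mlp = TRUE, use_dra = TRUE,
                         dra = dra_config(),
                         osmlp_g = 4L, osmlp_hidden = 332L,
                         dra_hidden = 16L,
                         decoder_widths = c(256L, 128L, 64L, 32L),
                         classes = 1L) {
  stopifnot(length(stage_widths) == 5L, length(stage_depths) == 5L,
            all(stage_widths >= 1L), all(stage_depths >= 1L),
            length(decoder_widths) == 4L, classes == 1L)
  if (any(stage_widths %% norm_groups != 0L) ||
      any(decoder_widths %% norm_groups != 0L))
    stop("every stage width must be divisible by norm_groups")
  if (any(block_sites < 1L | block_sites > 5L))
    stop("block_sites must index encoder stages 1-5")
  structure(list(input_size = as.integer(input_size),
                 stage_widths = as.integer(stage_widths),
                 stage_depths = as.integer(stage_depths),
                 norm_groups = as.integer(norm_groups),
                 block_sites = as.integer(block_sites),
                 use_mlp = isTRUE(use_mlp), use_dra = isTRUE(use_dra),
                 dra = dra, osmlp_g = as.integer(osmlp_g),
                 osmlp_hidden = as.integer(osmlp_hidden),
                 dra_hidden = if (is.null(dra_hidden)) NULL else as.integer(dra_hidden),
                 decoder_widths = as.integer(decoder_widths),
                 classes = as.integer(classes)),
            class = "model_config")
}

# residual basic block: two 3x3 convs with group norm + ReLU, identity
# shortcut (projection 1x1 conv + GN when the shape changes)
basic_block <- function(cin, cout, stride = 1L, groups = 8L) {
  main <- nn_seq(list(nn_conv(cin, cout, 3L, stride), nn_gn(cout, groups),
                      nn_act("relu"),
                      nn_conv(cout, cout, 3L, 1L), nn_gn(cout, groups)))
  proj <- if (stride != 1L || cin != cout)
    nn_seq(list(nn_conv(cin, cout, 1L, stride, 0L), nn_gn(cout, groups)))
  else NULL
  structure(list(type = "basic_block", main = main, proj = proj),
            class = "basic_block")
}

block_fwd <- function(blk, x) {
  rm_ <- seq_fwd(blk$main, x)
  if (is.null(blk$proj)) {
    sc <- x; cp <- NULL
  } else {
    rp <- seq_fwd(blk$proj, x); sc <- rp$y; cp <- rp$cache
  }
  pre <- rm_$y + sc
  list(y = pmax(pre, 0),
       cache = list(cm = rm_$cache, cp = cp, pre = pre))
}

block_bwd <- function(blk, cache, gy) {
  gpre <- gy * (cache$pre > 0)
  bm <- seq_bwd(blk$main, cache$cm, gpre)
  grads <- prefix_grads(bm$grads, "main.")
  if (is.null(blk$proj)) {
    gx <- bm$gx + gpre
  } else {
    bp <- seq_bwd(blk$proj, cache$cp, gpre)
    gx <- bm$gx + bp$gx
    grads <- c(grads, prefix_grads(bp$grads, "proj."))
  }
  list(gx = gx, grads = grads)
}

#' Build the staged encoder
#'
#' Stage 1 is a 7x7 stride-2 stem (1/2 resolution); stage 2 runs residual
#' basic blocks after a 3x3 stride-2 max pool (1/4); stages 3-5 halve the
#' resolution with a stride-2 first block (1/8, 1/16, 1/32).
#'
#' @param cfg a [model_config()].
#' @return an encoder module.
#' @export
build_encoder <- function(cfg) {
  w <- cfg$stage_widths; g <- cfg$norm_groups
  stem <- nn_seq(list(nn_conv(3L, w[1], 7L, 2L, 3L, first = TRUE),
                      nn_gn(w[1], g), nn_act("relu")))
  stages <- vector("list", 4L)
  cin <- w[1]
  for (s in 2:5) {
    blocks <- vector("list", cfg$stage_depths[s])
    stride1 <- if (s == 2L) 1L else 2L  # stage 2 is downsampled by the max pool
    for (b in seq_len(cfg$stage_depths[s])) {
      blocks[[b]] <- basic_block(cin, w[s], if (b == 1L) stride1 else 1L, g)
      cin <- w[s]
    }
    stages[[s - 1L]] <- blocks
  }
  structure(list(type = "encoder", stem = stem, pool = nn_maxpool(),
                 stages = stages), class = "dranet_encoder")
}

encoder_fwd <- function(enc, x) {
  r0 <- seq_fwd(enc$stem, x)
  rp <- nn_fwd(enc$pool, r0$y)
  feats <- vector("list", 5L)
  feats[[1]] <- r0$y
  caches <- list(stem = r0$cache, pool = rp$cache, stages = vector("list", 4L))
  h <- rp$y
  for (s in seq_along(enc$stages)) {
    cs <- vector("list", length(enc$stages[[s]]))
    for (b in seq_along(enc$stages[[s]])) {
      r <- block_fwd(enc$stages[[s]][[b]], h)
      h <- r$y; cs[[b]] <- r$cache
    }
    caches$stages[[s]] <- cs
    feats[[s + 1L]] <- h
  }
  list(feats = feats, cache = caches)
}

# gfeats: gradients w.r.t. each stage output (list of 5, NULL allowed)
encoder_bwd <- function(enc, cache, gfeats) {
  grads <- list()
  gh <- NULL
  for (s in rev(seq_along(enc$stages))) {
    gs <- gfeats[[s + 1L]]
    gh <- if (is.null(gh)) gs else if (is.null(gs)) gh else gh + gs
    for (b in rev(seq_along(enc$stages[[s]]))) {
      r <- block_bwd(enc$stages[[s]][[b]], cache$stages[[s]][[b]], gh)
      gh <- r$gx
      grads <- c(grads, prefix_grads(r$grads,
                                     paste0("stages.", s, ".", b, ".")))
    }
  }
  gpool <- nn_bwd(enc$pool, cache$pool, gh)$gx
  gstem <- gpool
  if (!is.null(gfeats[[1]])) gstem <- gstem + gfeats[[1]]
  bs <- seq_bwd(enc$stem, cache$stem, gstem)
  grads <- c(grads, prefix_grads(bs$grads, "stem."))
  list(gx = bs$gx, grads = grads)
}

decoder_stage <- function(cin_up, cskip, cout, groups = 8L) {
  structure(list(type = "decoder_stage", cskip = cskip,
                 convs = nn_seq(list(
                   nn_conv(cin_up + cskip, cout, 3L), nn_gn(cout, groups),
                   nn_act("relu"),
                   nn_conv(cout, cout, 3L), nn_gn(cout, groups),
                   nn_act("relu")))),
            class = "decoder_stage")
}

# bilinear upsampling straight to the skip's resolution (supports inputs
# whose pyramid sizes are odd)
dstage_fwd <- function(st, x, skip) {
  up <- cpp_bilinear_fwd(x, dim(skip)[1], dim(skip)[2])
  if (dim(skip)[1] < dim(x)[1])
    stop("decoder assembly error: skip resolution mismatch")
  cat_in <- abind4(up, skip)
  rc <- seq_fwd(st$convs, cat_in)
  list(y = rc$y, cache = list(xdim = dim(x), cc = rc$cache, cup = dim(x)[3]))
}

dstage_bwd <- function(st, cache, gy) {
  bc <- seq_bwd(st$convs, cache$cc, gy)
  cup <- cache$cup
  gup <- bc$gx[, , seq_len(cup), , drop = FALSE]
  gskip <- bc$gx[, , -seq_len(cup), , drop = FALSE]
  gx <- cpp_bilinear_bwd(gup, cache$xdim[1], cache$xdim[2])
  list(gx = gx, gskip = gskip, grads = prefix_grads(bc$grads, "convs."))
}

# concatenate two (H,W,C,N) maps along channels
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

#' Build the staged decoder
#'
#' Each stage bilinearly doubles the resolution (half-pixel-centered),
#' concatenates the same-level encoder feature and applies two
#' conv-norm-ReLU units; a final x2 upsample, 1x1 convolution and sigmoid
#' yield the probability map at input resolution.
#'
#' @param cfg a [model_config()].
#' @return a decoder module.
#' @export
build_decoder <- function(cfg) {
  w <- cfg$stage_widths; dw <- cfg$decoder_widths; g <- cfg$norm_groups
  stages <- list(
    decoder_stage(w[5], w[4], dw[1], g),
    decoder_stage(dw[1], w[3], dw[2], g),
    decoder_stage(dw[2], w[2], dw[3], g),
    decoder_stage(dw[3], w[1], dw[4], g)
  )
  structure(list(type = "decoder", stages = stages,
                 head = nn_conv(dw[4], cfg$classes, 1L, 1L, 0L, bias = TRUE),
                 out_act = nn_act("sigmoid")),
            class = "dranet_decoder")
}

decoder_fwd <- function(dec, feats, out_hw) {
  h <- feats[[5]]
  caches <- vector("list", 4L)
  for (i in seq_len(4L)) {
    r <- dstage_fwd(dec$stages[[i]], h, feats[[5L - i]])
    h <- r$y; caches[[i]] <- r$cache
  }
  hdim <- dim(h)
  up <- cpp_bilinear_fwd(h, out_hw[1], out_hw[2])
  rh <- nn_fwd(dec$head, up)
  ra <- nn_fwd(dec$out_act, rh$y)
  list(y = ra$y, cache = list(stages = caches, cup = hdim,
                              chead = rh$cache, cact = ra$cache))
}

decoder_bwd <- function(dec, cache, gy) {
  ga <- nn_bwd(dec$out_act, cache$cact, gy)
  bh <- nn_bwd(dec$head, cache$chead, ga$gx)
  gh <- cpp_bilinear_bwd(bh$gx, cache$cup[1], cache$cup[2])
  grads <- prefix_grads(bh$grads, "head.")
  gskips <- vector("list", 5L)
  for (i in rev(seq_len(4L))) {
    r <- dstage_bwd(dec$stages[[i]], cache$stages[[i]], gh)
    gh <- r$gx
    gskips[[5L - i]] <- r$gskip
    grads <- c(grads, prefix_grads(r$grads, paste0("stages.", i, ".")))
  }
  gskips[[5]] <- gh  # gradient w.r.t. the bottleneck feature
  list(gskips = gskips, grads = grads)
}

#' Assemble the full segmentation network
#'
#' Encoder, then at each `block_site` the ordered-shift-MLP branch gated by
#' dynamic regional attention is added to the convolutional stream, then the
#' skip-connected decoder. The forward pass on an (H, W, 3) image returns an
#' H x W probability map in (0, 1).
#'
#' @param cfg a [model_config()].
#' @return a `dranet_model`.
#' @export
assemble <- function(cfg) {
  enc <- build_encoder(cfg)
  dec <- build_decoder(cfg)
  half <- function(s) as.integer(ceiling(s / 2))
  res <- Reduce(function(s, i) half(s), 1:5, accumulate = TRUE,
                init = cfg$input_size)[-1]
  sites <- list()
  if (cfg$use_mlp || cfg$use_dra) {
    for (s in cfg$block_sites) {
      cs <- cfg$stage_widths[s]
      site <- list(stage = s)
      if (cfg$use_mlp)
        site$osmlp <- osmlp_block(cs, g = cfg$osmlp_g, hidden = cfg$osmlp_hidden)
      if (cfg$use_dra) {
        dcfg <- cfg$dra
        px <- res[s]^2
        if (dcfg$k > px) {
          warning(sprintf(
            "DRA k = %d exceeds the %d pixels of the stage-%d map at input size %d; using k = %d",
            dcfg$k, px, s, cfg$input_size, px))
          dcfg$k <- px
        }
        site$dra <- dra_block(cs, dcfg, hidden = cfg$dra_hidden)
      }
      sites[[length(sites) + 1L]] <- site
    }
  }
  structure(list(cfg = cfg, enc = enc, sites = sites, dec = dec),
            class = "dranet_model")
}

# site forward: conv stream x -> x + gated branch
site_fwd <- function(site, x) {
  cache <- list()
  if (!is.null(site$osmlp)) {
    rb <- osmlp_fwd(site$osmlp, x)
    branch <- rb$y; cache$cosmlp <- rb$cache
  } else branch <- x
  if (!is.null(site$dra)) {
    rd <- dra_fwd(site$dra, x, branch)
    gated <- rd$y; cache$cdra <- rd$cache
  } else gated <- branch
  list(y = x + gated, cache = cache)
}

site_bwd <- function(site, cache, gy) {
  # y = x + gated(branch(x)); accumulate the three paths into gx explicitly
  grads <- list()
  gx <- gy                      # identity path
  gbranch <- gy                 # gradient reaching the branch output
  if (!is.null(site$dra)) {
    rd <- dra_bwd(site$dra, cache$cdra, gy)
    gx <- gx + rd$gx            # projection/gate path into x
    gbranch <- rd$gbranch
    grads <- c(grads, prefix_grads(rd$grads, "dra."))
  }
  if (!is.null(site$osmlp)) {
    rb <- osmlp_bwd(site$osmlp, cache$cosmlp, gbranch)
    gx <- gx + rb$gx
    grads <- c(grads, prefix_grads(rb$grads, "osmlp."))
  } else {
    gx <- gx + gbranch          # branch was the identity map on x
  }
  list(gx = gx, grads = grads)
}

#' Forward pass of the assembled model
#'
#' @param model a `dranet_model`.
#' @param x image batch (H, W, 3) or (H, W, 3, N), values in `[0, 1]`.
#' @param training keep caches for a subsequent [model_backward()].
#' @return probabilities (H, W, 1, N) (with `training = TRUE`, a list
#'   `(y, cache)`).
#' @export
model_forward <- function(model, x, training = FALSE) {
  x4 <- as_map4(x)
  re <- encoder_fwd(model$enc, x4)
  feats <- re$feats
  scache <- vector("list", length(model$sites))
  for (i in seq_along(model$sites)) {
    s <- model$sites[[i]]$stage
    r <- site_fwd(model$sites[[i]], feats[[s]])
    feats[[s]] <- r$y
    scache[[i]] <- r$cache
  }
  rd <- decoder_fwd(model$dec, feats, dim(x4)[1:2])
  if (!training) return(rd$y)
  list(y = rd$y, cache = list(cenc = re$cache, cs = scache, cdec = rd$cache))
}

#' Backward pass; returns the flat named gradient list
#'
#' @param model a `dranet_model`; @param cache from
#'   `model_forward(training = TRUE)`; @param gy gradient of the loss
#'   w.r.t. the probability output.
#' @return named list of gradient arrays (names match `flatten_params`).
#' @export
model_backward <- function(model, cache, gy) {
  rd <- decoder_bwd(model$dec, cache$cdec, gy)
  gfeats <- rd$gskips
  grads <- prefix_grads(rd$grads, "dec.")
  for (i in rev(seq_along(model$sites))) {
    s <- model$sites[[i]]$stage
    r <- site_bwd(model$sites[[i]], cache$cs[[i]], gfeats[[s]])
    gfeats[[s]] <- r$gx
    grads <- c(grads, prefix_grads(r$grads, paste0("sites.", i, ".")))
  }
  re <- encoder_bwd(model$enc, cache$cenc, gfeats)
  c(grads, prefix_grads(re$grads, "enc."))
}
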