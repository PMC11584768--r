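# Parameter and FLOP accounting. Parameters are counted from the actual
# arrays of the assembled model; FLOPs are closed-form multiply-accumulate
# counts (1 MAC = 1 FLOP) over convolutions, linear maps and the DRA
# distance computations. Normalization, activation and interpolation
# element-operations are excluded, the usual profiler convention.

#' Count trainable parameters
#'
#' @param model a `dranet_model` (or any module tree).
#' @return a `profile_report` with the total, the total in millions (two
#'   decimals) and a per-module breakdown.
#' @export
count_parameters <- function(model) {
  ps <- flatten_params(model)
  n <- vapply(ps, length, integer(1))
  top <- sub("\\..*$", "", names(ps))
  breakdown <- vapply(split(n, top), sum, numeric(1))
  breakdown <- breakdown[order(-breakdown)]
  structure(list(kind = "parameters",
                 total = sum(n),
                 parameters_millions = round(sum(n) / 1e6, 2),
                 breakdown = data.frame(module = names(breakdown),
                                        parameters = as.numeric(breakdown),
                                        row.names = NULL)),
            class = "profile_report")
}

conv_macs <- function(hw_out, k, cin, cout) prod(hw_out) * k * k * cin * cout

# FLOPs of one forward pass at the given input size, derived from the
# configuration (spatial sizes traced through the architecture)
#' Count forward-pass FLOPs
#'
#' Multiply-accumulate counts at a fixed input size, including the DRA
#' similarity searches (H*W x searched-centers x iterations MACs per site),
#' which generic profilers skip.
#'
#' @param model a `dranet_model`.
#' @param input_size spatial input size in pixels (default: the model's).
#' @return a `profile_report` with GFLOPs and a per-module breakdown.
#' @export
count_flops <- function(model, input_size = model$cfg$input_size) {
  cfg <- model$cfg
  w <- cfg$stage_widths; dw <- cfg$decoder_widths
  sz <- as.integer(input_size)
  half <- function(s) as.integer(ceiling(s / 2))
  s1 <- half(sz); s2 <- half(s1); s3 <- half(s2); s4 <- half(s3); s5 <- half(s4)
  res <- c(s1, s2, s3, s4, s5)
  fl <- c(enc = 0, sites = 0, dec = 0)
  fl["enc"] <- conv_macs(c(s1, s1), 7L, 3L, w[1])
  cin <- w[1]
  for (s in 2:5) {
    r <- res[s]
    for (b in seq_len(cfg$stage_depths[s])) {
      fl["enc"] <- fl["enc"] + conv_macs(c(r, r), 3L, cin, w[s]) +
        conv_macs(c(r, r), 3L, w[s], w[s])
      if (cin != w[s]) fl["enc"] <- fl["enc"] + conv_macs(c(r, r), 1L, cin, w[s])
      cin <- w[s]
    }
  }
  for (site in model$sites) {
    r <- res[site$stage]; cs <- w[site$stage]
    if (!is.null(site$osmlp)) {
      h <- cfg$osmlp_hidden
      fl["sites"] <- fl["sites"] +
        2 * (conv_macs(c(r, r), 1L, cs, h) + conv_macs(c(r, r), 1L, h, cs)) +
        r * r * 9 * cs +                       # depthwise positional conv
        2 * 2 * (cs * (cs %/% 4) * 2)          # two score MLPs x two pools
    }
    if (!is.null(site$dra)) {
      hd <- cfg$dra_hidden
      proj <- if (is.null(hd)) conv_macs(c(r, r), 1L, cs, 1L)
              else conv_macs(c(r, r), 1L, cs, hd) + conv_macs(c(r, r), 1L, hd, 1L)
      fl["sites"] <- fl["sites"] + proj +
        r * r * min(model$cfg$dra$k, r * r) * model$cfg$dra$iterations
    }
  }
  skips <- c(w[4], w[3], w[2], w[1])
  ups <- c(w[5], dw[1], dw[2], dw[3])
  drs <- c(s4, s3, s2, s1)
  for (i in 1:4) {
    r <- drs[i]
    fl["dec"] <- fl["dec"] + conv_macs(c(r, r), 3L, ups[i] + skips[i], dw[i]) +
      conv_macs(c(r, r), 3L, dw[i], dw[i])
  }
  fl["dec"] <- fl["dec"] + conv_macs(c(sz, sz), 1L, dw[4], cfg$classes)
  structure(list(kind = "flops",
                 total = sum(fl),
                 gflops = round(sum(fl) / 1e9, 2),
                 input_size = sz,
                 breakdown = data.frame(module = names(fl),
                                        macs = as.numeric(fl),
                                        row.names = NULL)),
            class = "profile_report")
}

#' @export
print.profile_report <- function(x, ...) {
  if (x$kind == "parameters")
    cat(sprintf("Trainable parameters: %s (%.2f M)\n",
                format(x$total, big.mark = ","), x$parameters_millions))
  else
    cat(sprintf("Forward FLOPs at %dx%d: %s MACs (%.2f GFLOPs)\n",
                x$input_size, x$input_size, format(x$total, big.mark = ","),
                x$gflops))
  print(x$breakdown, row.names = FALSE)
  invisible(x)
}

#' Emit a profile report as JSON
#' @param x a `profile_report`; @param path output file.
#' @export
write_profile <- function(x, path) {
  jsonlite::write_json(unclass(x), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Save model weights and configuration to a single checkpoint file
#' @param model a `dranet_model`; @param path file path; @param extra
#'   optional metadata list (seed, history, ...).
#' @export
save_checkpoint <- function(model, path, extra = list()) {
  saveRDS(list(cfg = model$cfg, params = flatten_params(model),
               extra = extra), path)
  invisible(path)
}

#' Load a checkpoint saved by [save_checkpoint()]
#' @param path checkpoint file.
#' @return list with `model` (weights restored) and `extra`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- assemble(ck$cfg)
  model <- set_params(model, ck$params)
  list(model = model, extra = ck$extra)
}

# write a flat named parameter list back into a module tree (names as
# produced by flatten_params)
set_params <- function(node, flat, prefix = "") {
  if (!is.list(node)) return(node)
  nms <- names(node)
  if (is.null(nms)) nms <- rep("", length(node))
  for (i in seq_along(node)) {
    nm <- if (nzchar(nms[i])) nms[i] else as.character(i)
    if (identical(nms[i], "params")) {
      for (pn in names(node[[i]])) {
        key <- paste0(prefix, pn)
        if (!key %in% names(flat)) stop("checkpoint is missing parameter ", key)
        tgt <- flat[[key]]
        if (length(tgt) != length(node[[i]][[pn]]))
          stop("checkpoint/config shape mismatch for parameter ", key)
        # keep the same array object when shapes already agree, so the
        # optimizer's in-place updates stay visible through the model tree
        if (!identical(dim(tgt), dim(node[[i]][[pn]])))
          dim(tgt) <- dim(node[[i]][[pn]])
        node[[i]][[pn]] <- tgt
      }
    } else if (is.list(node[[i]])) {
      node[[i]] <- set_params(node[[i]], flat, paste0(prefix, nm, "."))
    }
  }
  node
}
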