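# Independent oracles and small utilities shared across tests. These
# deliberately re-derive results from first principles (naive loops,
# enumeration) rather than calling the implementation they check.

# central finite-difference gradient of f at x (array), elementwise
fd_grad <- function(f, x, eps = 1e-6, idx = seq_along(x)) {
  g <- array(0, dim(x) %||% length(x))
  for (i in idx) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_err <- function(a, b) {
  denom <- pmax(abs(a) + abs(b), 1e-6)
  max(abs(a - b) / denom)
}

# roll-with-zero-fill oracle for grouped axial shifts (naive per-element)
naive_shift <- function(x, group_count, offsets, axis) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  gs <- C / group_count
  y <- array(0, d)
  for (c in seq_len(C)) {
    g <- ceiling(c / gs)
    o <- offsets[g]
    for (h in seq_len(H)) for (w in seq_len(W)) {
      if (axis == "height") { sh <- h - o; sw <- w } else { sh <- h; sw <- w - o }
      if (sh >= 1 && sh <= H && sw >= 1 && sw <= W) y[h, w, c] <- x[sh, sw, c]
    }
  }
  y
}

# brute-force 1-D k-means with grid-sampled init, Lloyd iterations, empty
# repair at the farthest value, and a final assignment pass -- the same
# protocol the partitioner specifies, written independently
naive_kmeans1d <- function(p, k, iters) {
  H <- nrow(p); W <- ncol(p)
  v <- as.vector(p)
  gr <- ceiling(sqrt(k))
  centers <- numeric(k)
  for (i in seq_len(k)) {
    r <- (i - 1) %/% gr; cc <- (i - 1) %% gr
    hh <- min(H - 1, floor((r + 0.5) * H / gr))
    ww <- min(W - 1, floor((cc + 0.5) * W / gr))
    centers[i] <- p[hh + 1, ww + 1]
  }
  assign_all <- function() {
    sapply(v, function(x) which.min(abs(x - centers)))
  }
  lab <- NULL
  for (it in seq_len(iters)) {
    lab <- assign_all()
    for (c in seq_len(k)) {
      if (any(lab == c)) centers[c] <- mean(v[lab == c])
      else centers[c] <- v[which.max(abs(v - centers[c]))]
    }
  }
  lab <- assign_all()
  for (pass in seq_len(k)) {
    if (all(seq_len(k) %in% lab)) break
    for (c in setdiff(seq_len(k), unique(lab)))
      centers[c] <- v[which.max(abs(v - centers[c]))]
    lab <- assign_all()
  }
  matrix(lab - 1L, H, W)
}

# naive per-region mean oracle
naive_region_mean <- function(p, labels) {
  y <- p
  for (l in unique(as.vector(labels)))
    y[labels == l] <- mean(p[labels == l])
  y
}

# 4-connected component count via BFS flood fill (independent of the
# generator's bookkeeping)
count_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  seen <- matrix(FALSE, H, W)
  ncomp <- 0L
  for (h0 in seq_len(H)) for (w0 in seq_len(W)) {
    if (mask[h0, w0] == 0 || seen[h0, w0]) next
    ncomp <- ncomp + 1L
    queue <- list(c(h0, w0)); seen[h0, w0] <- TRUE
    while (length(queue)) {
      q <- queue[[1]]; queue <- queue[-1]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        h <- q[1] + d[1]; w <- q[2] + d[2]
        if (h >= 1 && h <= H && w >= 1 && w <= W && mask[h, w] != 0 &&
            !seen[h, w]) {
          seen[h, w] <- TRUE
          queue[[length(queue) + 1L]] <- c(h, w)
        }
      }
    }
  }
  ncomp
}

# tiny model configuration used wherever a full-size network is unnecessary
tiny_model_config <- function(input_size = 64L,
                              dra = dra_config(k = 2L, iterations = 2L),
                              ...) {
  model_config(input_size = input_size,
               stage_widths = c(8L, 8L, 16L, 16L, 16L),
               norm_groups = 4L, osmlp_g = 2L, osmlp_hidden = 8L,
               dra_hidden = 4L, decoder_widths = c(16L, 16L, 8L, 8L),
               dra = dra, ...)
}

make_samples <- function(n, size = 48L, preset = "easy", seed_base = 1000L) {
  spec <- scene_preset(preset, size = c(size, size))
  lapply(seq_len(n), function(i) {
    sp <- spec; sp$seed <- seed_base + i
    generate_sample(sp)
  })
}
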