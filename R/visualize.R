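# Region-partition visualization: PNG overlays with region boundaries and
# the receptive-field box of a chosen pixel.

#' Visualize a region partition as a PNG overlay
#'
#' Draws region boundaries (dark outline) over a grayscale rendering of the
#' map and, for `focus` pixels, a red box marking the 2s x 2s local search
#' window (the receptive field of the local mode).
#'
#' @param p an H x W matrix (projected map); @param part a
#'   `region_partition` from [partition_regions()]; @param path output PNG.
#' @param focus optional list of `c(h, w)` pixel coordinates to box.
#' @param s window half-size in pixels (defaults to `sqrt(H*W/k)`).
#' @return invisibly, the RGB overlay array.
#' @export
visualize_regions <- function(p, part, path = NULL, focus = NULL, s = NULL) {
  H <- nrow(p); W <- ncol(p)
  if (is.null(s)) s <- sqrt(H * W / part$k)
  g <- (p - min(p)) / max(1e-12, diff(range(p)))
  img <- array(rep(g, 3L), c(H, W, 3L))
  lab <- part$labels
  edge <- matrix(FALSE, H, W)
  edge[-H, ] <- edge[-H, ] | lab[-H, ] != lab[-1, ]
  edge[, -W] <- edge[, -W] | lab[, -W] != lab[, -1]
  for (c3 in 1:3) { ch <- img[, , c3]; ch[edge] <- if (c3 == 2) 0.9 else 0.1; img[, , c3] <- ch }
  box <- function(h0, h1, w0, w1) {
    h0 <- max(1L, h0); h1 <- min(H, h1); w0 <- max(1L, w0); w1 <- min(W, w1)
    img[h0:h1, c(w0, w1), 1] <<- 1; img[h0:h1, c(w0, w1), 2:3] <<- 0
    img[c(h0, h1), w0:w1, 1] <<- 1; img[c(h0, h1), w0:w1, 2:3] <<- 0
  }
  for (f in focus %||% list())
    box(as.integer(f[1] - 2 * s), as.integer(f[1] + 2 * s),
        as.integer(f[2] - 2 * s), as.integer(f[2] + 2 * s))
  if (!is.null(path)) png::writePNG(img, path)
  invisible(img)
}
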