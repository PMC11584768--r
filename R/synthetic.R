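# Synthetic histology-style scenes: stain-tinted textured elliptical or
# ring ("gland"-like, with lumen) objects on a textured background, fuzzy
# boundaries, additive noise, and exact binary masks rendered before any
# blurring. Deterministic per seed, so every pipeline stage is testable
# without external data.

#' Scene specification for the synthetic generator
#'
#' @param size (H, W) canvas in pixels.
#' @param n_objects integer range (min, max) of objects per scene.
#' @param object_kind `"blob"` (filled ellipse) or `"ring"` (annulus with a
#'   lumen, gland-like).
#' @param intensity_range foreground stain intensity bounds in `[0, 1]`.
#' @param boundary_blur Gaussian sigma (pixels) applied to the object/
#'   background compositing mask (the stored mask stays exact).
#' @param noise_sigma additive Gaussian noise scale.
#' @param axis_range object semi-axis bounds as fractions of the canvas.
#' @param margin canvas margin (pixels) objects must keep clear.
#' @param seed integer seed; identical seeds give bit-identical samples.
#' @return a `scene_spec` list.
#' @export
scene_spec <- function(size = c(96L, 96L), n_objects = c(3L, 6L),
                       object_kind = c("blob", "ring"),
                       intensity_range = c(0.45, 0.85),
                       boundary_blur = 1.5, noise_sigma = 0.04,
                       axis_range = c(0.08, 0.16), margin = 4L,
                       seed = 1L) {
  object_kind <- match.arg(object_kind)
  stopifnot(length(size) == 2L, all(size >= 16L), n_objects[1] >= 1L,
            n_objects[2] >= n_objects[1], boundary_blur >= 0,
            noise_sigma >= 0, axis_range[1] > 0)
  structure(list(size = as.integer(size), n_objects = as.integer(n_objects),
                 object_kind = object_kind,
                 intensity_range = intensity_range,
                 boundary_blur = boundary_blur, noise_sigma = noise_sigma,
                 axis_range = axis_range, margin = as.integer(margin),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Named presets mirroring the qualitative contrast between a compact,
#' regular glandular dataset and a scattered, complicated one
#'
#' @param name `"glas_like"` (compact glandular rings, regular boundaries,
#'   mild noise) or `"cocahis_like"` (scattered irregular blobs, strong blur
#'   and noise) or `"easy"` (high-contrast blobs for fast-converging
#'   training checks).
#' @param size canvas size; @param seed integer seed.
#' @return a [scene_spec()].
#' @export
scene_preset <- function(name = c("easy", "glas_like", "cocahis_like"),
                         size = c(96L, 96L), seed = 1L) {
  switch(match.arg(name),
    easy = scene_spec(size = size, n_objects = c(2L, 4L),
                      object_kind = "blob", intensity_range = c(0.55, 0.8),
                      boundary_blur = 1.0, noise_sigma = 0.03,
                      axis_range = c(0.10, 0.18), seed = seed),
    glas_like = scene_spec(size = size, n_objects = c(3L, 6L),
                           object_kind = "ring",
                           intensity_range = c(0.45, 0.75),
                           boundary_blur = 1.5, noise_sigma = 0.04,
                           seed = seed),
    cocahis_like = scene_spec(size = size, n_objects = c(5L, 9L),
                              object_kind = "blob",
                              intensity_range = c(0.35, 0.7),
                              boundary_blur = 2.5, noise_sigma = 0.08,
                              axis_range = c(0.05, 0.12), seed = seed))
}

# run code under a temporary RNG state so generation is pure in its seed
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Perlin-style value noise: random coarse lattice, half-pixel bilinear
# upsampling, two octaves
value_noise <- function(H, W, scale = 12) {
  octave <- function(sc) {
    gh <- max(2L, as.integer(ceiling(H / sc))); gw <- max(2L, as.integer(ceiling(W / sc)))
    g <- array(runif(gh * gw), c(gh, gw, 1L, 1L))
    matrix(cpp_bilinear_fwd(g, H, W), H, W)
  }
  n <- 0.7 * octave(scale) + 0.3 * octave(scale / 3)
  (n - min(n)) / max(1e-12, diff(range(n)))
}

gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k1 <- dnorm(seq(-r, r), sd = sigma); k1 <- k1 / sum(k1)
  k <- outer(k1, k1)
  d <- dim(x)
  if (length(d) == 2L) d <- c(d, 1L)
  xin <- array(x, c(d[1], d[2], 1L, d[3]))  # channels as batch entries
  w <- array(k, c(2L * r + 1L, 2L * r + 1L, 1L, 1L))
  y <- cpp_conv2d_fwd(xin, w, NULL, 1L, r)
  array(y, dim(x))
}

# rasterize a rotated ellipse; returns an H x W logical matrix
ellipse_mask <- function(H, W, ch, cw, a, b, theta, inner = 0) {
  hh <- matrix(seq_len(H), H, W) - ch
  ww <- matrix(seq_len(W), H, W, byrow = TRUE) - cw
  u <- cos(theta) * hh + sin(theta) * ww
  v <- -sin(theta) * hh + cos(theta) * ww
  d2 <- (u / a)^2 + (v / b)^2
  if (inner > 0) d2 <= 1 & d2 >= inner^2 else d2 <= 1
}

#' Generate one synthetic image/mask pair
#'
#' @param spec a [scene_spec()].
#' @return a `segmentation_sample`: `image` (H, W, 3 in `[0,1]`), `mask`
#'   (H, W integer 0/1, exact, rendered before blurring), `seed`, `spec`.
#' @export
generate_sample <- function(spec) {
  with_seed(spec$seed, {
    H <- spec$size[1]; W <- spec$size[2]
    n <- if (spec$n_objects[1] == spec$n_objects[2]) spec$n_objects[1]
         else sample(spec$n_objects[1]:spec$n_objects[2], 1L)
    mask <- matrix(FALSE, H, W)
    placed <- 0L; tries <- 0L; restarts <- 0L
    obj_list <- list()
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 400L) {
        # a crowded draw can paint itself into a corner: restart the scene
        restarts <- restarts + 1L
        if (restarts > 25L)
          stop("generation error: could not place ", n, " objects inside the ",
               spec$margin, "-pixel margin without overlap")
        mask <- matrix(FALSE, H, W)
        placed <- 0L; tries <- 0L
        obj_list <- list()
      }
      a <- runif(1, spec$axis_range[1], spec$axis_range[2]) * H
      b <- runif(1, spec$axis_range[1], spec$axis_range[2]) * W
      r <- max(a, b)
      ch <- runif(1, spec$margin + r + 1, H - spec$margin - r)
      cw <- runif(1, spec$margin + r + 1, W - spec$margin - r)
      if (ch <= spec$margin + r || cw <= spec$margin + r) next
      theta <- runif(1, 0, pi)
      inner <- if (spec$object_kind == "ring") runif(1, 0.35, 0.55) else 0
      m <- ellipse_mask(H, W, ch, cw, a, b, theta, inner)
      # demand a 2-pixel moat so connected components match the object count
      moat <- ellipse_mask(H, W, ch, cw, a + 2, b + 2, theta, 0)
      if (any(moat & mask)) next
      mask <- mask | m
      placed <- placed + 1L
      obj_list[[placed]] <- list(m = m, intensity = runif(1, spec$intensity_range[1],
                                                          spec$intensity_range[2]))
    }
    # eosin-pink background with multiplicative texture
    bgtex <- 0.85 + 0.3 * (value_noise(H, W) - 0.5)
    img <- array(0, c(H, W, 3L))
    base <- c(0.91, 0.79, 0.88)
    for (c3 in 1:3) img[, , c3] <- base[c3] * bgtex
    # hematoxylin-purple objects, per-object intensity, own texture
    objtex <- 0.9 + 0.4 * (value_noise(H, W, scale = 6) - 0.5)
    tint <- c(0.48, 0.28, 0.62)
    soft <- array(0, c(H, W))
    color <- array(0, c(H, W, 3L))
    for (ob in obj_list) {
      soft <- pmax(soft, ob$m * 1)
      for (c3 in 1:3) color[, , c3] <- color[, , c3] +
        ob$m * (1 - ob$intensity * tint[c3] / max(tint)) * tint[c3] / 0.62
    }
    alpha <- gaussian_blur(soft, spec$boundary_blur)
    alpha <- pmin(pmax(alpha, 0), 1)
    colb <- gaussian_blur(color, spec$boundary_blur)
    for (c3 in 1:3)
      img[, , c3] <- img[, , c3] * (1 - alpha) + colb[, , c3] * objtex * alpha
    img <- img + array(rnorm(H * W * 3L, sd = spec$noise_sigma), c(H, W, 3L))
    img <- pmin(pmax(img, 0), 1)
    structure(list(image = img, mask = matrix(as.integer(mask), H, W),
                   seed = spec$seed, spec = spec),
              class = "segmentation_sample")
  })
}

#' Generate a dataset tree of synthetic samples
#'
#' Writes `images/` and `masks/` PNGs plus `train.txt` / `test.txt` split
#' lists (disjoint) and a `manifest.yaml`; filenames encode the per-sample
#' seed for provenance. Regeneration with the same spec reproduces identical
#' files.
#'
#' @param spec a [scene_spec()]; its `seed` acts as the master seed.
#' @param n_train,n_test split sizes.
#' @param out_dir output directory (created).
#' @return invisibly, the manifest list.
#' @export
generate_dataset <- function(spec, n_train, n_test, out_dir) {
  dir.create(file.path(out_dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  n <- n_train + n_test
  seeds <- spec$seed * 1000L + seq_len(n)
  split <- rep(c("train", "test"), c(n_train, n_test))
  files <- sprintf("%s_%04d_seed%d.png", split, seq_len(n), seeds)
  for (i in seq_len(n)) {
    sp <- spec; sp$seed <- seeds[i]
    smp <- generate_sample(sp)
    png::writePNG(smp$image, file.path(out_dir, "images", files[i]))
    png::writePNG(smp$mask + 0, file.path(out_dir, "masks", files[i]))
  }
  writeLines(files[split == "train"], file.path(out_dir, "train.txt"))
  writeLines(files[split == "test"], file.path(out_dir, "test.txt"))
  manifest <- list(generator = "dranet synthetic", spec = unclass(spec),
                   n_train = n_train, n_test = n_test, files = files)
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}
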