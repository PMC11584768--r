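# Dataset reading: image/mask directory trees with split lists, PNG or
# TIFF images, PNG masks. Images are resized bilinearly, masks with
# nearest-neighbor, and masks are strictly binarized on load.

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop("unsupported image format '", ext, "' for ", path,
         " (PNG and TIFF are supported)"))
  d <- dim(img)
  if (length(d) == 2L) img <- array(rep(img, 3L), c(d, 3L))   # grayscale
  if (d[length(d)] == 4L) img <- img[, , 1:3]                  # drop alpha
  img
}

nearest_resize <- function(m, Ho, Wo) {
  H <- nrow(m); W <- ncol(m)
  hi <- pmin(H, pmax(1L, floor((seq_len(Ho) - 0.5) * H / Ho) + 1L))
  wi <- pmin(W, pmax(1L, floor((seq_len(Wo) - 0.5) * W / Wo) + 1L))
  m[hi, wi, drop = FALSE]
}

bilinear_resize <- function(img, Ho, Wo) {
  d <- dim(img)
  x <- array(img, c(d[1], d[2], 1L, d[3]))   # channels ride the batch axis
  array(cpp_bilinear_fwd(x, as.integer(Ho), as.integer(Wo)), c(Ho, Wo, d[3]))
}

#' Load an image/mask dataset split
#'
#' Expects `root/images/`, `root/masks/` and a `root/<split>.txt` list of
#' file names. Pairs are resized to `input_size` (bilinear for images,
#' nearest-neighbor for masks) and masks binarized at 0.5. Ordering follows
#' the split list (deterministic).
#'
#' @param root dataset directory; @param split `"train"` or `"test"`;
#' @param input_size target square size (`NULL` keeps native size).
#' @return list of `segmentation_sample`s.
#' @export
load_dataset <- function(root, split = "train", input_size = NULL) {
  listfile <- file.path(root, paste0(split, ".txt"))
  if (!file.exists(listfile)) stop("missing split list ", listfile)
  files <- readLines(listfile)
  files <- files[nzchar(files)]
  lapply(files, function(f) {
    ip <- file.path(root, "images", f)
    mp <- file.path(root, "masks", f)
    if (!file.exists(ip)) stop("missing image file ", ip)
    if (!file.exists(mp))
      stop("image ", f, " has no matching mask at ", mp)
    img <- read_image(ip)
    msk <- png::readPNG(mp)
    if (length(dim(msk)) == 3L) msk <- msk[, , 1]
    if (!is.null(input_size)) {
      img <- bilinear_resize(img, input_size, input_size)
      msk <- nearest_resize(msk, input_size, input_size)
    }
    structure(list(image = img,
                   mask = matrix(as.integer(msk > 0.5), nrow(msk), ncol(msk)),
                   seed = NA_integer_, path = f),
              class = "segmentation_sample")
  })
}

# right-angle rotations / flips / contrast jitter; all draws come from the
# session RNG so a seeded training loop is reproducible
augment_sample <- function(img, msk, contrast = 0.2) {
  k <- sample(0:3, 1L)
  if (k > 0) for (i in seq_len(k)) {
    img <- aperm(img, c(2, 1, 3))[rev(seq_len(dim(img)[2])), , , drop = FALSE]
    msk <- t(msk)[rev(seq_len(ncol(msk))), , drop = FALSE]
  }
  if (runif(1) < 0.5) { img <- img[rev(seq_len(nrow(img))), , , drop = FALSE]
                        msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE] }
  if (runif(1) < 0.5) { img <- img[, rev(seq_len(ncol(img))), , drop = FALSE]
                        msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE] }
  if (contrast > 0) {
    f <- runif(1, 1 - contrast, 1 + contrast)
    mu <- mean(img)
    img <- pmin(pmax((img - mu) * f + mu, 0), 1)
  }
  list(image = img, mask = msk)
}

# stack samples into (H,W,3,N) image and (H,W,1,N) mask arrays
stack_batch <- function(samples) {
  H <- nrow(samples[[1]]$mask); W <- ncol(samples[[1]]$mask)
  N <- length(samples)
  x <- array(0, c(H, W, 3L, N)); y <- array(0, c(H, W, 1L, N))
  for (n in seq_len(N)) {
    x[, , , n] <- samples[[n]]$image
    y[, , 1L, n] <- samples[[n]]$mask
  }
  list(x = x, y = y)
}
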