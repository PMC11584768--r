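# Synthetic histology-style scene generator.

test_that("samples are binary-masked, aligned and deterministic", {
  spec <- scene_spec(size = c(64L, 64L), seed = 7L)
  s1 <- generate_sample(spec)
  expect_true(all(s1$mask %in% c(0L, 1L)))
  expect_identical(dim(s1$image), c(64L, 64L, 3L))
  expect_identical(dim(s1$mask), c(64L, 64L))
  expect_true(all(s1$image >= 0 & s1$image <= 1))
  # identical seed, identical bits
  s2 <- generate_sample(spec)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
  # different seed, different scene
  spec$seed <- 8L
  expect_false(identical(generate_sample(spec)$mask, s1$mask))
})

test_that("connected components in the mask equal the object count", {
  for (kind in c("blob", "ring")) {
    for (seed in 1:5) {
      n <- 3L
      spec <- scene_spec(size = c(72L, 72L), n_objects = c(n, n),
                         object_kind = kind, seed = seed)
      s <- generate_sample(spec)
      expect_equal(count_components(s$mask), n)
    }
  }
})

test_that("foreground fraction stays inside the generator's placement band", {
  fracs <- vapply(1:100, function(seed)
    mean(generate_sample(scene_spec(size = c(96L, 96L), seed = seed))$mask),
    numeric(1))
  expect_true(all(fracs > 0.05 & fracs < 0.60))
})

test_that("generate_dataset writes a reproducible, disjoint split tree", {
  root <- file.path(tempdir(), "synthtree")
  unlink(root, recursive = TRUE)
  spec <- scene_spec(size = c(48L, 48L), seed = 5L)
  generate_dataset(spec, n_train = 8L, n_test = 2L, out_dir = root)
  tr <- readLines(file.path(root, "train.txt"))
  te <- readLines(file.path(root, "test.txt"))
  expect_length(tr, 8L)
  expect_length(te, 2L)
  expect_length(intersect(tr, te), 0L)
  expect_length(list.files(file.path(root, "images")), 10L)
  expect_length(list.files(file.path(root, "masks")), 10L)
  sums1 <- tools::md5sum(list.files(file.path(root, "images"), full.names = TRUE))
  # regeneration reproduces identical files
  root2 <- file.path(tempdir(), "synthtree2")
  unlink(root2, recursive = TRUE)
  generate_dataset(spec, n_train = 8L, n_test = 2L, out_dir = root2)
  sums2 <- tools::md5sum(list.files(file.path(root2, "images"), full.names = TRUE))
  expect_identical(unname(sums1), unname(sums2))
  unlink(c(root, root2), recursive = TRUE)
})

test_that("presets encode the intended difficulty ordering for a small model", {
  # ring objects + strong blur and noise must segment worse than the easy
  # preset under an identical, deliberately short training budget
  tcfg <- train_config(epochs = 6L, input_size = 48L, seed = 9L,
                       val_fraction = 0)
  mcfg <- tiny_model_config(input_size = 48L)
  dice <- sapply(c("easy", "cocahis_like"), function(preset) {
    tr <- make_samples(12L, size = 48L, preset = preset, seed_base = 300L)
    te <- make_samples(6L, size = 48L, preset = preset, seed_base = 900L)
    r <- train(mcfg, tcfg, samples = tr, verbose = FALSE)
    evaluate(r$model, samples = te)$aggregate$dice
  })
  expect_gt(dice["easy"], dice["cocahis_like"])
})
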