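# data_pipeline: image IO, resizing, augmentation, standardisation

test_that("generated images and masks round-trip through the loaders", {
  man <- tiny_dataset()
  src <- manifest_domain(man, "source")
  ns <- asNamespace("adamnet")
  img <- load_image(ns$resolve_path(src, src$path[1]))
  expect_identical(dim(img), c(48L, 48L))
  expect_true(all(img >= 0 & img <= 1))
  msk <- load_mask(ns$resolve_path(src, src$mask_path[1]))
  expect_identical(dim(msk), c(48L, 48L))
  expect_true(all(msk %in% c(0, 1)))
  # target records carry no masks
  tgt <- manifest_domain(man, "target")
  expect_true(all(!nzchar(tgt$mask_path)))
  expect_true(all(nzchar(src$mask_path)))
})

test_that("resize_matrix: identity at native size, nearest keeps binarity", {
  ns <- asNamespace("adamnet")
  set.seed(50)
  img <- matrix(runif(30 * 20), 30, 20)
  expect_equal(ns$resize_matrix(img, 30L, 20L), img, tolerance = 1e-12)
  up <- ns$resize_matrix(img, 60L, 40L)
  expect_identical(dim(up), c(60L, 40L))
  expect_true(min(up) >= min(img) - 1e-12 && max(up) <= max(img) + 1e-12)
  mask <- matrix(rbinom(100, 1, 0.4), 10, 10)
  mn <- ns$resize_matrix(mask, 17L, 13L, "nearest")
  expect_true(all(mn %in% c(0, 1)))
})

test_that("augment is deterministic given a directive and seed", {
  set.seed(51)
  img <- matrix(runif(48 * 48), 48, 48)
  mask <- matrix(rbinom(48 * 48, 1, 0.3), 48, 48)
  dir <- paste0('{"flip":"horizontal","rotation":7.5,"crop":0.9,',
                '"noise_sd":0.01,"brightness":0.05}')
  a1 <- augment(img, mask, dir, rng_seed = 3L)
  a2 <- augment(img, mask, dir, rng_seed = 3L)
  expect_identical(a1$image, a2$image)
  expect_identical(a1$mask, a2$mask)
  expect_false(identical(a1$image, img))
  expect_identical(dim(a1$image), dim(img))
  expect_true(all(a1$mask %in% c(0, 1)))
  # empty directive is the identity
  a0 <- augment(img, mask, "", rng_seed = 3L)
  expect_identical(a0$image, img)
  expect_identical(a0$mask, mask)
})

test_that("preprocess standardises with fixed constants at any size", {
  img <- matrix(0.5, 48, 48)
  x <- preprocess(img, size = 64L)
  expect_identical(dim(x), c(64L, 64L, 3L))
  # fixed ImageNet constants: channel c gets (0.5 - mean_c) / sd_c
  means <- c(0.485, 0.456, 0.406)
  sds <- c(0.229, 0.224, 0.225)
  for (c in 1:3) {
    expect_equal(unique(as.vector(x[, , c])), (0.5 - means[c]) / sds[c],
                 tolerance = 1e-6)
  }
  # standardisation is affine: a global brightness offset survives it
  x2 <- preprocess(img + 0.1, size = 64L)
  expect_gt(min(x2 - x), 0)
})

test_that("stack_batch lays out (H, W, N, C)", {
  imgs <- lapply(1:3, function(i) array(i, c(8, 8, 3)))
  x <- adamnet:::stack_batch(imgs)
  expect_identical(dim(x), c(8L, 8L, 3L, 3L))
  for (i in 1:3) expect_true(all(x[, , i, ] == i))
})
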