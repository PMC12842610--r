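# data_pipeline: largest-remainder allocation, unit-stratified splitting,
# leakage guards, minority oversampling

ns <- asNamespace("adamnet")

make_manifest <- function(units, images_per_unit = 3L, grades = NULL) {
  n <- length(units) * images_per_unit
  df <- data.frame(
    path = sprintf("img%03d.png", seq_len(n)),
    mask_path = "",
    grade = if (is.null(grades)) rep_len(0:3, n) else rep(grades,
                                                          each = images_per_unit),
    unit_id = rep(units, each = images_per_unit),
    domain = "source",
    stringsAsFactors = FALSE
  )
  as_manifest(df, root = tempdir())
}

test_that("largest_remainder allocates exactly and matches 7:1:2 and 6:1:3", {
  expect_identical(ns$largest_remainder(10L, c(0.7, 0.1, 0.2)), c(7L, 1L, 2L))
  expect_identical(ns$largest_remainder(10L, c(0.6, 0.1, 0.3)), c(6L, 1L, 3L))
  # allocation property: sums to n for random ratio vectors
  set.seed(20)
  for (i in 1:50) {
    r <- runif(3); r <- r / sum(r)
    n <- sample(1:40, 1)
    a <- ns$largest_remainder(n, r)
    expect_identical(sum(a), as.integer(n))
    expect_true(all(abs(a - n * r) < 1))
  }
})

test_that("stratified_unit_split isolates units and hits the unit counts", {
  units <- sprintf("u%02d", 1:10)
  man <- make_manifest(units, grades = rep(1L, 10))  # one 10-unit stratum
  for (ratios in list(c(0.7, 0.1, 0.2), c(0.6, 0.1, 0.3))) {
    # single-stratum manifest: the empty-strata warning is expected here
    sp <- suppressWarnings(stratified_unit_split(man, split_spec(ratios,
                                                                 seed = 5L)))
    counts <- vapply(sp, function(m) length(unique(m$unit_id)), 0L)
    expect_identical(unname(counts), as.integer(10 * ratios))
    # unit isolation: every unit appears in exactly one role
    all_units <- lapply(sp, function(m) unique(m$unit_id))
    expect_identical(sort(unname(unlist(all_units))), sort(units))
    expect_identical(anyDuplicated(unlist(all_units)), 0L)
    # no image is lost or duplicated
    expect_identical(sort(unname(unlist(lapply(sp, function(m) m$path)))),
                     sort(man$path))
  }
})

test_that("splits are deterministic in the seed and stratified by grade", {
  man <- tiny_dataset()
  src <- manifest_domain(man, "source")
  s1 <- stratified_unit_split(src, split_spec(seed = 3L))
  s2 <- stratified_unit_split(src, split_spec(seed = 3L))
  s3 <- stratified_unit_split(src, split_spec(seed = 4L))
  expect_identical(s1$train$path, s2$train$path)
  expect_false(identical(s1$train$path, s3$train$path))
  expect_identical(attr(s1$train, "role"), "train")
  expect_identical(attr(s1$test, "role"), "test")
})

test_that("oversample_minority equalises counts {180,612,168,40} -> all 612", {
  counts <- c(180L, 612L, 168L, 40L)
  units <- unlist(lapply(0:3, function(g) {
    sprintf("g%d_u%02d", g, seq_len(counts[g + 1] %/% 4L))
  }))
  grades <- rep(0:3, counts %/% 4L)
  man <- make_manifest(units, images_per_unit = 4L, grades = grades)
  attr(man, "role") <- "train"
  expect_identical(as.integer(table(man$grade)), counts)
  over <- oversample_minority(man, seed = 9L)
  expect_identical(as.integer(table(over$grade)), rep(612L, 4))
  # originals are retained; extras are duplicates with augment directives
  expect_true(all(man$path %in% over$path))
  extras <- over[duplicated(over$path), , drop = FALSE]
  expect_true(all(nzchar(extras$augment)))
  expect_identical(nrow(extras), sum(612L - counts))
  # refuses to oversample evaluation manifests
  attr(man, "role") <- "test"
  expect_error(oversample_minority(man), "train")
})

test_that("the UDA guard strips target labels before training sees them", {
  man <- tiny_dataset()
  src <- manifest_domain(man, "source")
  tgt <- manifest_domain(man, "target")
  cfg <- train_config(source_manifest = src, target_manifest = tgt,
                      variant = "DANN", backbone = "tiny", epochs = 1L)
  fit_clean <- train(cfg, seed = 21L)
  # poison every target-domain grade; training must be bit-identical
  tgt_poison <- tgt
  tgt_poison$grade <- (tgt_poison$grade + 1L) %% 4L
  cfg2 <- train_config(source_manifest = src, target_manifest = tgt_poison,
                       variant = "DANN", backbone = "tiny", epochs = 1L)
  fit_poison <- train(cfg2, seed = 21L)
  expect_identical(fit_clean$log$Ltotal, fit_poison$log$Ltotal)
  expect_identical(
    lapply(fit_clean$model$params, function(p) p$value),
    lapply(fit_poison$model$params, function(p) p$value)
  )
})
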