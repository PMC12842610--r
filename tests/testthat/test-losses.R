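# losses_schedules: closed forms, invariances and input validation

test_that("grl_lambda matches its closed form and boundary values", {
  expect_identical(grl_lambda(0, 8), 0)
  expect_equal(grl_lambda(1, 8), 2 / (1 + exp(-8)) - 1, tolerance = 1e-12)
  p <- seq(0, 1, length.out = 101)
  for (g in c(4, 8, 14)) {
    expect_equal(grl_lambda(p, g), 2 / (1 + exp(-g * p)) - 1,
                 tolerance = 1e-12)
  }
})

test_that("grl_lambda is monotone, bounded in [0, 1) and validates input", {
  p <- seq(0, 1, length.out = 1000)
  for (g in c(4, 6, 8, 10, 12, 14)) {
    v <- grl_lambda(p, g)
    expect_true(all(diff(v) > 0))
    expect_true(all(v >= 0 & v < 1))
  }
  expect_error(grl_lambda(-0.1), "\\[0, 1\\]")
  expect_error(grl_lambda(1.1), "\\[0, 1\\]")
  expect_error(grl_lambda(0.5, gamma = 0), "positive")
  expect_error(grl_lambda(0.5, gamma = -1), "positive")
})

test_that("cls_loss: uniform logits give ln K, confident logits approach 0", {
  logits <- matrix(0, 4, 10)
  labels <- rep(0:3, length.out = 10)
  expect_equal(cls_loss(logits, labels), log(4), tolerance = 1e-12)
  # strongly correct logits
  strong <- matrix(-50, 4, 4)
  strong[cbind(1:4, 1:4)] <- 50
  expect_lt(cls_loss(strong, 0:3), 1e-6)
  # permutation invariance over samples
  set.seed(1)
  z <- matrix(rnorm(4 * 12), 4, 12)
  y <- sample(0:3, 12, replace = TRUE)
  perm <- sample(12)
  expect_equal(cls_loss(z, y), cls_loss(z[, perm], y[perm]))
  expect_error(cls_loss(z, c(y[-1], 4)), "labels")
})

test_that("seg_loss matches the spec's worked examples and conventions", {
  # single background pixel, uniform probabilities -> 0.4 * ln 2 / 0.4
  z1 <- array(0, c(1, 1, 1, 2))
  m1 <- array(0, c(1, 1, 1))
  expect_equal(seg_loss(z1, m1), log(2), tolerance = 1e-12)
  # one background + one foreground pixel, both uniform -> still ln 2
  z2 <- array(0, c(1, 2, 1, 2))
  m2 <- array(c(0, 1), c(1, 2, 1))
  expect_equal(seg_loss(z2, m2), log(2), tolerance = 1e-12)
  # scaling both class weights leaves the normalised loss unchanged
  set.seed(2)
  z <- array(rnorm(6 * 6 * 2 * 2), c(6, 6, 2, 2))
  m <- array(rbinom(72, 1, 0.4), c(6, 6, 2))
  expect_equal(seg_loss(z, m, omega = c(0.4, 1)),
               seg_loss(z, m, omega = 10 * c(0.4, 1)), tolerance = 1e-12)
  # with equal weights it reduces to the plain mean pixel cross-entropy
  p_gland <- 1 / (1 + exp(z[, , , 1] - z[, , , 2]))
  ce <- -mean(log(ifelse(m == 1, p_gland, 1 - p_gland)))
  expect_equal(seg_loss(z, m, omega = c(1, 1)), ce, tolerance = 1e-10)
  expect_error(seg_loss(z, m + 0.5), "binary")
})

test_that("cons_loss reproduces the worked example in both modes", {
  # two per-sample constant maps 0.2 and 0.6, delta = 0.4 -> 0.04
  a <- array(c(rep(0.2, 16), rep(0.6, 16)), c(4, 4, 2))
  expect_equal(cons_loss(a, delta = 0.4), 0.04, tolerance = 1e-12)
  expect_equal(cons_loss(a, delta = 0.4, mode = "spatial_mean"), 0.04,
               tolerance = 1e-12)
  # a map equal to delta everywhere is a zero of the loss
  expect_equal(cons_loss(array(0.5, c(3, 3, 2)), delta = 0.5), 0)
  # pixel mode upper-bounds spatial_mean mode (Jensen)
  set.seed(3)
  b <- array(runif(4 * 4 * 3), c(4, 4, 3))
  expect_gte(cons_loss(b, 0.5), cons_loss(b, 0.5, mode = "spatial_mean"))
  expect_error(cons_loss(a, delta = 0), "\\(0, 1\\)")
  expect_error(cons_loss(a, delta = 1), "\\(0, 1\\)")
})

test_that("dom_loss gives ln 2 at p = 0.5 and validates the batch", {
  logits <- matrix(0, 2, 8)
  domains <- rep(c(0L, 1L), 4)
  expect_equal(dom_loss(logits, domains), log(2), tolerance = 1e-12)
  expect_error(dom_loss(logits, rep(2L, 8)), "0 or 1")
  expect_warning(dom_loss(logits, rep(0L, 8)), "single-domain")
})

test_that("uncertainty_weight closed forms and minimiser", {
  expect_equal(uncertainty_weight(1, 0), 0.5, tolerance = 1e-12)
  expect_equal(uncertainty_weight(2, log(2)), 0.5 + log(2), tolerance = 1e-12)
  # w(s) = exp(-s) L / 2 + s, so for fixed L the minimiser is s = ln(L / 2)
  L <- 2.7
  s_grid <- seq(-3, 3, by = 0.01)
  vals <- vapply(s_grid, function(s) uncertainty_weight(L, s), 0)
  expect_equal(s_grid[which.min(vals)], log(L / 2), tolerance = 0.01)
  expect_error(uncertainty_weight(Inf, 0), "finite")
})

test_that("total_loss reproduces the worked composition 1.55", {
  b <- total_loss(l_cls = 1, l_seg = 2, l_dom = 0, l_cons = 0.5,
                  s_cls = 0, s_seg = 0, lambda = 0, mu = 0.1)
  expect_s3_class(b, "loss_bundle")
  expect_equal(b$total, 1.55, tolerance = 1e-12)
  expect_equal(b$alpha, 0.5)
  expect_equal(b$beta, 0.5)
  # the domain term enters the total with weight one; the adversarial
  # -lambda scaling lives only inside the GRL
  b2 <- total_loss(1, 2, 0.3, 0.5, lambda = 0.7, mu = 0.1)
  expect_equal(b2$total, b$total + 0.3, tolerance = 1e-12)
  expect_error(total_loss(NaN, 1, 1, 1), "l_cls")
})
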