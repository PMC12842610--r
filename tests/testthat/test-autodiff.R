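# model_core/losses: reverse-mode gradients against central differences,
# and the gradient-reversal contract

ns <- asNamespace("adamnet")

# builds a scalar-valued graph from an input array and returns the autodiff
# gradient next to the numerical one; ops with single-precision forward
# kernels (conv, convT) need a larger step so the finite difference clears
# the float32 rounding noise, and a tolerance to match
check_grad <- function(make_scalar, x, tol = 1e-4, eps = 1e-5) {
  tape <- ns$tape_new()
  xin <- ns$av_input(tape, x)
  loss <- make_scalar(tape, xin)
  ns$tape_backward(tape, loss)
  g_num <- num_grad(function(v) {
    tp <- ns$tape_new()
    make_scalar(tp, ns$av_input(tp, v))$value
  }, x, eps = eps)
  expect_lt(rel_err(as.numeric(xin$grad), as.numeric(g_num)), tol)
}

sum_node <- function(tape, x) {
  # reduce any tensor node to a scalar via a weighted sum with fixed weights
  d <- if (is.null(dim(x$value))) length(x$value) else dim(x$value)
  w <- array(seq_len(prod(d)) / prod(d), d)
  ns$new_node(tape, sum(x$value * w), list(x),
              function(nd, g) ns$accum_grad(x, g * w))
}

test_that("convolution and pooling gradients match central differences", {
  set.seed(10)
  x <- array(rnorm(6 * 6 * 2 * 3), c(6, 6, 2, 3))
  p <- ns$layer_conv("t.conv", 3L, 3L, 4L, group = "f")
  check_grad(function(tp, xin) {
    sum_node(tp, ns$av_conv2d(tp, xin, p, stride = 1L, pad = 1L))
  }, x, tol = 5e-3, eps = 1e-3)
  check_grad(function(tp, xin) sum_node(tp, ns$av_maxpool(tp, xin)), x)
  pt <- ns$layer_convT("t.convT", 2L, 3L, 2L, group = "seg")
  check_grad(function(tp, xin) {
    sum_node(tp, ns$av_convT2d(tp, xin, pt, stride = 2L))
  }, x, tol = 5e-3, eps = 1e-3)
})

test_that("attention and shape op gradients match central differences", {
  set.seed(11)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  check_grad(function(tp, xin) sum_node(tp, ns$av_relu(tp, xin)), x)
  check_grad(function(tp, xin) sum_node(tp, ns$av_sigmoid(tp, xin)), x)
  check_grad(function(tp, xin) sum_node(tp, ns$av_channel_pool(tp, xin)), x)
  check_grad(function(tp, xin) {
    pools <- ns$av_gap_gmp(tp, xin)
    ns$av_add(tp, sum_node(tp, pools$avg), sum_node(tp, pools$max))
  }, x)
  check_grad(function(tp, xin) sum_node(tp, ns$av_flatten(tp, xin)), x)
  check_grad(function(tp, xin) {
    sum_node(tp, ns$av_slice_n(tp, xin, 2L))
  }, x)
  check_grad(function(tp, xin) {
    sum_node(tp, ns$av_resize_bilinear(tp, xin, 7L, 5L))
  }, x)
  check_grad(function(tp, xin) {
    sum_node(tp, ns$av_resize_bilinear(tp, xin, 2L, 3L))
  }, x)
  # scale ops: gradient w.r.t. both factors via a shared input
  check_grad(function(tp, xin) {
    a <- ns$av_gap_gmp(tp, xin)$avg
    sum_node(tp, ns$av_scale_channels(tp, xin, a))
  }, x)
  check_grad(function(tp, xin) {
    pooled <- ns$av_channel_pool(tp, xin)
    sum_node(tp, ns$av_concat_c(tp, pooled, pooled))
  }, x)
  check_grad(function(tp, xin) {
    a <- ns$av_sigmoid(tp, sum_node(tp, xin))
    nsfx <- ns$new_node(tp, array(a$value, c(4, 4, 2, 1)), list(a),
                        function(nd, g) ns$accum_grad(a, sum(g)))
    sum_node(tp, ns$av_scale_spatial(tp, xin, nsfx))
  }, x)
  check_grad(function(tp, xin) {
    sum_node(tp, ns$av_add_relu(tp, xin, ns$av_sigmoid(tp, xin)))
  }, x, tol = 1e-3)
})

test_that("batch norm and loss-node gradients match central differences", {
  set.seed(12)
  x <- array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2))
  bn <- ns$layer_bn("t.bn", 2L, group = "f")
  check_grad(function(tp, xin) {
    sum_node(tp, bn$forward(tp, xin, training = TRUE))
  }, x, tol = 5e-3)
  labels <- c(0L, 2L, 1L)
  z <- matrix(rnorm(12), 4, 3)
  check_grad(function(tp, xin) ns$av_softmax_ce(tp, xin, labels), z)
  mask <- array(rbinom(4 * 4 * 3, 1, 0.5), c(4, 4, 3))
  check_grad(function(tp, xin) {
    ns$av_weighted_seg_ce(tp, xin, mask, c(0.4, 1))
  }, array(rnorm(4 * 4 * 3 * 2), c(4, 4, 3, 2)))
  check_grad(function(tp, xin) ns$av_mse_const(tp, xin, 0.5),
             array(runif(8), c(2, 2, 2)))
})

test_that("GRL is identity forward and scales gradients by -lambda", {
  set.seed(13)
  x <- array(rnorm(3 * 3 * 2 * 2), c(3, 3, 2, 2))
  for (lambda in c(0, 0.3, 1.0)) {
    tape <- ns$tape_new()
    xin <- ns$av_input(tape, x)
    out <- ns$av_grl(tape, xin, lambda)
    expect_identical(out$value, x)            # exact identity forward
    loss <- sum_node(tape, out)
    ns$tape_backward(tape, loss)
    # analytic gradient of the probe without the GRL
    tape2 <- ns$tape_new()
    xin2 <- ns$av_input(tape2, x)
    ns$tape_backward(tape2, sum_node(tape2, xin2))
    if (lambda == 0) {
      expect_true(all(xin$grad == 0))
    } else {
      expect_lt(rel_err(as.numeric(xin$grad),
                        as.numeric(-lambda * xin2$grad)), 1e-12)
    }
  }
  expect_error(ns$av_grl(ns$tape_new(), ns$av_input(ns$tape_new(), 1), -0.1),
               "non-negative")
})

test_that("uncertainty-weight node trains s towards log(L)", {
  tape <- ns$tape_new()
  L <- ns$av_input(tape, 2)
  s <- ns$new_param("t.s", 1L, "loss", init = "zeros")
  out <- ns$av_uncertainty_weight(tape, L, s)
  expect_equal(out$value, uncertainty_weight(2, 0))
  ns$tape_backward(tape, out)
  # d/ds [exp(-s)/2 L + s] at s=0, L=2 is 1 - 1 = 0 ... use s=1 instead
  s2 <- ns$new_param("t.s2", 1L, "loss", init = "ones")
  tape2 <- ns$tape_new()
  out2 <- ns$av_uncertainty_weight(tape2, ns$av_input(tape2, 2), s2)
  ns$tape_backward(tape2, out2)
  expect_equal(as.numeric(s2$grad), 1 - exp(-1) / 2 * 2, tolerance = 1e-12)
})
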