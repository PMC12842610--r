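# model_core: architecture conformance, variant ladder, parameter groups,
# forward-pass shapes and checkpoint round-trips (tiny backbone for speed)

test_that("tiny backbone honours the scaled resnet18 topology", {
  set.seed(40)
  model <- build_model(model_config(backbone = "tiny"))
  info <- inspect_model(model)
  expect_identical(info$backbone, "tiny")
  expect_identical(info$input_size, 64L)
  expect_identical(info$feature_shape, c(128L, 2L, 2L))
  expect_identical(info$decoder_blocks, 4L)
  expect_identical(info$decoder_out_channels, c(64L, 32L, 16L, 16L))
  expect_identical(info$k_seg, 2L)
  expect_identical(info$seg_resolution, 64L)
  expect_true(info$has_sgsa)
  expect_true(info$has_cbam)
  expect_true(info$has_domain_head)
  expect_identical(info$head_cls$widths, c(512L, 512L, 256L, 4L))
  expect_identical(info$head_dom$widths, c(512L, 512L, 256L, 2L))
  expect_equal(info$head_cls$dropout_p, 0.35)
  expect_identical(info$head_cls$dropout_between_fc, c(1L, 2L))
})

test_that("forward pass produces the contracted shapes and ranges", {
  set.seed(41)
  model <- build_model(model_config(backbone = "tiny"))
  x <- array(runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  out <- model_forward(model, x, training = FALSE, lambda = 0.5)
  expect_identical(dim(out$f$value), c(2L, 2L, 3L, 128L))
  expect_identical(dim(out$seg_logits$value), c(64L, 64L, 3L, 2L))
  expect_identical(dim(out$attention$value), c(64L, 64L, 3L, 1L))
  expect_true(all(out$attention$value >= 0 & out$attention$value <= 1))
  expect_identical(dim(out$cls_logits$value), c(4L, 3L))
  expect_identical(dim(out$dom_logits$value), c(2L, 3L))
  expect_error(model_forward(model, array(0, c(32, 32, 1, 3))), "expected")
})

test_that("the variant ladder toggles exactly the advertised components", {
  set.seed(42)
  caps <- list(
    "Baseline" = c(dom = FALSE, seg = FALSE, cbam = FALSE, sgsa = FALSE),
    "DANN" = c(dom = TRUE, seg = FALSE, cbam = FALSE, sgsa = FALSE),
    "DANN-Head" = c(dom = TRUE, seg = FALSE, cbam = FALSE, sgsa = FALSE),
    "DANN-Head+Seg" = c(dom = TRUE, seg = TRUE, cbam = FALSE, sgsa = FALSE),
    "DANN-Head+Seg+CBAM" = c(dom = TRUE, seg = TRUE, cbam = TRUE,
                             sgsa = FALSE),
    "ADAM-Net" = c(dom = TRUE, seg = TRUE, cbam = TRUE, sgsa = TRUE)
  )
  for (v in names(caps)) {
    m <- build_variant(v, model_config(backbone = "tiny"))
    info <- inspect_model(m)
    expect_identical(info$has_domain_head, unname(caps[[v]]["dom"]),
                     info = v)
    expect_identical(info$decoder_blocks > 0L, unname(caps[[v]]["seg"]),
                     info = v)
    expect_identical(info$has_cbam, unname(caps[[v]]["cbam"]), info = v)
    expect_identical(info$has_sgsa, unname(caps[[v]]["sgsa"]), info = v)
  }
  # Baseline and plain DANN keep the original shallow heads; the widened
  # stack arrives with the "-Head" variants
  b <- build_variant("Baseline", model_config(backbone = "tiny"))
  expect_identical(inspect_model(b)$head_cls$widths, c(512L, 128L, 4L))
  d_plain <- inspect_model(build_variant("DANN", model_config(backbone = "tiny")))
  d_head <- inspect_model(build_variant("DANN-Head",
                                        model_config(backbone = "tiny")))
  expect_lt(length(d_plain$head_dom$widths) +
              sum(d_plain$head_dom$widths),
            length(d_head$head_dom$widths) + sum(d_head$head_dom$widths))
  expect_error(build_variant("NoSuch", model_config(backbone = "tiny")),
               "variant")
})

test_that("param_groups partition the parameter set exactly", {
  set.seed(43)
  model <- build_model(model_config(backbone = "tiny"))
  gr <- param_groups(model)
  expect_identical(sort(names(gr)), sort(c("f", "seg", "cls", "dom", "loss")))
  all_names <- unlist(lapply(gr, function(g) {
    vapply(g, function(p) p$name, "")
  }))
  model_names <- vapply(model$params, function(p) p$name, "")
  expect_identical(sort(unname(all_names)), sort(unname(model_names)))
  expect_identical(anyDuplicated(all_names), 0L)
  # group membership follows the module: decoder params in seg, heads in
  # cls/dom, encoder+attention in f, log-variances in loss
  expect_true(all(grepl("^dec\\.", vapply(gr$seg, function(p) p$name, ""))))
  expect_true(all(grepl("^cls\\.", vapply(gr$cls, function(p) p$name, ""))))
  expect_true(all(grepl("^dom\\.", vapply(gr$dom, function(p) p$name, ""))))
  expect_identical(length(gr$loss), 2L)
})

test_that("dropout is active only in training mode", {
  set.seed(44)
  model <- build_model(model_config(backbone = "tiny"))
  x <- array(runif(64 * 64 * 3), c(64, 64, 1, 3))
  e1 <- model_forward(model, x, training = FALSE)$cls_logits$value
  e2 <- model_forward(model, x, training = FALSE)$cls_logits$value
  expect_identical(e1, e2)                        # eval mode is deterministic
  set.seed(1); t1 <- model_forward(model, x, training = TRUE)$cls_logits$value
  set.seed(2); t2 <- model_forward(model, x, training = TRUE)$cls_logits$value
  expect_false(identical(t1, t2))                 # dropout masks differ
})

test_that("checkpoints restore an identical evaluation state", {
  fit <- tiny_fit()
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  restored <- load_checkpoint(path)
  man <- fit$splits$source$test
  r1 <- evaluate(fit$model, man)
  r2 <- evaluate(restored, man)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$dice, r2$dice)
  # logits agree bit-for-bit on a fixed input
  x <- array(runif(64 * 64 * 3), c(64, 64, 1, 3))
  expect_identical(model_forward(fit$model, x)$cls_logits$value,
                   model_forward(restored, x)$cls_logits$value)
})

test_that("pretrained = TRUE demands a weights file", {
  expect_error(build_model(model_config(backbone = "tiny", pretrained = TRUE)),
               "weights_file")
})
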