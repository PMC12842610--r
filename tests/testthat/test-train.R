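# training_engine: schedule wiring, determinism, logging, artefacts

test_that("training logs carry the full loss bundle and the GRL schedule", {
  fit <- tiny_fit()
  log <- fit$log
  expect_true(all(c("iter", "Lcls", "Lseg", "Ldom", "Lcons", "lambda",
                    "s_cls", "s_seg", "Ltotal") %in% names(log)))
  expect_true(all(is.finite(log$Ltotal)))
  expect_true(all(is.finite(log$Lcls)))
  # lambda follows grl_lambda over normalised progress: 0 at the first
  # iteration, non-decreasing, < 1
  expect_identical(log$lambda[1], 0)
  expect_true(all(diff(log$lambda) >= 0))
  expect_true(all(log$lambda < 1))
  n <- nrow(log)
  p <- (seq_len(n) - 1) / (n - 1)
  expect_equal(log$lambda, grl_lambda(p, 8), tolerance = 1e-12)
  expect_identical(length(fit$val_accuracy), 2L)
  expect_true(fit$best_val_accuracy >= 0 && fit$best_val_accuracy <= 1)
})

test_that("training is deterministic given the seed", {
  man <- tiny_dataset()
  cfg <- train_config(source_manifest = manifest_domain(man, "source"),
                      variant = "Baseline", backbone = "tiny", epochs = 1L)
  f1 <- train(cfg, seed = 33L)
  f2 <- train(cfg, seed = 33L)
  f3 <- train(cfg, seed = 34L)
  expect_identical(f1$log$Ltotal, f2$log$Ltotal)
  expect_identical(
    lapply(f1$model$params, function(p) p$value),
    lapply(f2$model$params, function(p) p$value)
  )
  expect_false(identical(f1$log$Ltotal, f3$log$Ltotal))
})

test_that("Baseline ignores the target manifest; DANN requires one", {
  man <- tiny_dataset()
  src <- manifest_domain(man, "source")
  cfg <- train_config(source_manifest = src, variant = "Baseline",
                      backbone = "tiny", epochs = 1L)
  fit <- train(cfg, seed = 1L)
  expect_null(fit$splits$target)
  expect_true(all(is.na(fit$log$Ldom)))
  cfg2 <- train_config(source_manifest = src, variant = "DANN",
                       backbone = "tiny", epochs = 1L)
  expect_error(train(cfg2, seed = 1L), "target manifest")
})

test_that("out_dir receives a checkpoint and a training log", {
  man <- tiny_dataset()
  out <- file.path(tempdir(), "adamnet-test-out")
  cfg <- train_config(source_manifest = manifest_domain(man, "source"),
                      target_manifest = manifest_domain(man, "target"),
                      variant = "ADAM-Net", backbone = "tiny", epochs = 1L,
                      out_dir = out)
  fit <- train(cfg, seed = 2L)
  expect_true(file.exists(fit$checkpoint))
  logs <- list.files(out, pattern = "\\.csv$", full.names = TRUE)
  expect_gte(length(logs), 1L)
  restored <- load_checkpoint(fit$checkpoint)
  expect_identical(inspect_model(restored), inspect_model(fit$model))
})

test_that("the uncertainty log-variances are trained", {
  fit <- tiny_fit()
  log <- fit$log
  # s parameters start at 0 and must have moved by the end of training
  expect_false(isTRUE(all.equal(log$s_cls[nrow(log)], 0)))
  expect_false(isTRUE(all.equal(log$s_seg[nrow(log)], 0)))
})

test_that("multi_seed_run aggregates mean and sd over seeds", {
  man <- tiny_dataset()
  cfg <- train_config(source_manifest = manifest_domain(man, "source"),
                      variant = "Baseline", backbone = "tiny", epochs = 1L,
                      seeds = c(5L, 6L))
  res <- multi_seed_run(cfg)
  expect_identical(length(res$per_seed), 2L)
  for (metric in c("accuracy", "precision", "recall", "f1", "mcc")) {
    expect_true(is.finite(res$source$mean[[metric]]))
    expect_true(is.finite(res$source$sd[[metric]]))
  }
  accs <- vapply(res$per_seed, function(r) r$source$accuracy, 0)
  expect_equal(unname(res$source$mean["accuracy"]), mean(accs),
               tolerance = 1e-12)
  expect_equal(unname(res$source$sd["accuracy"]), stats::sd(accs),
               tolerance = 1e-12)
  expect_null(res$target)   # no target domain for the Baseline variant
  expect_error(multi_seed_run(train_config(
    source_manifest = manifest_domain(man, "source"), variant = "Baseline",
    backbone = "tiny", epochs = 1L, seeds = 1L)), "seed")
})
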