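# explainability: Grad-CAM maps and t-SNE feature embeddings

test_that("gradcam returns a normalised map at input resolution", {
  fit <- tiny_fit()
  man <- fit$splits$source$test
  ns <- asNamespace("adamnet")
  img <- load_image(ns$resolve_path(man, man$path[1]))
  cam <- gradcam(fit$model, img)
  expect_identical(dim(cam$cam), c(64L, 64L))
  expect_true(all(cam$cam >= 0 & cam$cam <= 1))
  expect_identical(length(cam$logits), 4L)
  expect_identical(cam$class, which.max(cam$logits) - 1L)
  # an explicit class overrides the argmax
  cam2 <- gradcam(fit$model, img, class = 2L)
  expect_identical(cam2$class, 2L)
  expect_identical(cam2$logits, cam$logits)
})

test_that("embed_tsne separates well-separated clusters", {
  set.seed(60)
  a <- matrix(rnorm(30 * 5), 30, 5)
  b <- matrix(rnorm(30 * 5, mean = 25), 30, 5)
  y <- embed_tsne(rbind(a, b), perplexity = 8, n_iter = 1000L, seed = 2L)
  expect_identical(dim(y), c(60L, 2L))
  # every point ends nearer its own cluster centroid than the other one
  ca <- colMeans(y[1:30, ]); cb <- colMeans(y[31:60, ])
  d2a <- rowSums(sweep(y, 2, ca)^2)
  d2b <- rowSums(sweep(y, 2, cb)^2)
  expect_true(all(d2a[1:30] < d2b[1:30]))
  expect_true(all(d2b[31:60] < d2a[31:60]))
  # deterministic in the seed
  y2 <- embed_tsne(rbind(a, b), perplexity = 8, n_iter = 1000L, seed = 2L)
  expect_identical(y, y2)
  expect_error(embed_tsne(a, perplexity = 30), "perplexity")
})

test_that("embed_features labels rows with domain and grade", {
  fit <- tiny_fit()
  mans <- list(source = fit$splits$source$test,
               target = fit$splits$target$test)
  n <- nrow(mans$source) + nrow(mans$target)
  emb <- embed_features(fit$model, mans, perplexity = floor((n - 1) / 3),
                        n_iter = 50L)
  expect_identical(nrow(emb), n)
  expect_identical(sort(unique(emb$domain)), c("source", "target"))
  expect_true(all(emb$grade[emb$domain == "source"] %in% 0:3))
})
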