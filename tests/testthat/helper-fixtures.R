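# Shared fixtures, memoised so expensive artefacts are built once per session.

# small two-domain phantom dataset used by pipeline / training / eval tests
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "adamnet-test-data")
    if (!file.exists(file.path(dir, "manifest.csv"))) {
      # enough units per grade stratum that the 10% validation share is
      # non-empty after largest-remainder rounding
      cfg <- list(
        image_size = c(48L, 48L), n_glands = 8L, stripe_width_px = 3L,
        domains = list(
          source = list(n = 96L, n_units = 48L, grade_probs = rep(0.25, 4)),
          target = list(n = 32L, n_units = 16L, grade_probs = rep(0.25, 4),
                        shift = domain_shift_spec(brightness_offset = 0.1,
                                                  contrast_gain = 1.3,
                                                  gamma = 0.8))
        )
      )
      generate_dataset(cfg, dir, seed = 99L)
    }
    cache <<- read_manifest(file.path(dir, "manifest.csv"))
    cache
  }
})

manifest_domain <- function(man, dom) {
  out <- man[man$domain == dom, , drop = FALSE]
  attr(out, "root") <- attr(man, "root")
  class(out) <- class(man)
  out
}

# small trained ADAM-Net (tiny backbone, 2 epochs) shared by eval/checkpoint
# and explainability tests
tiny_fit <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    man <- tiny_dataset()
    cfg <- train_config(
      source_manifest = manifest_domain(man, "source"),
      target_manifest = manifest_domain(man, "target"),
      variant = "ADAM-Net", backbone = "tiny", epochs = 2L)
    cache <<- train(cfg, seed = 11L)
    cache
  }
})

# central-difference numerical gradient of f at x (arrays or vectors)
num_grad <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# the criterion-7/8 benchmark is run once and shared by both acceptance blocks
acceptance_benchmark <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    t0 <- proc.time()
    bench <- uda_benchmark(
      data_dir = file.path(tempdir(), "adamnet-acceptance-bench"))
    cache <<- list(bench = bench,
                   elapsed = unname((proc.time() - t0)["elapsed"]))
    cache
  }
})
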