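# Leakage-free dataset splitting.
#
# Isolation is enforced at the anatomical-unit level: all images of one
# patient eyelid land in exactly one of train/val/test.  Stratification is
# by grade at the unit level (a unit's modal grade defines its stratum),
# with largest-remainder rounding of the per-stratum counts.

# deterministic largest-remainder apportionment of n into length(ratios) bins
largest_remainder <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(exact - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Split specification
#'
#' @param ratios train/val/test proportions, non-negative, summing to 1.
#' @param seed integer seed controlling the unit shuffle.
#' @return a `split_spec` list.
#' @export
split_spec <- function(ratios = c(0.7, 0.1, 0.2), seed = 1L) {
  if (length(ratios) != 3L || any(ratios < 0)) {
    stop("ratios must be three non-negative numbers", call. = FALSE)
  }
  if (abs(sum(ratios) - 1) > 1e-9) stop("ratios must sum to 1", call. = FALSE)
  structure(list(ratios = ratios, seed = as.integer(seed)),
            class = "split_spec")
}

modal_grade <- function(grades) {
  tab <- table(grades)
  as.integer(names(tab)[which.max(tab)])   # ties resolve to the lower grade
}

#' Stratified unit-level split
#'
#' Splits a manifest into train/val/test so that (a) no `unit_id` appears in
#' more than one subset, (b) within each grade stratum the unit counts follow
#' the requested ratios up to largest-remainder rounding, and (c) the result
#' is deterministic given the seed.
#'
#' @param manifest an `adamnet_manifest`.
#' @param spec a [split_spec()].
#' @param stratify stratify by grade (default). With `stratify = FALSE` all
#'   units form a single stratum and the `grade` column is never read --
#'   required for target-domain splits, whose partition must not depend on
#'   labels that an unsupervised method is not allowed to see.
#' @return named list of three manifests (`train`, `val`, `test`), each
#'   tagged with a `role` attribute.
#' @export
stratified_unit_split <- function(manifest, spec = split_spec(),
                                  stratify = TRUE) {
  stopifnot(inherits(spec, "split_spec"))
  units <- unique(manifest$unit_id)
  if (stratify) {
    ug <- vapply(units, function(u) {
      modal_grade(manifest$grade[manifest$unit_id == u])
    }, 0L)
    missing_grades <- setdiff(0:3, unique(ug))
    if (length(missing_grades)) {
      warning("grade(s) with zero units: ",
              paste(missing_grades, collapse = ", "),
              "; their strata are empty")
    }
  } else {
    ug <- rep(0L, length(units))
  }
  assign <- character(0)
  names(assign) <- character(0)
  withr::with_seed(spec$seed, {
    for (g in sort(unique(ug))) {
      us <- sample(units[ug == g])
      counts <- largest_remainder(length(us), spec$ratios)
      lab <- rep(c("train", "val", "test"), counts)
      assign[us] <- lab
    }
  })
  out <- lapply(c(train = "train", val = "val", test = "test"), function(role) {
    m <- manifest[manifest$unit_id %in% names(assign)[assign == role], ,
                  drop = FALSE]
    attr(m, "root") <- manifest_root(manifest)
    attr(m, "role") <- role
    class(m) <- class(manifest)
    m
  })
  out
}

# random augmentation directive drawing from the five training-time
# operations (flip, rotation, crop, Gaussian noise, brightness)
random_directive <- function(max_rotation = 15, min_crop = 0.85,
                             max_brightness = 0.2, max_noise_sd = 0.05) {
  d <- list()
  if (stats::runif(1) < 0.5) d$flip <- sample(c("horizontal", "vertical"), 1)
  if (stats::runif(1) < 0.5) d$rotation <- stats::runif(1, -max_rotation, max_rotation)
  if (stats::runif(1) < 0.5) d$crop <- stats::runif(1, min_crop, 1)
  if (stats::runif(1) < 0.5) d$noise_sd <- stats::runif(1, 0, max_noise_sd)
  if (stats::runif(1) < 0.5) d$brightness <- stats::runif(1, -max_brightness, max_brightness)
  d
}

#' Oversample minority grades of a training manifest
#'
#' Duplicates minority-grade records (sampling with replacement) until every
#' grade reaches the majority-grade record count; each duplicate carries a
#' randomized augmentation directive (JSON in the `augment` column) applied
#' when the record is loaded.  Original records are left unchanged.  Refused
#' on validation/test manifests to prevent augmentation leakage.
#'
#' @param manifest a training manifest (from [stratified_unit_split()]).
#' @param seed integer seed for sampling and directive draws.
#' @return the augmented manifest.
#' @export
oversample_minority <- function(manifest, seed = 1L) {
  role <- attr(manifest, "role")
  if (!is.null(role) && role != "train") {
    stop("oversample_minority must only be applied to a training manifest ",
         "(got role '", role, "')", call. = FALSE)
  }
  counts <- table(factor(manifest$grade, levels = 0:3))
  target <- max(counts)
  extras <- list()
  withr::with_seed(seed, {
    for (g in 0:3) {
      n_have <- counts[[as.character(g)]]
      n_need <- target - n_have
      if (n_need <= 0 || n_have == 0) next
      pick <- sample(which(manifest$grade == g), n_need, replace = TRUE)
      add <- as.data.frame(manifest)[pick, , drop = FALSE]
      add$augment <- vapply(seq_len(nrow(add)), function(i) {
        as.character(jsonlite::toJSON(random_directive(), auto_unbox = TRUE,
                                      digits = NA))
      }, "")
      extras[[length(extras) + 1L]] <- add
    }
  })
  out <- rbind(as.data.frame(manifest), do.call(rbind, extras))
  rownames(out) <- NULL
  attr(out, "root") <- manifest_root(manifest)
  attr(out, "role") <- role
  class(out) <- class(manifest)
  out
}
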