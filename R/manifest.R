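# Dataset manifests: the on-disk catalog of samples.
#
# CSV dialect: header `path,mask_path,grade,unit_id,domain` (optionally an
# `augment` column holding JSON augmentation directives for oversampled
# records); `mask_path` may be empty (target-domain records carry no
# segmentation labels).  Paths are stored relative to the manifest file.

#' Read a dataset manifest
#'
#' @param path CSV file with columns `path,mask_path,grade,unit_id,domain`.
#' @return a `adamnet_manifest` data frame; image paths are resolved
#'   against the manifest's directory (kept in the `root` attribute).
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  df$grade <- as.integer(df$grade)
  as_manifest(df, root = dirname(normalizePath(path)))
}

#' @rdname read_manifest
#' @param df data frame with the manifest columns.
#' @param root directory that relative paths are resolved against.
#' @export
as_manifest <- function(df, root = ".") {
  need <- c("path", "mask_path", "grade", "unit_id", "domain")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(df$grade %in% 0:3)) stop("grades must lie in 0..3", call. = FALSE)
  if (!all(df$domain %in% c("source", "target"))) {
    stop("domain must be 'source' or 'target'", call. = FALSE)
  }
  if (any(!nzchar(df$unit_id))) stop("unit_id must be non-empty", call. = FALSE)
  if (is.null(df$augment)) df$augment <- ""
  df$mask_path[is.na(df$mask_path)] <- ""
  attr(df, "root") <- root
  class(df) <- c("adamnet_manifest", "data.frame")
  df
}

#' @rdname read_manifest
#' @param manifest a manifest to write.
#' @export
write_manifest <- function(manifest, path) {
  cols <- c("path", "mask_path", "grade", "unit_id", "domain")
  if (any(nzchar(manifest$augment))) cols <- c(cols, "augment")
  utils::write.csv(as.data.frame(manifest)[cols], path, row.names = FALSE,
                   quote = which(cols == "augment"))
  invisible(path)
}

manifest_root <- function(manifest) {
  r <- attr(manifest, "root")
  if (is.null(r)) "." else r
}

resolve_path <- function(manifest, p) {
  ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(manifest_root(manifest), p))
}

#' Generate a synthetic phantom dataset on disk
#'
#' Writes PNG images (plus mask PNGs for the source domain) and a CSV
#' manifest.  Units are allocated to grades by largest-remainder rounding of
#' `grade_probs`, every unit owns the same number of images (up to
#' remainder), and images of one unit share gland geometry and dropout
#' fraction.  Target-domain images are passed through the domain's shift
#' spec; `mask_path` is left empty for them.
#'
#' @param config list with entries `image_size`, `n_glands`,
#'   `stripe_width_px`, and `domains`: a named list (`source`, `target`) of
#'   lists with `n` (images), `n_units`, `grade_probs` (length 4), optional
#'   `shift` ([domain_shift_spec()]) and optional `artifact_prob` /
#'   `artifact_spec`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @return the combined manifest (invisibly also written to
#'   `<out_dir>/manifest.csv`).
#' @export
generate_dataset <- function(config, out_dir, seed = 1L) {
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), showWarnings = FALSE)
  rows <- list()
  withr::with_seed(seed, {
    for (dn in names(config$domains)) {
      dc <- config$domains[[dn]]
      probs <- dc$grade_probs
      stopifnot(length(probs) == 4L)
      unit_grades <- rep(0:3, largest_remainder(dc$n_units, probs / sum(probs)))
      unit_grades <- sample(unit_grades)
      per_unit <- largest_remainder(dc$n, rep(1 / dc$n_units, dc$n_units))
      for (u in seq_len(dc$n_units)) {
        g <- unit_grades[u]
        rho <- switch(as.character(g),
                      "0" = 0,
                      "1" = stats::runif(1, 0.08, 0.30),
                      "2" = stats::runif(1, 0.36, 0.63),
                      "3" = stats::runif(1, 0.69, 0.95))
        uid <- sprintf("%s_u%03d", substr(dn, 1, 1), u)
        for (i in seq_len(per_unit[u])) {
          sp <- phantom_spec(
            image_size = config$image_size, n_glands = config$n_glands,
            stripe_width_px = config$stripe_width_px, rho = rho,
            unit_id = uid, domain_id = dn,
            artifact_spec = if (!is.null(dc$artifact_prob) &&
                                stats::runif(1) < dc$artifact_prob)
              dc$artifact_spec,
            rng_seed = sample.int(2^31 - 1L, 1L))
          sm <- render_phantom(sp)
          img <- sm$image
          if (!is.null(dc$shift)) {
            img <- apply_domain_shift(img, dc$shift,
                                      rng_seed = sp$rng_seed + 7L)
          }
          ipath <- sprintf("images/%s_%02d.png", uid, i)
          png::writePNG(img, file.path(out_dir, ipath))
          mpath <- ""
          if (dn == "source") {
            mpath <- sprintf("masks/%s_%02d.png", uid, i)
            png::writePNG(sm$mask, file.path(out_dir, mpath))
          }
          rows[[length(rows) + 1L]] <- data.frame(
            path = ipath, mask_path = mpath, grade = sm$grade,
            unit_id = uid, domain = dn, stringsAsFactors = FALSE)
        }
      }
    }
  })
  df <- do.call(rbind, rows)
  man <- as_manifest(df, root = normalizePath(out_dir))
  write_manifest(man, file.path(out_dir, "manifest.csv"))
  invisible(man)
}
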