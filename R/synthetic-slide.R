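#' Configuration for the synthetic pyramidal slide generator
#'
#' Describes a toy slide with known ground truth: a white background, smooth
#' tissue blobs in a stain-like pink, optionally a saturated marker stroke
#' (artifact) and a distinct darker "signal" subregion inside tissue.
#' Coarser pyramid levels are exact 2x decimations (strided subsampling) of
#' the base, so truth masks stay consistent across levels.
#'
#' @param base_size base-level side in pixels.
#' @param n_levels pyramid levels (factor-2 ladder, finest first).
#' @param n_blobs number of tissue disks (0 gives an empty slide).
#' @param blob_radius_range disk radius range as a fraction of `base_size`.
#' @param artifact add a marker stroke crossing the first blob.
#' @param signal add a signal subregion inside the first blob.
#' @param tissue_color,artifact_color,signal_color,background_color RGB
#'   triples in `[0, 1]`.
#' @param slide_id,label,slide_type,mpp slide metadata.
#' @return a list of class `slide_gen_config`.
#' @export
slide_gen_config <- function(base_size = 2048L, n_levels = 3L, n_blobs = 3L,
                             blob_radius_range = c(0.15, 0.28),
                             artifact = FALSE, signal = FALSE,
                             tissue_color = c(0.85, 0.62, 0.72),
                             artifact_color = c(0.05, 0.75, 0.15),
                             signal_color = c(0.65, 0.40, 0.55),
                             background_color = c(1, 1, 1),
                             slide_id = "synthetic_slide", label = NA_integer_,
                             slide_type = "FFPE", mpp = 0.5) {
  check_that(n_levels >= 2L, "need at least 2 levels (base + thumbnail)")
  check_that(base_size %% 2L^(n_levels - 1L) == 0L,
             "base_size must be divisible by 2^(n_levels - 1)")
  structure(as.list(environment()), class = "slide_gen_config")
}

#' Generate a synthetic pyramidal slide with ground truth
#'
#' @param config a [slide_gen_config()].
#' @param seed integer seed controlling blob placement.
#' @return list with `pyramid` (a [wsi_pyramid()]) and `truth`: logical
#'   base-level masks `tissue`, `artifact`, `signal`, plus
#'   `background_color` and the per-level decimation stride. Truth masks at
#'   coarser levels come from [truth_at_level()].
#' @export
gen_slide <- function(config, seed = 1L) {
  n <- config$base_size
  cx <- matrix(rep(seq_len(n) - 0.5, each = n), n, n)   # x coordinate per pixel
  cy <- matrix(rep(seq_len(n) - 0.5, times = n), n, n)  # y coordinate per pixel
  tissue <- matrix(FALSE, n, n)
  blobs <- with_seed(seed, {
    if (config$n_blobs == 0L) NULL else
      data.frame(x = stats::runif(config$n_blobs, 0.2, 0.8) * n,
                 y = stats::runif(config$n_blobs, 0.2, 0.8) * n,
                 r = stats::runif(config$n_blobs,
                                  config$blob_radius_range[1L],
                                  config$blob_radius_range[2L]) * n)
  })
  if (!is.null(blobs)) {
    for (b in seq_len(nrow(blobs))) {
      tissue <- tissue |
        ((cx - blobs$x[b])^2 + (cy - blobs$y[b])^2 <= blobs$r[b]^2)
    }
  }
  artifact <- matrix(FALSE, n, n)
  if (isTRUE(config$artifact) && !is.null(blobs)) {
    # a marker stroke: thin vertical bar through the first blob
    x0 <- round(blobs$x[1L]); hw <- max(2L, round(n * 0.01))
    xs <- max(1L, x0 - hw):min(n, x0 + hw)
    ys <- max(1L, round(blobs$y[1L] - blobs$r[1L] * 1.5)):
      min(n, round(blobs$y[1L] + blobs$r[1L] * 1.5))
    artifact[ys, xs] <- TRUE
  }
  signal <- matrix(FALSE, n, n)
  if (isTRUE(config$signal) && !is.null(blobs)) {
    signal <- ((cx - blobs$x[1L])^2 + (cy - blobs$y[1L])^2 <=
                 (blobs$r[1L] * 0.5)^2)
  }
  img <- array(rep(config$background_color, each = n * n), c(n, n, 3L))
  for (c in 1:3) {
    ch <- img[, , c]
    ch[tissue] <- config$tissue_color[c]
    ch[signal] <- config$signal_color[c]
    ch[artifact] <- config$artifact_color[c]
    img[, , c] <- ch
  }
  img <- round(img * 255) / 255            # 8-bit grid: TIFF round-trips exactly
  levels <- vector("list", config$n_levels)
  levels[[1L]] <- img
  for (l in 2:config$n_levels) {
    prev <- levels[[l - 1L]]
    keep <- seq(1L, dim(prev)[1L], by = 2L)
    levels[[l]] <- prev[keep, keep, , drop = FALSE]
  }
  pyramid <- wsi_pyramid(levels, 2^(seq_len(config$n_levels) - 1L),
                         slide_id = config$slide_id, label = config$label,
                         slide_type = config$slide_type, mpp = config$mpp)
  truth <- list(tissue = tissue, artifact = artifact, signal = signal,
                background_color = config$background_color)
  list(pyramid = pyramid, truth = truth)
}

#' Decimate a base-level truth mask to a coarser pyramid level
#'
#' Applies the same strided 2x decimation the image levels use, so the mask
#' at level `l` corresponds pixel-for-pixel to the image at level `l`.
#'
#' @param mask logical base-level matrix.
#' @param level 1-based level index.
#' @return logical matrix at that level's resolution.
#' @export
truth_at_level <- function(mask, level) {
  for (l in seq_len(level - 1L)) {
    keep <- seq(1L, nrow(mask), by = 2L)
    mask <- mask[keep, keep, drop = FALSE]
  }
  mask
}

#' Write the ground-truth masks next to a slide
#'
#' @param truth the `truth` element of [gen_slide()].
#' @param dir output directory; writes `tissue.png`, `artifact.png`,
#'   `signal.png`.
#' @return `dir`, invisibly.
#' @export
write_truth_masks <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("tissue", "artifact", "signal")) {
    png::writePNG(truth[[nm]] * 1, file.path(dir, paste0(nm, ".png")))
  }
  invisible(dir)
}
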