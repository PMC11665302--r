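# Ruifrok-Johnston stain separation vectors for H&E + DAB: rows are the
# optical-density directions of hematoxylin, eosin and DAB in RGB space.
RGB_FROM_HED <- matrix(c(0.65, 0.70, 0.29,
                         0.07, 0.99, 0.11,
                         0.27, 0.57, 0.78), 3, 3, byrow = TRUE)
HED_FROM_RGB <- solve(RGB_FROM_HED)

# RGB (h x w x 3, (0,1]) -> HED optical-density concentrations
rgb_to_hed <- function(img, eps = 1e-6) {
  od <- -log10(pmax(img, eps))
  dm <- dim(od)
  flat <- matrix(od, ncol = 3L) %*% HED_FROM_RGB
  array(flat, dm)
}

hed_to_rgb <- function(hed) {
  dm <- dim(hed)
  od <- matrix(hed, ncol = 3L) %*% RGB_FROM_HED
  img <- 10^(-od)
  array(pmin(pmax(img, 0), 1), dm)
}

#' Apply one deterministic tile augmentation
#'
#' The augmentation family used for tile embeddings: per-channel HED stain
#' scaling/offset (in optical-density space), additive Gaussian pixel noise,
#' a right-angle rotation and optional horizontal/vertical flips, applied in
#' that order. With identity parameters (`hed_alpha = 1`, `hed_beta = 0`,
#' `noise_sd = 0`, `rotation = 0`, no flips) the tile is returned unchanged
#' (up to floating-point round-trip of the stain transform).
#'
#' @param tile RGB array in `[0, 1]`.
#' @param params list with `hed_alpha` (3), `hed_beta` (3), `noise_sd`,
#'   `rotation` (0/90/180/270), `flip_h`, `flip_v`, and optionally
#'   `noise_seed` for the Gaussian draw.
#' @return augmented RGB array, same shape and range.
#' @export
apply_augmentation <- function(tile, params) {
  out <- tile
  if (any(params$hed_alpha != 1) || any(params$hed_beta != 0)) {
    hed <- rgb_to_hed(out)
    for (c in 1:3)
      hed[, , c] <- hed[, , c] * params$hed_alpha[c] + params$hed_beta[c]
    out <- hed_to_rgb(hed)
  }
  if (params$noise_sd > 0) {
    noise <- with_seed(params$noise_seed %||% 1L,
                       array(stats::rnorm(length(out), sd = params$noise_sd),
                             dim = dim(out)))
    out <- pmin(pmax(out + noise, 0), 1)
  }
  rot <- params$rotation %% 360
  check_that(rot %in% c(0, 90, 180, 270), "rotation must be a right angle")
  if (rot > 0) for (i in seq_len(rot / 90)) out <- rotate90(out)
  if (isTRUE(params$flip_h)) out <- out[, rev(seq_len(dim(out)[2L])), , drop = FALSE]
  if (isTRUE(params$flip_v)) out <- out[rev(seq_len(dim(out)[1L])), , , drop = FALSE]
  out
}

# clockwise 90-degree rotation of an h x w x 3 array
rotate90 <- function(img) {
  aperm(img, c(2L, 1L, 3L))[, rev(seq_len(dim(img)[1L])), , drop = FALSE]
}

#' Draw seeded augmentation parameters
#'
#' @param seed integer seed.
#' @param hed_scale_range multiplicative stain perturbation range.
#' @param hed_offset_range additive stain perturbation range.
#' @param noise_sd Gaussian pixel noise standard deviation.
#' @return a params list for [apply_augmentation()].
#' @export
draw_augmentation_params <- function(seed, hed_scale_range = c(0.95, 1.05),
                                     hed_offset_range = c(-0.02, 0.02),
                                     noise_sd = 0.01) {
  with_seed(seed, list(
    hed_alpha = stats::runif(3, hed_scale_range[1L], hed_scale_range[2L]),
    hed_beta = stats::runif(3, hed_offset_range[1L], hed_offset_range[2L]),
    noise_sd = noise_sd,
    noise_seed = sample.int(.Machine$integer.max, 1L),
    rotation = sample(c(0, 90, 180, 270), 1L),
    flip_h = stats::runif(1) < 0.5,
    flip_v = stats::runif(1) < 0.5))
}

#' Generate the two standard augmentations of a tile
#'
#' Each of the two outputs independently samples stain perturbation, noise,
#' rotation and flips; the pair is deterministic for a given seed.
#'
#' @param tile RGB array (a 512 x 512 tile in the standard pipeline).
#' @param seed integer seed.
#' @param n_augment number of augmented copies.
#' @return list of `n_augment` augmented tiles.
#' @export
augment_tile <- function(tile, seed, n_augment = 2L) {
  lapply(seq_len(n_augment), function(i)
    apply_augmentation(tile, draw_augmentation_params(seed + (i - 1L))))
}
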