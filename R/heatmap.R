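#' Tile footprints on the thumbnail
#'
#' Maps tile top-left coordinates at a given pyramid level to half-open
#' pixel rectangles on the thumbnail, using the ratio of downsample factors.
#'
#' @param tiles data.frame with `x`, `y` (tile top-left, level pixels).
#' @param level_downsample downsample factor of the tile level.
#' @param thumb_downsample downsample factor of the thumbnail.
#' @param tile_px tile side in level pixels.
#' @return data.frame `x0`, `y0`, `x1`, `y1` (0-based, half-open, thumbnail
#'   pixels).
#' @export
tile_footprints <- function(tiles, level_downsample, thumb_downsample,
                            tile_px = 512L) {
  scale <- level_downsample / thumb_downsample
  data.frame(x0 = floor(tiles$x * scale), y0 = floor(tiles$y * scale),
             x1 = ceiling((tiles$x + tile_px) * scale),
             y1 = ceiling((tiles$y + tile_px) * scale))
}

#' Render a continuous attention heatmap ("virtual staining")
#'
#' Attention weights are min-max rescaled across the slide's tiles (per-slide
#' relative scaling: absolute attention magnitudes are not comparable across
#' slides), mapped through a continuous perceptually uniform colormap and
#' alpha-blended onto the thumbnail over each tile footprint. Pixels outside
#' every footprint are left untouched.
#'
#' @param thumbnail RGB array in `[0, 1]`.
#' @param footprints data.frame from [tile_footprints()].
#' @param scores per-tile attention weights (nonnegative, summing to 1).
#' @param opacity overlay alpha in `[0, 1]`.
#' @param colormap function `n -> n hex colors` (continuous ramp).
#' @return RGB array, same shape as the thumbnail.
#' @export
render_attention <- function(thumbnail, footprints, scores, opacity = 0.5,
                             colormap = function(n)
                               grDevices::hcl.colors(n, "viridis")) {
  if (length(scores) == 0L) return(thumbnail)
  check_that(nrow(footprints) == length(scores),
             "one score per footprint required")
  check_that(all(scores >= 0) && abs(sum(scores) - 1) < 1e-6,
             "attention scores must lie on the simplex")
  rng <- range(scores)
  rel <- if (length(scores) == 1L) {
    1                       # a lone tile is trivially the slide's maximum
  } else if (diff(rng) < .Machine$double.eps^0.5) {
    warning("all attention scores equal: rendering uniform mid-scale overlay")
    rep(0.5, length(scores))
  } else (scores - rng[1L]) / diff(rng)
  ramp <- grDevices::col2rgb(colormap(256L)) / 255
  cols <- ramp[, pmin(255L, floor(rel * 255)) + 1L, drop = FALSE]
  blend_tiles(thumbnail, footprints, cols, opacity)
}

#' Render the binary excitatory/inhibitory contribution map
#'
#' Bounded patch contributions above 0.5 (excitatory for the positive class)
#' are painted red, those at or below 0.5 (inhibitory) blue, at fixed
#' opacity; exactly two overlay colors appear. Only additive variants
#' produce the patch scores this map needs.
#'
#' @param thumbnail RGB array in `[0, 1]`.
#' @param footprints data.frame from [tile_footprints()].
#' @param scores bounded contribution scores, strictly inside (0, 1).
#' @param opacity overlay alpha.
#' @return RGB array.
#' @export
render_contributions <- function(thumbnail, footprints, scores,
                                 opacity = 0.5) {
  if (length(scores) == 0L) return(thumbnail)
  check_that(nrow(footprints) == length(scores),
             "one score per footprint required")
  check_that(all(scores > 0 & scores < 1),
             "contribution scores must lie strictly inside (0, 1)")
  red <- c(1, 0, 0); blue <- c(0, 0, 1)
  cols <- vapply(scores, function(s) if (s > 0.5) red else blue, numeric(3))
  blend_tiles(thumbnail, footprints, cols, opacity)
}

# alpha-blend per-tile solid colors (3 x n matrix) over footprints
blend_tiles <- function(thumbnail, footprints, cols, opacity) {
  out <- thumbnail
  H <- dim(out)[1L]; W <- dim(out)[2L]
  for (i in seq_len(nrow(footprints))) {
    check_that(footprints$x0[i] >= 0 && footprints$y0[i] >= 0 &&
                 footprints$x1[i] <= W && footprints$y1[i] <= H &&
                 footprints$x1[i] > footprints$x0[i] &&
                 footprints$y1[i] > footprints$y0[i],
               "tile footprint %d lies outside the thumbnail", i)
    rows <- (footprints$y0[i] + 1L):footprints$y1[i]
    colsx <- (footprints$x0[i] + 1L):footprints$x1[i]
    for (c in 1:3) {
      out[rows, colsx, c] <- (1 - opacity) * out[rows, colsx, c] +
        opacity * cols[c, i]
    }
  }
  out
}

#' Write a heatmap PNG with a score sidecar
#'
#' @param img RGB array from a render function.
#' @param path output PNG path; per-tile scores and footprints go to
#'   `<path>.json` for downstream viewers.
#' @param footprints,scores the inputs that produced `img` (optional).
#' @return `path`, invisibly.
#' @export
write_heatmap_png <- function(img, path, footprints = NULL, scores = NULL) {
  png::writePNG(img, path)
  if (!is.null(scores)) {
    jsonlite::write_json(list(scores = scores, footprints = footprints),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
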