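#' An in-memory pyramidal slide
#'
#' A minimal pyramid-reader contract standing in for scanner formats: a list
#' of RGB levels (arrays `h x w x 3` in `[0, 1]`), strictly increasing
#' downsample factors relative to the base level, and slide metadata. The
#' coarsest level doubles as the thumbnail. Scanner formats can be adapted by
#' constructing this object from any reader.
#'
#' @param levels list of RGB arrays, finest first.
#' @param downsamples numeric vector of per-level downsample factors
#'   (base level = 1), strictly increasing.
#' @param slide_id slide identifier.
#' @param label optional binary slide label.
#' @param slide_type `"FFPE"` or `"frozen"`.
#' @param mpp microns per pixel at the base level (> 0).
#' @return an object of class `wsi_pyramid`.
#' @export
wsi_pyramid <- function(levels, downsamples, slide_id, label = NA_integer_,
                        slide_type = c("FFPE", "frozen"), mpp = 0.25) {
  slide_type <- match.arg(slide_type)
  check_that(length(levels) >= 1L, "a pyramid needs at least one level")
  check_that(length(downsamples) == length(levels),
             "one downsample factor per level required")
  check_that(all(diff(downsamples) > 0),
             "downsample factors must be strictly increasing")
  check_that(is.na(mpp) || mpp > 0, "mpp must be positive")
  base_dim <- dim(levels[[1L]])[1:2]
  for (l in seq_along(levels)) {
    dl <- dim(levels[[l]])
    check_that(length(dl) == 3L && dl[3L] == 3L,
               "level %d is not an RGB array", l)
    expect_dim <- round(base_dim * downsamples[1L] / downsamples[l])
    check_that(all(abs(dl[1:2] - expect_dim) <= 1),
               "level %d dimensions inconsistent with its downsample factor", l)
  }
  structure(list(levels = levels, downsamples = as.numeric(downsamples),
                 slide_id = slide_id, label = label, slide_type = slide_type,
                 mpp = mpp),
            class = "wsi_pyramid")
}

#' @export
print.wsi_pyramid <- function(x, ...) {
  dims <- vapply(x$levels, function(l) paste(dim(l)[2:1], collapse = "x"),
                 character(1))
  cat(sprintf("<wsi_pyramid '%s' (%s, mpp %.3g): %d level(s) [%s], downsamples %s>\n",
              x$slide_id, x$slide_type, x$mpp, length(x$levels),
              paste(dims, collapse = ", "),
              paste(x$downsamples, collapse = ", ")))
  invisible(x)
}

n_levels <- function(pyramid) length(pyramid$levels)

#' Read a rectangular region from a pyramid level
#'
#' The pixel accessor of the pyramid contract. Coordinates are 0-based
#' half-open `[x, x + w)` in the pixel grid of the requested level. Regions
#' extending past the level boundary are cropped (the caller pads).
#'
#' @param pyramid a `wsi_pyramid`.
#' @param level 1-based level index (1 = base, finest).
#' @param x,y top-left corner, 0-based, in level pixels.
#' @param w,h region width and height in level pixels.
#' @return RGB array `h' x w' x 3` with `h' <= h`, `w' <= w` after cropping.
#' @export
read_region <- function(pyramid, level, x, y, w, h) {
  check_that(level >= 1L && level <= n_levels(pyramid),
             "level %d out of range (1..%d)", level, n_levels(pyramid))
  img <- pyramid$levels[[level]]
  H <- dim(img)[1L]; W <- dim(img)[2L]
  check_that(x >= 0 && y >= 0, "region origin must be non-negative")
  check_that(x < W && y < H, "region origin (%d, %d) outside level extent", x, y)
  rows <- (y + 1):min(y + h, H)
  cols <- (x + 1):min(x + w, W)
  img[rows, cols, , drop = FALSE]
}

#' Thumbnail of a pyramid (its coarsest level)
#' @param pyramid a `wsi_pyramid`.
#' @return RGB array.
#' @export
pyramid_thumbnail <- function(pyramid) pyramid$levels[[n_levels(pyramid)]]

#' Write / read a pyramid as a multi-level TIFF
#'
#' Serializes each level as one directory of a multi-image TIFF, finest
#' first. Metadata travels in a JSON sidecar (`<path>.json`) holding
#' slide_id, label, slide_type, mpp and the downsample ladder.
#'
#' @param pyramid a `wsi_pyramid`.
#' @param path output `.tiff` path.
#' @return `path` (write) or a `wsi_pyramid` (read).
#' @export
write_pyramid_tiff <- function(pyramid, path) {
  tiff::writeTIFF(pyramid$levels, path, bits.per.sample = 8L)
  meta <- list(slide_id = pyramid$slide_id, label = pyramid$label,
               slide_type = pyramid$slide_type, mpp = pyramid$mpp,
               downsamples = pyramid$downsamples)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_pyramid_tiff
#' @export
read_pyramid_tiff <- function(path) {
  levels <- tiff::readTIFF(path, all = TRUE)
  meta_path <- paste0(path, ".json")
  check_that(file.exists(meta_path), "missing sidecar '%s'", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  wsi_pyramid(levels, meta$downsamples, meta$slide_id,
              label = if (is.null(meta$label) || is.na(meta$label))
                NA_integer_ else as.integer(meta$label),
              slide_type = meta$slide_type, mpp = meta$mpp)
}
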