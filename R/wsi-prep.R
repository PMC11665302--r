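#' Extract slide metadata to a table
#'
#' One row per slide: id, label, slide type and microns-per-pixel at the base
#' level. Rows with a missing label or missing/non-positive mpp are flagged
#' invalid (with a warning) and should be excluded downstream.
#'
#' @param slides list of `wsi_pyramid` objects.
#' @return data.frame with columns `slide_id`, `label`, `slide_type`, `mpp`,
#'   `valid`.
#' @export
extract_metadata <- function(slides) {
  rows <- lapply(slides, function(s) {
    data.frame(slide_id = s$slide_id,
               label = if (is.null(s$label)) NA_integer_ else s$label,
               slide_type = s$slide_type,
               mpp = if (is.null(s$mpp)) NA_real_ else s$mpp)
  })
  meta <- do.call(rbind, rows)
  meta$valid <- !is.na(meta$label) & !is.na(meta$mpp) & meta$mpp > 0
  if (any(!meta$valid))
    warning(sum(!meta$valid), " slide(s) with missing label or mpp flagged invalid")
  meta
}

#' Write / read the metadata CSV
#'
#' Round-trips the table of [extract_metadata()] losslessly through CSV
#' (header `slide_id,label,slide_type,mpp,valid`, UTF-8).
#'
#' @param meta metadata data.frame.
#' @param path CSV path.
#' @export
write_metadata_csv <- function(meta, path) {
  utils::write.csv(meta, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_metadata_csv
#' @export
read_metadata_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Segment tissue on a slide thumbnail
#'
#' Converts the thumbnail to grayscale, finds Otsu's threshold, takes the
#' darker class as tissue (slides have a bright background), and applies a
#' morphological closing to fill pinholes and filter speckle noise. Returns
#' the set of tissue pixel coordinates together with the mean tissue color
#' and the grayscale cutoff (reused for tile-level tissue fractions).
#'
#' @param thumbnail RGB array `h x w x 3` in `[0, 1]`.
#' @param closing_size side of the square structuring element (pixels).
#' @param invert set `TRUE` for dark-background imagery (tissue = brighter
#'   class).
#' @return a list of class `tissue_pixels`: `P` (m x 2 integer matrix of
#'   0-based `(x, y)` coordinates), `mask` (logical h x w matrix),
#'   `mean_color` (RGB of tissue pixels), `cutoff` (grayscale Otsu
#'   threshold), `background_color` (mean RGB outside the mask).
#' @export
tissue_mask <- function(thumbnail, closing_size = 3L, invert = FALSE) {
  check_that(length(dim(thumbnail)) == 3L && dim(thumbnail)[3L] == 3L,
             "thumbnail must be an RGB array")
  gray <- rowMeans(thumbnail, dims = 2L)
  if (diff(range(gray)) < .Machine$double.eps^0.5) {
    warning("uniform thumbnail: Otsu threshold undefined, returning empty tissue set")
    return(empty_tissue_pixels(thumbnail))
  }
  cutoff <- EBImage::otsu(EBImage::Image(gray), range = c(0, 1))
  mask <- if (invert) gray > cutoff else gray < cutoff
  if (closing_size >= 2L) {
    kern <- EBImage::makeBrush(as.integer(closing_size), shape = "box")
    mask <- EBImage::closing(EBImage::Image(mask * 1), kern) > 0.5
  }
  mask <- matrix(as.logical(mask), nrow(gray), ncol(gray))
  if (!any(mask)) {
    warning("no tissue pixels found on thumbnail")
    return(empty_tissue_pixels(thumbnail, cutoff))
  }
  idx <- which(mask, arr.ind = TRUE)             # (row, col) 1-based
  P <- cbind(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L)
  structure(list(P = P, mask = mask,
                 mean_color = pixel_mean_color(thumbnail, mask),
                 cutoff = as.numeric(cutoff),
                 background_color = pixel_mean_color(thumbnail, !mask)),
            class = "tissue_pixels")
}

empty_tissue_pixels <- function(thumbnail, cutoff = NA_real_) {
  h <- dim(thumbnail)[1L]; w <- dim(thumbnail)[2L]
  structure(list(P = matrix(integer(0), 0, 2,
                            dimnames = list(NULL, c("x", "y"))),
                 mask = matrix(FALSE, h, w),
                 mean_color = rep(NA_real_, 3),
                 cutoff = cutoff,
                 background_color = pixel_mean_color(thumbnail,
                                                     matrix(TRUE, h, w))),
            class = "tissue_pixels")
}

pixel_mean_color <- function(img, mask) {
  if (!any(mask)) return(rep(NA_real_, 3))
  vapply(1:3, function(c) mean(img[, , c][mask]), numeric(1))
}

#' Filter artifact pixels by color distance
#'
#' Scanner artifacts and pathologists' pen annotations have colors far from
#' the stain. Each tissue pixel's RGB color is compared with the average
#' color of the whole input set `P` (computed once, not iterated); pixels
#' whose Euclidean distance exceeds the threshold are dropped.
#'
#' @param tps a `tissue_pixels` from [tissue_mask()].
#' @param thumbnail the same RGB thumbnail.
#' @param threshold maximum distance in 8-bit RGB units (0..441).
#' @return a filtered `tissue_pixels` (mask, P and mean colors updated; the
#'   Otsu cutoff is retained).
#' @export
artifact_filter <- function(tps, thumbnail, threshold = 100) {
  check_that(threshold >= 0, "artifact_filter: threshold must be >= 0")
  check_that(nrow(tps$P) > 0L, "artifact_filter: empty tissue pixel set")
  rgb255 <- vapply(1:3, function(c)
    thumbnail[cbind(tps$P[, "y"] + 1L, tps$P[, "x"] + 1L, c)] * 255,
    numeric(nrow(tps$P)))
  rgb255 <- matrix(rgb255, ncol = 3L)
  mean_col <- colMeans(rgb255)
  keep <- sqrt(rowSums(sweep(rgb255, 2L, mean_col)^2)) <= threshold
  mask <- matrix(FALSE, nrow(tps$mask), ncol(tps$mask))
  kept <- tps$P[keep, , drop = FALSE]
  mask[cbind(kept[, "y"] + 1L, kept[, "x"] + 1L)] <- TRUE
  structure(list(P = kept, mask = mask,
                 mean_color = pixel_mean_color(thumbnail, mask),
                 cutoff = tps$cutoff,
                 background_color = tps$background_color),
            class = "tissue_pixels")
}

#' Map thumbnail tissue pixels to candidate tile coordinates
#'
#' Uses the hierarchical property of the pyramid: a thumbnail pixel `(x, y)`
#' covers base coordinates around `(x, y) * thumb_downsample`; the covering
#' tile at the target level is `floor(base / (tile_px * target_downsample))`.
#' Duplicate tiles are collapsed and the result is sorted row-major.
#'
#' @param P m x 2 matrix of 0-based thumbnail `(x, y)` tissue coordinates.
#' @param thumb_downsample thumbnail downsample factor (relative to base).
#' @param target_downsample downsample factor of the tile level; must be
#'   finer than (or equal to) the thumbnail.
#' @param tile_px tile side in level pixels.
#' @return data.frame of candidate tiles: `tile_ix`, `tile_iy` (grid index),
#'   `x`, `y` (top-left, target-level pixels).
#' @export
map_thumb_to_tiles <- function(P, thumb_downsample, target_downsample,
                               tile_px = 512L) {
  check_that(thumb_downsample > 0 && target_downsample > 0,
             "downsample factors must be positive")
  check_that(thumb_downsample >= target_downsample,
             "target level (downsample %g) is coarser than the thumbnail (%g)",
             target_downsample, thumb_downsample)
  if (nrow(P) == 0L)
    return(data.frame(tile_ix = integer(0), tile_iy = integer(0),
                      x = integer(0), y = integer(0)))
  base_x <- P[, 1L] * thumb_downsample
  base_y <- P[, 2L] * thumb_downsample
  span <- tile_px * target_downsample            # tile footprint in base px
  ix <- floor(base_x / span)
  iy <- floor(base_y / span)
  keys <- unique(cbind(iy, ix))
  keys <- keys[order(keys[, 1L], keys[, 2L]), , drop = FALSE]
  data.frame(tile_ix = as.integer(keys[, 2L]), tile_iy = as.integer(keys[, 1L]),
             x = as.integer(keys[, 2L]) * as.integer(tile_px),
             y = as.integer(keys[, 1L]) * as.integer(tile_px))
}

#' Accept, pad or reject a fetched tile
#'
#' Tiles cut at the slide border come back smaller than `tile_px`; they are
#' padded on the right/bottom with the average background color. The tissue
#' fraction is the share of tile pixels darker than the slide-level Otsu
#' cutoff (the same criterion as the thumbnail mask, applied at tile scale,
#' over the full padded area); tiles below `tissue_threshold` are rejected.
#'
#' @param tile RGB array (height/width at most `tile_px`).
#' @param cutoff grayscale Otsu cutoff from [tissue_mask()].
#' @param tissue_threshold minimum tissue fraction to accept.
#' @param background_color RGB triple used for padding.
#' @param tile_px tile side.
#' @param invert same polarity flag as in [tissue_mask()].
#' @return list with `tile` (padded `tile_px` square), `tissue_fraction`,
#'   `status` (`"accepted"`, `"padded+accepted"` or `"rejected"`).
#' @export
accept_tile <- function(tile, cutoff, tissue_threshold = 0.3,
                        background_color = c(1, 1, 1), tile_px = 512L,
                        invert = FALSE) {
  dm <- dim(tile)
  check_that(dm[1L] <= tile_px && dm[2L] <= tile_px,
             "oversized tile %dx%d (tile_px = %d)", dm[2L], dm[1L], tile_px)
  padded <- dm[1L] < tile_px || dm[2L] < tile_px
  if (padded) {
    full <- array(rep(background_color, each = tile_px * tile_px),
                  dim = c(tile_px, tile_px, 3L))
    full[seq_len(dm[1L]), seq_len(dm[2L]), ] <- tile
    tile <- full
  }
  gray <- rowMeans(tile, dims = 2L)
  frac <- if (invert) mean(gray > cutoff) else mean(gray < cutoff)
  status <- if (frac >= tissue_threshold) {
    if (padded) "padded+accepted" else "accepted"
  } else "rejected"
  list(tile = tile, tissue_fraction = frac, status = status)
}

#' Random fraction sampling of tiles
#'
#' When a slide yields more than `limit` candidate tiles, a uniform random
#' `fraction` of them is kept (without replacement); otherwise all tiles are
#' used. Deterministic for a given seed.
#'
#' @param tiles data.frame of tiles (any columns).
#' @param fraction sampling fraction in (0, 1].
#' @param limit per-slide tile count above which sampling kicks in.
#' @param seed integer seed.
#' @return the sampled rows, original order preserved.
#' @export
sample_fraction <- function(tiles, fraction = 0.6, limit = 1000L, seed = 1L) {
  check_that(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  n <- nrow(tiles)
  if (n <= limit) return(tiles)
  keep <- with_seed(seed, sort(sample(n, round(fraction * n))))
  tiles[keep, , drop = FALSE]
}

#' Cluster-based sampling of parent tiles
#'
#' For moving one magnification step down the pyramid: k-means clusters the
#' parent tiles by their embeddings (morphological groups), then draws at
#' most `n_per_cluster` tiles uniformly from each cluster. Child tiles of
#' the selection are fetched with [expand_to_children()].
#'
#' @param parent_embeddings numeric matrix, one row per parent tile.
#' @param parent_tiles data.frame of parent tiles (rows correspond).
#' @param k number of k-means clusters (clamped to the tile count with a
#'   warning if larger).
#' @param n_per_cluster per-cluster cap.
#' @param seed integer seed for both the clustering and the draws.
#' @return list with `tiles` (selected rows), `cluster` (cluster id per
#'   selected row), `assignment` (cluster id for every parent tile).
#' @export
cluster_sample <- function(parent_embeddings, parent_tiles, k = 4L,
                           n_per_cluster = 20L, seed = 1L) {
  parent_embeddings <- as.matrix(parent_embeddings)
  n <- nrow(parent_embeddings)
  check_that(n >= 1L && n == nrow(parent_tiles),
             "embeddings and tiles must align")
  check_that(k >= 1L, "k must be >= 1")
  if (k > n) {
    warning("k = ", k, " exceeds the number of tiles (", n, "); clamped")
    k <- n
  }
  with_seed(seed, {
    # duplicate embeddings (e.g. visually identical tiles) and k >= n both
    # break stats::kmeans' center sampling; cluster the unique rows instead
    uniq <- unique(parent_embeddings)
    assignment <- if (k == 1L) {
      rep(1L, n)
    } else if (nrow(uniq) <= k) {
      k <- nrow(uniq)
      row_key <- apply(parent_embeddings, 1L, paste, collapse = "\r")
      match(row_key, apply(uniq, 1L, paste, collapse = "\r"))
    } else {
      centers <- uniq[sample(nrow(uniq), k), , drop = FALSE]
      stats::kmeans(parent_embeddings, centers = centers)$cluster
    }
    sel <- unlist(lapply(seq_len(k), function(cl) {
      members <- which(assignment == cl)
      if (length(members) <= n_per_cluster) members
      else sample(members, n_per_cluster)
    }), use.names = FALSE)
    sel <- sort(sel)
    list(tiles = parent_tiles[sel, , drop = FALSE],
         cluster = assignment[sel], assignment = assignment)
  })
}

#' Expand a parent tile into its child tiles one magnification up
#'
#' A tile at downsample `s_p` covers `r x r` tiles at downsample `s_c`,
#' where `r = s_p / s_c` must be an integer. Returns the grid of child tiles
#' whose base-coordinate footprints exactly partition the parent footprint.
#'
#' @param parent_tile list or one-row data.frame with `x`, `y` (top-left in
#'   parent-level pixels).
#' @param parent_downsample,child_downsample downsample factors; the child
#'   level must be finer.
#' @param tile_px tile side.
#' @return data.frame of child tiles: `tile_ix`, `tile_iy`, `x`, `y` in
#'   child-level pixels.
#' @export
expand_to_children <- function(parent_tile, parent_downsample,
                               child_downsample, tile_px = 512L) {
  r <- parent_downsample / child_downsample
  check_that(r >= 1 && abs(r - round(r)) < 1e-9,
             "parent/child downsample ratio %g is not a positive integer", r)
  r <- as.integer(round(r))
  px <- as.integer(parent_tile$x); py <- as.integer(parent_tile$y)
  # child grid origin: parent origin re-expressed in child-level pixels
  ox <- px * r
  oy <- py * r
  grid <- expand.grid(dx = 0:(r - 1L), dy = 0:(r - 1L))
  out <- data.frame(
    tile_ix = (ox %/% tile_px) + grid$dx,
    tile_iy = (oy %/% tile_px) + grid$dy,
    x = ox + grid$dx * tile_px,
    y = oy + grid$dy * tile_px)
  out[order(out$tile_iy, out$tile_ix), , drop = FALSE]
}
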