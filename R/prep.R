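#' Preprocess one slide into accepted tiles
#'
#' The per-slide pipeline: thumbnail tissue masking (Otsu + closing), color
#' -distance artifact filtering, hierarchical mapping of tissue pixels to
#' candidate tile coordinates at the requested magnification, tile fetching
#' with border padding and tissue-fraction acceptance, then either fraction
#' sampling (at the coarsest magnification of the ladder) or k-means
#' cluster sampling of the parent magnification followed by expansion to
#' child tiles.
#'
#' @param pyramid a `wsi_pyramid`.
#' @param config configuration list, see [default_config()].
#' @param encoder optional `mil_encoder`; required for cluster sampling
#'   (parent tiles are clustered in embedding space) and for
#'   [prep_slide_group()].
#' @return list with `manifest` (data.frame: slide_id, magnification, x, y,
#'   tissue_fraction, status — rejected tiles included), `tiles` (list of
#'   accepted padded tiles), `tissue` (the filtered `tissue_pixels`).
#' @export
prep_slide <- function(pyramid, config = default_config(), encoder = NULL) {
  mag <- config$magnification
  check_that(mag %in% names(MAG_LADDER), "unknown magnification '%s'", mag)
  thumb <- pyramid_thumbnail(pyramid)
  thumb_ds <- pyramid$downsamples[n_levels(pyramid)]
  tps <- tissue_mask(thumb, closing_size = config$closing_size)
  if (nrow(tps$P) == 0L)
    return(list(manifest = empty_manifest(), tiles = list(), tissue = tps))
  tps <- artifact_filter(tps, thumb, threshold = config$color_threshold)
  if (nrow(tps$P) == 0L)
    return(list(manifest = empty_manifest(), tiles = list(), tissue = tps))

  if (MAG_LADDER[mag] == max(MAG_LADDER)) {
    res <- fetch_at_level(pyramid, tps, mag, thumb_ds, config)
    acc <- res$manifest$status != "rejected"
    keep <- sample_fraction(res$manifest[acc, , drop = FALSE],
                            fraction = config$sample_fraction,
                            limit = config$tile_limit, seed = config$seed)
    res$tiles <- res$tiles[match(rownames(keep), rownames(res$manifest)[acc])]
    res$manifest <- rbind(keep, res$manifest[!acc, , drop = FALSE])
    res$tissue <- tps
    return(res)
  }

  # finer magnification: cluster-sample the parent level, expand to children
  parent_mag <- names(MAG_LADDER)[match(mag, names(MAG_LADDER)) + 1L]
  parent_cfg <- config; parent_cfg$magnification <- parent_mag
  parent <- prep_slide(pyramid, parent_cfg, encoder)
  pacc <- parent$manifest$status != "rejected"
  pman <- parent$manifest[pacc, , drop = FALSE]
  if (nrow(pman) == 0L)
    return(list(manifest = empty_manifest(), tiles = list(), tissue = tps))
  check_that(!is.null(encoder),
             "cluster sampling at %s needs an encoder for the parent tiles", mag)
  pemb <- encode_tiles(parent$tiles, encoder)
  cs <- cluster_sample(pemb, pman, k = config$kmeans_k,
                       n_per_cluster = config$tiles_per_cluster,
                       seed = config$seed)
  level <- level_for_mag(pyramid, mag)
  cutoff <- tps$cutoff; bg <- tps$background_color
  manifest <- list(); tiles <- list()
  for (i in seq_len(nrow(cs$tiles))) {
    children <- expand_to_children(cs$tiles[i, ], MAG_LADDER[parent_mag],
                                   MAG_LADDER[mag], config$tile_px)
    for (j in seq_len(nrow(children))) {
      rec <- fetch_one(pyramid, level, children$x[j], children$y[j], mag,
                       cutoff, bg, config)
      if (is.null(rec)) next
      manifest[[length(manifest) + 1L]] <- rec$row
      if (rec$row$status != "rejected") tiles[[length(tiles) + 1L]] <- rec$tile
    }
  }
  man <- if (length(manifest)) do.call(rbind, manifest) else empty_manifest()
  acc <- man$status != "rejected"
  man <- rbind(man[acc, , drop = FALSE], man[!acc, , drop = FALSE])
  list(manifest = man, tiles = tiles, tissue = tps)
}

empty_manifest <- function() {
  data.frame(slide_id = character(0), magnification = character(0),
             x = integer(0), y = integer(0), tissue_fraction = numeric(0),
             status = character(0))
}

level_for_mag <- function(pyramid, mag) {
  lvl <- match(MAG_LADDER[mag], pyramid$downsamples)
  check_that(!is.na(lvl), "pyramid has no level at downsample %g (%s)",
             MAG_LADDER[mag], mag)
  lvl
}

# fetch + accept every candidate tile mapped from the tissue pixel set
fetch_at_level <- function(pyramid, tps, mag, thumb_ds, config) {
  level <- level_for_mag(pyramid, mag)
  cands <- map_thumb_to_tiles(tps$P, thumb_ds, MAG_LADDER[mag], config$tile_px)
  manifest <- list(); tiles <- list()
  for (i in seq_len(nrow(cands))) {
    rec <- fetch_one(pyramid, level, cands$x[i], cands$y[i], mag,
                     tps$cutoff, tps$background_color, config)
    if (is.null(rec)) next
    manifest[[length(manifest) + 1L]] <- rec$row
    if (rec$row$status != "rejected") tiles[[length(tiles) + 1L]] <- rec$tile
  }
  man <- if (length(manifest)) do.call(rbind, manifest) else empty_manifest()
  list(manifest = man, tiles = tiles)
}

fetch_one <- function(pyramid, level, x, y, mag, cutoff, bg, config) {
  dimlvl <- dim(pyramid$levels[[level]])
  if (x >= dimlvl[2L] || y >= dimlvl[1L]) return(NULL)  # off-extent candidate
  raw <- read_region(pyramid, level, x, y, config$tile_px, config$tile_px)
  at <- accept_tile(raw, cutoff, tissue_threshold = config$tissue_threshold,
                    background_color = bg, tile_px = config$tile_px)
  list(row = data.frame(slide_id = pyramid$slide_id, magnification = mag,
                        x = x, y = y, tissue_fraction = at$tissue_fraction,
                        status = at$status),
       tile = at$tile)
}

#' Full prep of a slide into a store-ready group
#'
#' Runs [prep_slide()], augments each accepted tile, encodes originals and
#' augmentations, and bundles everything as a [slide_group()].
#'
#' @inheritParams prep_slide
#' @param encoder a `mil_encoder`.
#' @return list with `group` (a `slide_group`, `NULL` when no tile
#'   survives), `manifest`.
#' @export
prep_slide_group <- function(pyramid, config = default_config(), encoder) {
  prep <- prep_slide(pyramid, config, encoder)
  acc <- prep$manifest[prep$manifest$status != "rejected", , drop = FALSE]
  if (nrow(acc) == 0L) return(list(group = NULL, manifest = prep$manifest))
  emb <- encode_tiles(prep$tiles, encoder)
  aug_tiles <- list()
  for (i in seq_along(prep$tiles)) {
    pair <- augment_tile(prep$tiles[[i]],
                         seed = config$seed + 7919L * i,
                         n_augment = config$n_augment)
    aug_tiles <- c(aug_tiles, pair)
  }
  aug_emb <- if (length(aug_tiles)) encode_tiles(aug_tiles, encoder) else NULL
  mag_code <- match(acc$magnification, names(MAG_LADDER))
  coords <- cbind(level = mag_code, x = acc$x, y = acc$y)
  group <- slide_group(pyramid$slide_id, emb, coords,
                       label = pyramid$label, aug_embeddings = aug_emb)
  list(group = group, manifest = prep$manifest)
}
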