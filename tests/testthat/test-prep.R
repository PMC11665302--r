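toy_thumb <- function(size = 64, disk_center = c(32, 32), disk_r = 14,
                      tissue = c(0.8, 0.55, 0.65), bg = c(1, 1, 1)) {
  img <- array(rep(bg, each = size * size), c(size, size, 3))
  cx <- matrix(rep(seq_len(size) - 0.5, each = size), size, size)
  cy <- matrix(rep(seq_len(size) - 0.5, times = size), size, size)
  mask <- (cx - disk_center[1])^2 + (cy - disk_center[2])^2 <= disk_r^2
  for (c in 1:3) { ch <- img[, , c]; ch[mask] <- tissue[c]; img[, , c] <- ch }
  list(img = img, mask = mask)
}

test_that("metadata extraction passes fields through and flags bad rows", {
  s1 <- gen_slide(slide_gen_config(base_size = 64L, n_levels = 2L,
                                   slide_id = "a", label = 1L, mpp = 2.0))$pyramid
  s2 <- gen_slide(slide_gen_config(base_size = 64L, n_levels = 2L,
                                   slide_id = "b", slide_type = "frozen"))$pyramid
  expect_warning(meta <- extract_metadata(list(s1, s2)), "invalid")
  expect_identical(meta$slide_id, c("a", "b"))
  expect_equal(meta$mpp[1], 2.0)
  expect_identical(meta$valid, c(TRUE, FALSE))  # s2 has no label
  path <- tempfile(fileext = ".csv")
  write_metadata_csv(meta, path)
  expect_identical(read_metadata_csv(path), meta)
})

test_that("tissue masking recovers a dark disk on white ground", {
  tt <- toy_thumb()
  tps <- tissue_mask(tt$img)
  expect_gte(mask_iou(tps$mask, tt$mask), 0.9)
  # mean tissue color is the disk color
  expect_equal(tps$mean_color, c(0.8, 0.55, 0.65), tolerance = 0.05)
  # pure-white thumbnail has no tissue
  blank <- array(1, c(16, 16, 3))
  expect_warning(tps0 <- tissue_mask(blank), "uniform")
  expect_identical(nrow(tps0$P), 0L)
})

test_that("closing fills pinholes inside tissue", {
  tt <- toy_thumb()
  img <- tt$img
  img[32, 32, ] <- 1  # a 1-pixel hole
  tps <- tissue_mask(img, closing_size = 3)
  expect_true(tps$mask[32, 32])
  tps_open <- tissue_mask(img, closing_size = 0)
  expect_false(tps_open$mask[32, 32])
})

test_that("artifact filtering drops pixels far from the mean tissue color", {
  tt <- toy_thumb(tissue = c(200, 150, 160) / 255)
  img <- tt$img
  img[32, 32, ] <- c(0, 1, 0)  # saturated green marker pixel
  tps <- tissue_mask(img, closing_size = 0)
  expect_true(tps$mask[32, 32])
  filtered <- artifact_filter(tps, img, threshold = 100)
  expect_false(filtered$mask[32, 32])
  # distance of the marker from pink tissue: sqrt(200^2+105^2+160^2) = 276.8,
  # comfortably past the 100-unit threshold
  expect_equal(sqrt(sum((c(200, 150, 160) - c(0, 255, 0))^2)), 276.8,
               tolerance = 0.01)
  # a pixel at the mean color always survives; infinite threshold keeps all
  all_kept <- artifact_filter(tps, img, threshold = Inf)
  expect_identical(nrow(all_kept$P), nrow(tps$P))
  expect_error(artifact_filter(tps, img, threshold = -1), "threshold")
})

test_that("thumbnail pixels map to covering tile indices hierarchically", {
  # origin maps to tile (0,0) at any level
  P0 <- cbind(x = 0L, y = 0L)
  t0 <- map_thumb_to_tiles(P0, 64, 8)
  expect_identical(c(t0$tile_ix, t0$tile_iy), c(0L, 0L))
  # worked example: thumb (10,20) at ds 64 -> base (640,1280); tile span
  # 512*8 = 4096 so both coordinates floor to tile (0,0)
  t1 <- map_thumb_to_tiles(cbind(x = 10L, y = 20L), 64, 8)
  expect_identical(c(t1$tile_ix, t1$tile_iy), c(0L, 0L))
  # two pixels in one footprint collapse; output is sorted row-major
  t2 <- map_thumb_to_tiles(cbind(x = c(70, 3, 4), y = c(80, 2, 2)), 64, 8)
  expect_identical(nrow(t2), 2L)
  expect_identical(t2$tile_ix, c(0L, 1L))
  expect_identical(t2$x, c(0L, 512L))
  expect_error(map_thumb_to_tiles(P0, 8, 64), "coarser")
})

test_that("tile acceptance pads borders and applies the tissue threshold", {
  cutoff <- 0.9
  tissue <- array(0.6, c(512, 512, 3))
  res <- accept_tile(tissue, cutoff, tissue_threshold = 0.3)
  expect_identical(res$status, "accepted")
  expect_equal(res$tissue_fraction, 1.0)
  bg_tile <- array(1, c(512, 512, 3))
  expect_identical(accept_tile(bg_tile, cutoff)$status, "rejected")
  # a 300-wide border tile, half tissue: fraction (0.5*300*512)/512^2 < 0.3
  half <- array(1, c(512, 300, 3))
  half[1:256, , ] <- 0.6
  res2 <- accept_tile(half, cutoff, tissue_threshold = 0.3,
                      background_color = c(1, 1, 1))
  expect_identical(dim(res2$tile), c(512L, 512L, 3L))
  expect_equal(res2$tissue_fraction, 0.5 * 300 * 512 / 512^2, tolerance = 1e-9)
  expect_identical(res2$status, "rejected")
  expect_error(accept_tile(array(0, c(600, 512, 3)), cutoff), "oversized")
})

test_that("fraction sampling activates only above the tile limit", {
  tiles <- data.frame(x = 1:100, y = 1:100)
  s <- sample_fraction(tiles, fraction = 0.6, limit = 50, seed = 3)
  expect_identical(nrow(s), 60L)
  expect_identical(sample_fraction(tiles[1:40, ], 0.6, 50, 3), tiles[1:40, ])
  expect_identical(sample_fraction(tiles, 0.6, 50, 3), s)
  expect_error(sample_fraction(tiles, 0, 50, 1), "fraction")
})

test_that("cluster sampling caps draws per k-means cluster", {
  set.seed(5)
  # three well-separated clusters of sizes 25/10/5
  emb <- rbind(matrix(rnorm(25 * 2), 25, 2),
               matrix(rnorm(10 * 2, mean = 30), 10, 2),
               matrix(rnorm(5 * 2, mean = -30), 5, 2))
  tiles <- data.frame(id = 1:40)
  cs <- cluster_sample(emb, tiles, k = 3, n_per_cluster = 20, seed = 9)
  expect_identical(nrow(cs$tiles), 35L)         # 20 + 10 + 5
  expect_identical(sort(as.vector(table(cs$assignment))), c(5L, 10L, 25L))
  # k = 1 degenerates to a plain uniform sample with the cap
  cs1 <- cluster_sample(emb, tiles, k = 1, n_per_cluster = 20, seed = 9)
  expect_identical(nrow(cs1$tiles), 20L)
  # determinism and clamping
  cs2 <- cluster_sample(emb, tiles, k = 3, n_per_cluster = 20, seed = 9)
  expect_identical(cs$tiles, cs2$tiles)
  expect_warning(cluster_sample(emb[1:2, ], tiles[1:2, , drop = FALSE], k = 4),
                 "clamped")
})

test_that("parent tiles expand to an exact child tiling", {
  ch <- expand_to_children(list(x = 0L, y = 0L), parent_downsample = 2,
                           child_downsample = 1)
  expect_identical(nrow(ch), 4L)
  expect_setequal(paste(ch$x, ch$y), c("0 0", "0 512", "512 0", "512 512"))
  # r = 1 is the identity
  ch1 <- expand_to_children(list(x = 1024L, y = 512L), 2, 2)
  expect_identical(nrow(ch1), 1L)
  expect_identical(c(ch1$x, ch1$y), c(1024L, 512L))
  # base-coordinate footprints of children exactly cover the parent
  parent <- list(x = 512L, y = 1024L)
  ch2 <- expand_to_children(parent, 4, 2)
  base_cover <- unlist(lapply(seq_len(nrow(ch2)), function(i)
    outer(ch2$x[i] * 2 + 0:1023, (ch2$y[i] * 2 + 0:1023) * 1e7, `+`)))
  expect_identical(length(base_cover), length(unique(base_cover)))
  expect_identical(length(base_cover), 2048L * 2048L)
  expect_error(expand_to_children(parent, 3, 2), "integer")
})

test_that("children map back to their parent's footprint", {
  parent <- list(x = 1024L, y = 1536L)
  ch <- expand_to_children(parent, 4, 2)
  # each child's top-left, re-expressed at the parent level, lies inside
  # the parent tile's half-open footprint
  px <- ch$x * 2 / 4; py <- ch$y * 2 / 4
  expect_true(all(px >= parent$x & px < parent$x + 512))
  expect_true(all(py >= parent$y & py < parent$y + 512))
})

test_that("augmentations are seeded, invertible where expected, and bounded", {
  set.seed(2)
  tile <- array(runif(24 * 24 * 3, 0.2, 0.9), c(24, 24, 3))
  id_params <- list(hed_alpha = rep(1, 3), hed_beta = rep(0, 3),
                    noise_sd = 0, rotation = 0, flip_h = FALSE, flip_v = FALSE)
  expect_equal(apply_augmentation(tile, id_params), tile, tolerance = 1e-12)
  flip <- utils::modifyList(id_params, list(flip_h = TRUE))
  expect_identical(apply_augmentation(apply_augmentation(tile, flip), flip),
                   tile)
  rot <- utils::modifyList(id_params, list(rotation = 90))
  r4 <- Reduce(function(img, i) apply_augmentation(img, rot), 1:4,
               accumulate = FALSE, init = tile)
  expect_identical(r4, tile)
  a1 <- augment_tile(tile, seed = 33)
  a2 <- augment_tile(tile, seed = 33)
  expect_identical(a1, a2)
  expect_length(a1, 2)
  for (a in a1) {
    expect_identical(dim(a), dim(tile))
    expect_true(all(a >= 0 & a <= 1))
    expect_false(identical(a, tile))
  }
})

test_that("the prep pipeline accepts tiles only where tissue lies", {
  cfg <- slide_gen_config(base_size = 2048L, n_levels = 3L, n_blobs = 3L,
                          slide_id = "cs", label = 1L)
  sl <- gen_slide(cfg, seed = 4)
  pc <- default_config(); pc$magnification <- "20x"; pc$encoder_d <- 8L
  res <- suppressWarnings(prep_slide(sl$pyramid, pc, reference_encoder(d = 8L, seed = 1L)))
  acc <- res$manifest[res$manifest$status != "rejected", ]
  expect_gt(nrow(acc), 0)
  for (i in seq_len(nrow(acc))) {
    xs <- acc$x[i] + 1:512; ys <- acc$y[i] + 1:512
    xs <- xs[xs <= 2048]; ys <- ys[ys <= 2048]
    expect_gt(sum(sl$truth$tissue[ys, xs]), 0)
  }
})
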