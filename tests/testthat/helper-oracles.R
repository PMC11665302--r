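# Independent oracles used by the tests. Everything here is written with
# scalar loops and none of the package's linear-algebra paths, so agreement
# is evidence, not tautology.

# Hand-unrolled forward pass: every sum written out element by element.
scalar_forward <- function(variant, H, V, w, U, b, slope = 0.01) {
  n <- nrow(H); d <- ncol(H); D <- nrow(V); C <- nrow(U)
  act <- if (variant == "admil") {
    function(x) if (x > 0) x else slope * x
  } else tanh
  e <- numeric(n)
  for (i in 1:n) {
    for (k in 1:D) {
      s <- 0
      for (j in 1:d) s <- s + V[k, j] * H[i, j]
      e[i] <- e[i] + w[k] * act(s)
    }
  }
  a <- numeric(n)
  denom <- 0
  for (i in 1:n) denom <- denom + exp(e[i] - max(e))
  for (i in 1:n) a[i] <- exp(e[i] - max(e)) / denom
  if (variant == "amil") {
    z <- numeric(d)
    for (j in 1:d) for (i in 1:n) z[j] <- z[j] + a[i] * H[i, j]
    bag_logits <- numeric(C)
    for (c in 1:C) {
      bag_logits[c] <- b[c]
      for (j in 1:d) bag_logits[c] <- bag_logits[c] + U[c, j] * z[j]
    }
    patch_logits <- NULL
  } else {
    patch_logits <- matrix(0, n, C)
    for (i in 1:n) for (c in 1:C) {
      patch_logits[i, c] <- b[c]
      for (j in 1:d)
        patch_logits[i, c] <- patch_logits[i, c] + U[c, j] * a[i] * H[i, j]
    }
    bag_logits <- numeric(C)
    for (c in 1:C) for (i in 1:n) bag_logits[c] <- bag_logits[c] + patch_logits[i, c]
  }
  pdenom <- 0
  for (c in 1:C) pdenom <- pdenom + exp(bag_logits[c] - max(bag_logits))
  probs <- exp(bag_logits - max(bag_logits)) / pdenom
  list(attention = a, bag_logits = bag_logits, patch_logits = patch_logits,
       class_probabilities = probs)
}

# Mean pooling followed by the bag classifier: the degenerate (w = 0) AMIL.
mean_pool_forward <- function(H, U, b) {
  pooled <- numeric(ncol(H))
  for (j in seq_len(ncol(H))) pooled[j] <- mean(H[, j])
  logits <- drop(U %*% pooled) + b
  exp(logits - max(logits)) / sum(exp(logits - max(logits)))
}

# All-pairs concordance count (ties at half credit).
brute_force_auc <- function(scores, labels) {
  pos <- which(labels == 1); neg <- which(labels == 0)
  total <- 0
  for (i in pos) for (j in neg) {
    total <- total + if (scores[i] > scores[j]) 1
      else if (scores[i] == scores[j]) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Independent Otsu threshold: exhaustive minimization of within-class
# variance over 256 candidate cuts.
brute_force_otsu <- function(gray) {
  breaks <- seq(0, 1, length.out = 257)
  mids <- (breaks[-1] + breaks[-257]) / 2
  counts <- tabulate(findInterval(gray, breaks, rightmost.closed = TRUE), 256)
  best <- Inf; thr <- NA
  for (t in 1:255) {
    w0 <- sum(counts[1:t]); w1 <- sum(counts[(t + 1):256])
    if (w0 == 0 || w1 == 0) next
    m0 <- sum(counts[1:t] * mids[1:t]) / w0
    m1 <- sum(counts[(t + 1):256] * mids[(t + 1):256]) / w1
    v0 <- sum(counts[1:t] * (mids[1:t] - m0)^2) / w0
    v1 <- sum(counts[(t + 1):256] * (mids[(t + 1):256] - m1)^2) / w1
    wcv <- w0 * v0 + w1 * v1
    if (wcv < best) { best <- wcv; thr <- breaks[t + 1] }
  }
  thr
}

# Morphological closing with a 3x3 box via shift-based dilation and erosion.
brute_force_close3 <- function(mask) {
  shift_or <- function(m, f) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    for (dy in -1:1) for (dx in -1:1) {
      rs <- max(1, 1 + dy):min(nrow(m), nrow(m) + dy)
      cs <- max(1, 1 + dx):min(ncol(m), ncol(m) + dx)
      out[rs, cs] <- f(out[rs, cs], m[rs - dy, cs - dx])
    }
    out
  }
  dil <- shift_or(mask, `|`)
  ero <- matrix(TRUE, nrow(mask), ncol(mask))
  for (dy in -1:1) for (dx in -1:1) {
    shifted <- matrix(TRUE, nrow(mask), ncol(mask))  # border: pad with TRUE
    rs <- max(1, 1 + dy):min(nrow(dil), nrow(dil) + dy)
    cs <- max(1, 1 + dx):min(ncol(dil), ncol(dil) + dx)
    shifted[rs, cs] <- dil[rs - dy, cs - dx]
    ero <- ero & shifted
  }
  ero
}

# Pixel-by-pixel re-implementation of the accepted-tile count for a
# synthetic slide, sharing no code with prep_slide().
brute_force_tile_count <- function(pyramid, config) {
  thumb <- pyramid_thumbnail(pyramid)
  thumb_ds <- pyramid$downsamples[length(pyramid$levels)]
  gray <- (thumb[, , 1] + thumb[, , 2] + thumb[, , 3]) / 3
  thr <- brute_force_otsu(gray)
  mask <- brute_force_close3(gray < thr)
  # artifact filter on the tissue pixel colors
  idx <- which(mask, arr.ind = TRUE)
  cols <- cbind(thumb[, , 1][mask], thumb[, , 2][mask], thumb[, , 3][mask]) * 255
  mean_col <- colMeans(cols)
  keep <- sqrt((cols[, 1] - mean_col[1])^2 + (cols[, 2] - mean_col[2])^2 +
                 (cols[, 3] - mean_col[3])^2) <= config$color_threshold
  idx <- idx[keep, , drop = FALSE]
  if (nrow(idx) == 0) return(0L)
  target_ds <- c("20x" = 1, "10x" = 2, "5x" = 4)[[config$magnification]]
  lvl <- match(target_ds, pyramid$downsamples)
  span <- config$tile_px * target_ds
  tiles <- unique(cbind(floor((idx[, 2] - 1) * thumb_ds / span),
                        floor((idx[, 1] - 1) * thumb_ds / span)))
  img <- pyramid$levels[[lvl]]
  lg <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
  accepted <- 0L
  for (r in seq_len(nrow(tiles))) {
    x0 <- tiles[r, 1] * config$tile_px; y0 <- tiles[r, 2] * config$tile_px
    if (x0 >= ncol(lg) || y0 >= nrow(lg)) next
    n_tissue <- 0L
    for (yy in (y0 + 1):min(y0 + config$tile_px, nrow(lg))) {
      row <- lg[yy, (x0 + 1):min(x0 + config$tile_px, ncol(lg))]
      n_tissue <- n_tissue + sum(row < thr)   # padding is background: no tissue
    }
    if (n_tissue / config$tile_px^2 >= config$tissue_threshold)
      accepted <- accepted + 1L
  }
  accepted
}

# quick random bag for property tests
random_bag <- function(n, d, label = sample(0:1, 1)) {
  mil_bag(matrix(rnorm(n * d), n, d), label)
}

mask_iou <- function(a, b) sum(a & b) / sum(a | b)
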