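#' Reference tile encoder
#'
#' A deterministic, self-contained encoder mapping 512 x 512 RGB tiles to
#' d-dimensional embeddings: the tile is reduced to a feature vector of
#' pooled image statistics (a coarse grid of per-channel block means plus
#' global channel means and standard deviations), which is then passed
#' through a fixed seeded random projection. It is not a histology encoder;
#' it exists so the full pipeline is runnable and testable end to end.
#' Pretrained encoders plug in through the same contract: any object with
#' an `encode(tiles)` function and a `d` field.
#'
#' @param d embedding dimension (1024 matches common histology encoders).
#' @param seed seed for the projection weights; a given `(d, seed)` always
#'   yields the same encoder.
#' @param grid side of the pooling grid (features = 3 * grid^2 + 6).
#' @return object of class `mil_encoder` with fields `d`, `name`, `encode`.
#' @export
reference_encoder <- function(d = 1024L, seed = 42L, grid = 8L) {
  n_feat <- 3L * grid^2 + 6L
  W <- with_seed(seed, matrix(rnorm(d * n_feat, sd = 1 / sqrt(n_feat)),
                              as.integer(d), n_feat))
  encode_one <- function(tile) {
    feats <- c(vapply(1:3, function(c) block_means(tile[, , c], grid),
                      numeric(grid^2)),
               vapply(1:3, function(c) mean(tile[, , c]), numeric(1)),
               vapply(1:3, function(c) stats::sd(tile[, , c]), numeric(1)))
    drop(W %*% (feats - 0.5))
  }
  structure(list(d = as.integer(d),
                 name = sprintf("reference-pooled-projection-%d", seed),
                 encode_one = encode_one),
            class = "mil_encoder")
}

# mean of each cell of a g x g partition of a matrix
block_means <- function(m, g) {
  h <- nrow(m); w <- ncol(m)
  ri <- ceiling(seq_len(h) / (h / g))
  ci <- ceiling(seq_len(w) / (w / g))
  as.numeric(tapply(m, list(ri[row(m)], ci[col(m)]), mean))
}

#' @export
print.mil_encoder <- function(x, ...) {
  cat(sprintf("<mil_encoder '%s': d = %d>\n", x$name, x$d))
  invisible(x)
}

#' Encode a list of tiles into an embedding matrix
#'
#' Streams through the tiles in batches so peak memory is bounded by the
#' batch, not the slide.
#'
#' @param tiles list of RGB arrays (all the same size).
#' @param encoder a `mil_encoder` (see [reference_encoder()]).
#' @param batch_size tiles per batch.
#' @return numeric matrix, one embedding per row (n x d).
#' @export
encode_tiles <- function(tiles, encoder, batch_size = 32L) {
  check_that(inherits(encoder, "mil_encoder"), "not a mil_encoder")
  n <- length(tiles)
  out <- matrix(NA_real_, n, encoder$d)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    for (k in i:j) {
      dm <- dim(tiles[[k]])
      check_that(length(dm) == 3L && dm[3L] == 3L,
                 "tile %d is not an RGB array", k)
      out[k, ] <- encoder$encode_one(tiles[[k]])
    }
    i <- j + 1L
  }
  out
}

#' A slide's embeddings plus metadata, ready for the store
#'
#' @param slide_id slide identifier (HDF5 group name).
#' @param embeddings n x d matrix of original-tile embeddings.
#' @param aug_embeddings optional 2n x d matrix of augmented-tile
#'   embeddings; row `2(i-1)+j` is the j-th augmentation of tile i.
#' @param coords n x 3 integer matrix `(magnification code, x, y)`.
#' @param label slide label (0/1).
#' @return object of class `slide_group`.
#' @export
slide_group <- function(slide_id, embeddings, coords, label,
                        aug_embeddings = NULL) {
  embeddings <- as.matrix(embeddings)
  coords <- as.matrix(coords)
  check_that(nrow(coords) == nrow(embeddings),
             "coords rows must match embedding rows")
  check_that(ncol(coords) == 3L, "coords must have 3 columns (level, x, y)")
  if (!is.null(aug_embeddings)) {
    aug_embeddings <- as.matrix(aug_embeddings)
    check_that(nrow(aug_embeddings) == 2L * nrow(embeddings),
               "aug_embeddings must hold 2 rows per original tile")
    check_that(ncol(aug_embeddings) == ncol(embeddings),
               "aug_embeddings dimension mismatch")
  }
  structure(list(slide_id = slide_id, embeddings = embeddings,
                 aug_embeddings = aug_embeddings, coords = coords,
                 label = as.integer(label)),
            class = "slide_group")
}

#' Write slide groups to an HDF5 embedding store
#'
#' Layout (store dialect, `schema = 1` root attribute): one HDF5 group per
#' slide, holding float64 datasets `embeddings` (n x d) and, when present,
#' `aug_embeddings` (2n x d), an int `coords` dataset (n x 3), and scalar
#' attributes `label`, `d`, `encoder_name`. Datasets are chunked by row and
#' compressed. The file is written to a temporary sibling and atomically
#' renamed, so a failed write never leaves a half-valid store.
#'
#' @param path output `.h5` path.
#' @param groups list of [slide_group()] objects (unique slide ids).
#' @param encoder_name recorded on each group.
#' @return `path`, invisibly.
#' @export
write_store <- function(path, groups, encoder_name = "unknown") {
  ids <- vapply(groups, function(g) g$slide_id, character(1))
  check_that(!anyDuplicated(ids), "duplicate slide_id in groups: %s",
             paste(ids[duplicated(ids)], collapse = ", "))
  tmp <- paste0(path, ".tmp")
  if (file.exists(tmp)) file.remove(tmp)
  ok <- FALSE
  on.exit({
    rhdf5::h5closeAll()
    if (!ok && file.exists(tmp)) file.remove(tmp)
  })
  rhdf5::h5createFile(tmp)
  fid <- rhdf5::H5Fopen(tmp)
  rhdf5::h5writeAttribute(1L, fid, "schema")
  rhdf5::H5Fclose(fid)
  for (g in groups) {
    grp <- paste0("/", g$slide_id)
    rhdf5::h5createGroup(tmp, grp)
    write_chunked(tmp, paste0(grp, "/embeddings"), g$embeddings)
    if (!is.null(g$aug_embeddings))
      write_chunked(tmp, paste0(grp, "/aug_embeddings"), g$aug_embeddings)
    coords <- g$coords; storage.mode(coords) <- "integer"
    rhdf5::h5write(coords, tmp, paste0(grp, "/coords"))
    fid <- rhdf5::H5Fopen(tmp)
    gid <- rhdf5::H5Gopen(fid, grp)
    rhdf5::h5writeAttribute(g$label, gid, "label")
    rhdf5::h5writeAttribute(ncol(g$embeddings), gid, "d")
    rhdf5::h5writeAttribute(encoder_name, gid, "encoder_name")
    rhdf5::H5Gclose(gid)
    rhdf5::H5Fclose(fid)
  }
  rhdf5::h5closeAll()
  ok <- TRUE
  file.rename(tmp, path)
  invisible(path)
}

write_chunked <- function(file, name, mat) {
  if (nrow(mat) == 0L) {
    rhdf5::h5write(mat, file, name)
    return(invisible())
  }
  rhdf5::h5createDataset(file, name, dims = dim(mat),
                         storage.mode = "double",
                         chunk = c(1L, ncol(mat)), level = 4L)
  rhdf5::h5write(mat, file, name)
}

#' List the slide ids in a store
#' @param path HDF5 store path.
#' @return character vector of slide ids.
#' @export
store_slide_ids <- function(path) {
  info <- rhdf5::h5ls(path, recursive = FALSE)
  info$name[info$otype == "H5I_GROUP"]
}

#' Read bags back from an HDF5 embedding store
#'
#' @param path store path written by [write_store()].
#' @param slide_ids slides to read (default: all, in store order).
#' @param include_augmented fold the augmented embeddings into each bag as
#'   extra instances (training mode, bag size 3n) or leave them out
#'   (evaluation mode, bag size n).
#' @return list of `mil_bag`, named by slide id.
#' @export
read_store <- function(path, slide_ids = NULL, include_augmented = FALSE) {
  check_that(file.exists(path), "no store at '%s'", path)
  available <- store_slide_ids(path)
  if (is.null(slide_ids)) slide_ids <- available
  missing <- setdiff(slide_ids, available)
  check_that(length(missing) == 0L,
             "unknown slide id(s) %s; store has: %s",
             paste(missing, collapse = ", "), paste(available, collapse = ", "))
  on.exit(rhdf5::h5closeAll())
  bags <- lapply(slide_ids, function(id) {
    grp <- paste0("/", id)
    emb <- as.matrix(rhdf5::h5read(path, paste0(grp, "/embeddings")))
    coords <- as.matrix(rhdf5::h5read(path, paste0(grp, "/coords")))
    attrs <- rhdf5::h5readAttributes(path, grp)
    if (include_augmented) {
      objs <- rhdf5::h5ls(path)
      has_aug <- any(objs$group == grp & objs$name == "aug_embeddings")
      if (has_aug) {
        aug <- as.matrix(rhdf5::h5read(path, paste0(grp, "/aug_embeddings")))
        emb <- rbind(emb, aug)
        coords <- rbind(coords, coords[rep(seq_len(nrow(coords)), each = 2L), ,
                                       drop = FALSE])
      }
    }
    mil_bag(emb, label = as.integer(attrs$label), tile_coords = coords,
            slide_id = id)
  })
  names(bags) <- slide_ids
  bags
}

#' Emit synthetic bags directly as an embedding store
#'
#' Convenience bridge from the bag generator to the store: each synthetic
#' bag becomes a slide group with dummy coordinates.
#'
#' @param bags list of `mil_bag` from [gen_bags()].
#' @param path output store path.
#' @return `path`, invisibly.
#' @export
bags_to_store <- function(bags, path) {
  groups <- lapply(seq_along(bags), function(i) {
    b <- bags[[i]]
    coords <- if (is.null(b$tile_coords)) {
      cbind(level = rep(0L, b$n), x = seq_len(b$n) - 1L, y = rep(0L, b$n))
    } else b$tile_coords
    slide_group(b$slide_id %||% sprintf("bag_%03d", i), b$instances, coords,
                b$label)
  })
  write_store(path, groups, encoder_name = "synthetic")
}
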