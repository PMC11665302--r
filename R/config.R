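#' Default pipeline configuration
#'
#' Every threshold the preprocessing narrative leaves open is surfaced here
#' as a key with its default: the artifact color-distance threshold (8-bit
#' RGB units), the minimum tile tissue fraction, the per-slide tile-count
#' limit that triggers 60% fraction sampling, the k of the k-means cluster
#' sampler and its per-cluster cap, the morphological closing size, the
#' number of augmentations per tile, and the encoder settings.
#'
#' @return named list of configuration values.
#' @export
default_config <- function() {
  list(magnification = "5x",       # target tile level: 5x, 10x or 20x
       tile_px = 512L,
       tissue_threshold = 0.3,     # min tile tissue fraction
       color_threshold = 100,      # artifact filter, 8-bit RGB distance
       sample_fraction = 0.6,      # fraction kept above tile_limit
       tile_limit = 1000L,         # per-slide count triggering sampling
       kmeans_k = 4L,              # clusters for cross-magnification sampling
       tiles_per_cluster = 20L,    # per-cluster cap
       closing_size = 3L,          # closing structuring element side
       n_augment = 2L,             # augmentations per tile
       encoder_d = 1024L,          # embedding length
       encoder_seed = 42L,
       seed = 1L)
}

# magnification tag -> downsample factor of the ladder (20x is the base)
MAG_LADDER <- c("20x" = 1, "10x" = 2, "5x" = 4)

#' Read / write a flat key-value config file
#'
#' Format: one `key = value` pair per line, `#` comments allowed. Values are
#' parsed as numbers when possible, otherwise kept as strings; unknown keys
#' error, missing keys fall back to [default_config()].
#'
#' @param path config file path.
#' @return the merged configuration list.
#' @export
read_config <- function(path) {
  base <- default_config()
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    check_that(length(kv) == 2L, "malformed config line: '%s'", ln)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    check_that(key %in% names(base), "unknown config key '%s'", key)
    num <- suppressWarnings(as.numeric(val))
    base[[key]] <- if (is.na(num)) val else {
      if (is.integer(default_config()[[key]])) as.integer(num) else num
    }
  }
  base
}

#' @rdname read_config
#' @param config configuration list to write.
#' @export
write_config <- function(config, path) {
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, as.character, character(1))), path)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record emitted next to every pipeline artifact: the config
#' snapshot, seeds, input/output paths, package version and a timestamp.
#'
#' @param config configuration list.
#' @param inputs,outputs character vectors of paths.
#' @return manifest list.
#' @export
run_manifest <- function(config, inputs, outputs) {
  list(config = config, seed = config$seed, inputs = inputs,
       outputs = outputs,
       package_version = as.character(utils::packageVersion("wsimil")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}
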