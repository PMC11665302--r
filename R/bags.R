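#' Construct a MIL bag
#'
#' A bag is one slide's worth of instances: an \eqn{n \times d} matrix of
#' tile embedding vectors together with a single binary slide-level label.
#' Instance-level labels are latent in real data; the synthetic generator
#' attaches them for evaluation only (they are never seen by training code).
#'
#' @param instances numeric matrix, one row per instance (tile embedding).
#' @param label bag label, 0 or 1.
#' @param instance_labels optional 0/1 vector of length `nrow(instances)`;
#'   ground-truth witness indicators from a synthetic generator.
#' @param tile_coords optional matrix/data.frame with one row per instance
#'   giving `(level, x, y)` of the source tile.
#' @param slide_id optional slide identifier string.
#' @return an object of class `mil_bag`.
#' @export
#' @examples
#' b <- mil_bag(matrix(rnorm(12), 3, 4), label = 1)
#' b$n
mil_bag <- function(instances, label, instance_labels = NULL,
                    tile_coords = NULL, slide_id = NULL) {
  instances <- as.matrix(instances)
  storage.mode(instances) <- "double"
  check_that(nrow(instances) >= 1L, "a bag needs at least one instance")
  check_that(all(is.finite(instances)), "bag instances must be finite")
  label <- as.integer(label)
  check_that(length(label) == 1L && label %in% c(0L, 1L),
             "bag label must be 0 or 1")
  if (!is.null(instance_labels)) {
    instance_labels <- as.integer(instance_labels)
    check_that(length(instance_labels) == nrow(instances),
               "instance_labels length (%d) != number of instances (%d)",
               length(instance_labels), nrow(instances))
    check_that(all(instance_labels %in% c(0L, 1L)),
               "instance_labels must be 0/1")
  }
  if (!is.null(tile_coords)) {
    tile_coords <- as.matrix(tile_coords)
    check_that(nrow(tile_coords) == nrow(instances),
               "tile_coords rows (%d) != number of instances (%d)",
               nrow(tile_coords), nrow(instances))
  }
  structure(
    list(instances = instances, label = label,
         instance_labels = instance_labels, tile_coords = tile_coords,
         slide_id = slide_id, n = nrow(instances), d = ncol(instances)),
    class = "mil_bag")
}

#' @export
print.mil_bag <- function(x, ...) {
  cat(sprintf("<mil_bag%s: %d instances x %d dims, label = %d%s>\n",
              if (is.null(x$slide_id)) "" else paste0(" ", x$slide_id),
              x$n, x$d, x$label,
              if (is.null(x$instance_labels)) ""
              else sprintf(", %d witness(es)", sum(x$instance_labels))))
  invisible(x)
}

# label vector of a bag list
bag_labels <- function(bags) vapply(bags, function(b) b$label, integer(1))
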