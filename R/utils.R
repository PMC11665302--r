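#' Numerically stable softmax
#'
#' @param x numeric vector of finite logits.
#' @return vector of the same length, positive, summing to 1.
#' @keywords internal
#' @noRd
softmax <- function(x) {
  if (length(x) == 0L) stop("softmax of an empty vector is undefined")
  if (any(!is.finite(x))) stop("softmax requires finite logits")
  z <- exp(x - max(x))
  z / sum(z)
}

#' Logistic (sigmoid) function
#' @keywords internal
#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))

#' Shannon entropy (nats) of a probability vector
#' @keywords internal
#' @noRd
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# stopifnot-style check with a formatted message
check_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
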