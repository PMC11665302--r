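#' Shannon entropy of an attention distribution
#'
#' Measures how spread out a bag's attention is: low entropy means the model
#' concentrates on few instances (sparse, localized attention), high entropy
#' means attention is spread across the bag. Normalization by `log(n)` maps
#' the value to `[0, 1]` so bags of different sizes are comparable.
#'
#' @param attention attention weight vector (simplex).
#' @param normalize divide by `log(n)`.
#' @return scalar entropy (nats, or fraction of maximum if normalized).
#' @export
attention_entropy <- function(attention, normalize = TRUE) {
  check_that(length(attention) >= 1L && all(attention >= 0),
             "attention weights must be nonnegative")
  h <- shannon_entropy(attention)
  if (normalize && length(attention) > 1L) h <- h / log(length(attention))
  h
}

#' Witness localization rate of a trained model
#'
#' For every positive bag carrying ground-truth instance labels (synthetic
#' fixtures), checks whether the model places a higher mean attention weight
#' on witness instances than on background instances. Returns the fraction
#' of positive bags where it does — a direct, label-free-training test of
#' whether attention finds the instances that make the bag positive.
#'
#' @param model a trained `mil_model`.
#' @param bags list of `mil_bag` with `instance_labels`.
#' @return list with `rate`, `n_positive`, and the per-bag logical vector
#'   `localized`.
#' @export
witness_localization <- function(model, bags) {
  pos <- Filter(function(b) b$label == 1L && !is.null(b$instance_labels) &&
                  any(b$instance_labels == 1L) && any(b$instance_labels == 0L),
                bags)
  check_that(length(pos) > 0L,
             "no positive bags with instance labels available")
  localized <- vapply(pos, function(b) {
    a <- mil_forward(model, b)$attention
    mean(a[b$instance_labels == 1L]) > mean(a[b$instance_labels == 0L])
  }, logical(1))
  list(rate = mean(localized), n_positive = length(pos),
       localized = localized)
}
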