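#' Attention logits for a bag of embeddings
#'
#' Scores every instance independently with the two-layer attention scorer
#' \eqn{\psi_a(h_i) = w^\top \mathrm{act}(V h_i^\top)}, where `act` is either
#' `tanh` (AMIL-style attention) or `leaky_relu` (AdMIL-style attention).
#' Instances are treated as sequentially independent, so the score of one
#' instance never depends on the others.
#'
#' @param H numeric matrix, \eqn{n \times d}, one embedding per row.
#' @param V weight matrix, \eqn{D \times d}.
#' @param w weight vector, length \eqn{D}.
#' @param activation `"tanh"` or `"leaky_relu"`.
#' @param slope negative slope of the LeakyReLU; ignored for tanh.
#' @return numeric vector of n unnormalized attention logits.
#' @seealso [attention_normalize()] for the softmax that turns logits into
#'   attention weights.
#' @export
attention_logits <- function(H, V, w, activation = c("tanh", "leaky_relu"),
                             slope = 0.01) {
  activation <- match.arg(activation)
  H <- as.matrix(H); V <- as.matrix(V); w <- as.numeric(w)
  check_that(nrow(H) >= 1L, "attention_logits: bag must be non-empty")
  check_that(ncol(V) == ncol(H),
             "attention_logits: V is %dx%d but embeddings have length %d",
             nrow(V), ncol(V), ncol(H))
  check_that(length(w) == nrow(V),
             "attention_logits: w has length %d but V has %d rows",
             length(w), nrow(V))
  S <- H %*% t(V)                       # n x D pre-activations
  Tact <- activation_fun(activation)(S, slope)
  drop(Tact %*% w)
}

activation_fun <- function(activation) {
  switch(activation,
         tanh = function(s, slope) tanh(s),
         leaky_relu = function(s, slope) ifelse(s > 0, s, slope * s),
         stop("unknown activation: ", activation))
}

activation_grad <- function(activation) {
  switch(activation,
         tanh = function(s, t, slope) 1 - t^2,
         leaky_relu = function(s, t, slope) ifelse(s > 0, 1, slope),
         stop("unknown activation: ", activation))
}

#' Normalize attention logits to attention weights
#'
#' Softmax over the instance axis: the weights are positive and sum to one,
#' making the downstream weighted sum a permutation-invariant MIL pooling
#' operator.
#'
#' @param logits numeric vector of finite attention logits.
#' @return attention weights on the simplex.
#' @export
attention_normalize <- function(logits) {
  check_that(length(logits) >= 1L, "attention_normalize: empty input")
  softmax(as.numeric(logits))
}

#' Build a MIL model
#'
#' Constructs one of three architectures. All three share the embedding-level
#' attention scorer \eqn{\psi_a} and differ in its activation and in the head:
#' \describe{
#'   \item{`amil`}{tanh attention; the attention-weighted sum of embeddings is
#'     passed through a bag classifier \eqn{\psi_p}.}
#'   \item{`admil`}{LeakyReLU attention; \eqn{\psi_p} is a patch score layer
#'     applied to each attention-scaled embedding \eqn{a_i h_i}, and the
#'     per-patch class logits are summed into the bag logits.}
#'   \item{`admil_tanh`}{the AdMIL additive head with the tanh attention of
#'     AMIL — a hybrid that trades attention sparsity for coverage.}
#' }
#'
#' @param variant `"amil"`, `"admil"` or `"admil_tanh"`.
#' @param d embedding dimension (1024 for typical histology encoders).
#' @param D attention hidden width.
#' @param C number of classes (2: negative, positive).
#' @param slope LeakyReLU negative slope.
#' @param seed integer seed for the parameter initialization; the same
#'   `(variant, d, seed)` always yields identical parameters.
#' @param init_sd standard deviation of the Gaussian initialization.
#' @return an object of class `mil_model` holding the trainable parameters
#'   `V` (D x d), `w` (D), `U` (C x d), `b` (C).
#' @export
#' @examples
#' m <- mil_model("amil", d = 8, seed = 1)
#' p <- predict(m, mil_bag(matrix(rnorm(40), 5, 8), label = 0))
#' sum(p$attention)  # 1
mil_model <- function(variant = c("amil", "admil", "admil_tanh"),
                      d = 1024L, D = 128L, C = 2L, slope = 0.01,
                      seed = 1L, init_sd = 0.05) {
  variant <- match.arg(variant)
  check_that(d >= 1L && D >= 1L && C >= 2L, "mil_model: invalid dimensions")
  activation <- if (variant == "admil") "leaky_relu" else "tanh"
  params <- with_seed(as.integer(seed), list(
    V = matrix(rnorm(D * d, sd = init_sd), D, d),
    w = rnorm(D, sd = init_sd),
    U = matrix(rnorm(C * d, sd = init_sd), C, d),
    b = numeric(C)))
  structure(
    list(variant = variant, activation = activation, d = as.integer(d),
         D = as.integer(D), C = as.integer(C), slope = slope,
         seed = as.integer(seed), params = params, trained = FALSE),
    class = "mil_model")
}

is_additive <- function(model) model$variant %in% c("admil", "admil_tanh")

#' Forward pass of a MIL model over one bag
#'
#' For AMIL the pooled embedding \eqn{z = \sum_i a_i h_i} goes through the bag
#' classifier; for the additive variants each scaled embedding \eqn{a_i h_i}
#' goes through the patch score layer and the per-patch class logits are
#' summed into the bag logits. Class probabilities are the softmax of the bag
#' logits. The computation is invariant to the ordering of instances.
#'
#' @param model a `mil_model`.
#' @param bag a `mil_bag`, or a bare numeric matrix of embeddings.
#' @return an object of class `mil_prediction`: a list with
#'   `class_probabilities` (length C, sums to 1), `attention` (length n,
#'   simplex), `bag_logits` (length C) and, for additive variants,
#'   `patch_logits` (n x C).
#' @export
mil_forward <- function(model, bag) {
  H <- if (inherits(bag, "mil_bag")) bag$instances else as.matrix(bag)
  check_that(ncol(H) == model$d,
             "bag embedding length %d does not match model d = %d",
             ncol(H), model$d)
  p <- model$params
  e <- attention_logits(H, p$V, p$w, model$activation, model$slope)
  a <- attention_normalize(e)
  z <- drop(crossprod(H, a))            # d-vector, sum_i a_i h_i
  if (is_additive(model)) {
    # psi_p(a_i h_i) = U (a_i h_i) + b per patch; bag logits are their sum
    patch_logits <- (a * H) %*% t(p$U) +
      matrix(p$b, nrow(H), model$C, byrow = TRUE)
    bag_logits <- colSums(patch_logits)
  } else {
    patch_logits <- NULL
    bag_logits <- drop(p$U %*% z) + p$b
  }
  structure(
    list(class_probabilities = softmax(bag_logits), attention = a,
         bag_logits = bag_logits, patch_logits = patch_logits,
         pooled = z, variant = model$variant),
    class = "mil_prediction")
}

#' @export
print.mil_prediction <- function(x, ...) {
  cat(sprintf("<mil_prediction (%s): P(positive) = %.4f over %d instances>\n",
              x$variant, x$class_probabilities[2L], length(x$attention)))
  invisible(x)
}

#' AMIL forward pass
#'
#' Thin wrapper over [mil_forward()] that insists on the `amil` variant.
#' @inheritParams mil_forward
#' @return a `mil_prediction` without `patch_logits`.
#' @export
amil_forward <- function(model, bag) {
  check_that(model$variant == "amil",
             "amil_forward called with variant '%s'", model$variant)
  mil_forward(model, bag)
}

#' Additive MIL forward pass
#'
#' Thin wrapper over [mil_forward()] that insists on an additive variant
#' (`admil` or `admil_tanh`), whose predictions carry per-patch class logits.
#' @inheritParams mil_forward
#' @return a `mil_prediction` with `patch_logits`.
#' @export
admil_forward <- function(model, bag) {
  check_that(is_additive(model),
             "admil_forward called with variant '%s'", model$variant)
  mil_forward(model, bag)
}

#' Bound per-patch contributions to (0, 1)
#'
#' Passes additive-MIL patch logits through the logistic function, giving a
#' bounded contribution score per patch and class. For the positive class a
#' score above 0.5 is excitatory (pushes the bag toward positive) and a score
#' of 0.5 or below is inhibitory.
#'
#' @param patch_logits numeric n x C matrix of per-patch class logits.
#' @return a list with `values` (n x C matrix in (0,1)) and `polarity`
#'   (character n-vector, `"excitatory"`/`"inhibitory"`, judged on the
#'   positive class, ties at 0.5 inhibitory).
#' @export
bound_contributions <- function(patch_logits) {
  patch_logits <- as.matrix(patch_logits)
  check_that(all(is.finite(patch_logits)),
             "bound_contributions: logits must be finite")
  values <- sigmoid(patch_logits)
  polarity <- ifelse(values[, ncol(values)] > 0.5, "excitatory", "inhibitory")
  list(values = values, polarity = polarity)
}

#' @export
print.mil_model <- function(x, ...) {
  cat(sprintf("<mil_model '%s': d = %d, attention width D = %d (%s), C = %d%s>\n",
              x$variant, x$d, x$D, x$activation, x$C,
              if (isTRUE(x$trained)) ", trained" else ", untrained"))
  invisible(x)
}

#' @export
summary.mil_model <- function(object, ...) {
  npar <- length(unlist(object$params))
  cat(sprintf("MIL model, variant '%s'\n", object$variant))
  cat(sprintf("  attention: psi_a(h) = w' %s(V h), V %dx%d, w %d\n",
              object$activation, object$D, object$d, object$D))
  cat(sprintf("  head: %s, U %dx%d + bias\n",
              if (is_additive(object)) "per-patch score layer (additive)"
              else "bag classifier on pooled embedding",
              object$C, object$d))
  cat(sprintf("  %d trainable parameters; init seed %d\n", npar, object$seed))
  invisible(object)
}

#' @export
coef.mil_model <- function(object, ...) object$params

#' Predict method for MIL models
#'
#' @param object a `mil_model`.
#' @param newdata a `mil_bag`, an embedding matrix, or a list of bags.
#' @param type `"prediction"` for full [mil_forward()] output, `"prob"` for
#'   the positive-class probability only.
#' @param ... unused.
#' @return a `mil_prediction` (or list thereof), or a numeric vector of
#'   positive-class probabilities for `type = "prob"`.
#' @export
predict.mil_model <- function(object, newdata, type = c("prediction", "prob"),
                              ...) {
  type <- match.arg(type)
  single <- inherits(newdata, "mil_bag") || is.matrix(newdata)
  bags <- if (single) list(newdata) else newdata
  preds <- lapply(bags, function(b) mil_forward(object, b))
  if (type == "prob") {
    probs <- vapply(preds, function(p) p$class_probabilities[2L], numeric(1))
    return(if (single) probs[[1L]] else probs)
  }
  if (single) preds[[1L]] else preds
}

#' Save / load a model checkpoint
#'
#' The parameter set is serialized to a single file; a JSON sidecar
#' (`<path>.json`) records variant, dimensions and seed so checkpoints are
#' self-describing.
#'
#' @param model a `mil_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  meta <- list(variant = model$variant, d = model$d, D = model$D,
               C = model$C, seed = model$seed, trained = isTRUE(model$trained),
               package = "wsimil")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  check_that(inherits(model, "mil_model"),
             "'%s' is not a mil_model checkpoint", path)
  model
}
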