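#' Experiment configuration
#'
#' Bundles every knob of the training protocol: an 80/20 train/test split,
#' 5-fold cross-validation on the training set with best-fold model
#' selection, and replication over several split seeds. Optimization is Adam
#' with binary cross-entropy on the positive-class probability, one bag per
#' step.
#'
#' @param variant model variant passed to [mil_model()].
#' @param train_fraction fraction of bags in the training set.
#' @param n_folds number of cross-validation folds.
#' @param n_replicates number of independent runs (distinct split seeds).
#' @param epochs passes over the training bags per fold.
#' @param lr Adam learning rate.
#' @param beta1,beta2,adam_eps Adam moment decay rates and epsilon.
#' @param D,C,slope,init_sd architecture settings, see [mil_model()].
#' @param seed base seed; replicate r uses seed + r - 1 for its split and
#'   training randomness.
#' @param selection `"auc"` (default) picks the fold with the best validation
#'   AUC; `"loss"` picks the lowest final validation loss.
#' @return a list of class `mil_config`.
#' @export
experiment_config <- function(variant = "amil", train_fraction = 0.8,
                              n_folds = 5L, n_replicates = 5L,
                              epochs = 30L, lr = 1e-4,
                              beta1 = 0.9, beta2 = 0.999, adam_eps = 1e-8,
                              D = 128L, C = 2L, slope = 0.01, init_sd = 0.05,
                              seed = 1L, selection = c("auc", "loss")) {
  check_that(train_fraction > 0 && train_fraction < 1,
             "train_fraction must be in (0,1)")
  check_that(n_folds >= 2L, "n_folds must be >= 2")
  check_that(n_replicates >= 1L, "n_replicates must be >= 1")
  structure(list(variant = variant, train_fraction = train_fraction,
                 n_folds = as.integer(n_folds),
                 n_replicates = as.integer(n_replicates),
                 epochs = as.integer(epochs), lr = lr, beta1 = beta1,
                 beta2 = beta2, adam_eps = adam_eps, D = as.integer(D),
                 C = as.integer(C), slope = slope, init_sd = init_sd,
                 seed = as.integer(seed), selection = match.arg(selection)),
            class = "mil_config")
}

#' Stratified train/test split
#'
#' Splits bags into a training set holding `round(train_fraction * N)` bags
#' and a test set with the rest, stratified by label so both sets keep the
#' class balance, deterministically for a given seed.
#'
#' @param bags list of `mil_bag`.
#' @param seed integer split seed.
#' @param train_fraction training fraction.
#' @return list with elements `train` and `test` (disjoint, covering input).
#' @export
split_dataset <- function(bags, seed, train_fraction = 0.8) {
  check_that(length(bags) >= 5L, "need at least 5 bags to split")
  y <- bag_labels(bags)
  check_that(all(table(factor(y, levels = 0:1)) >= 2L),
             "need at least 2 bags of each class to stratify the split")
  n_train_total <- round(train_fraction * length(bags))
  idx <- with_seed(seed, {
    train_idx <- integer(0)
    for (cls in c(0L, 1L)) {
      cls_idx <- which(y == cls)
      k <- round(train_fraction * length(cls_idx))
      train_idx <- c(train_idx, sample(cls_idx, k))
    }
    # per-class rounding can drift by 1 from round(f N); repair by moving
    # bags of the majority class so the test set keeps both classes
    excess <- length(train_idx) - n_train_total
    while (excess != 0L) {
      if (excess > 0L) {
        counts <- table(factor(y[train_idx], levels = 0:1))
        cand <- train_idx[y[train_idx] == as.integer(names(which.max(counts)))]
        train_idx <- setdiff(train_idx, cand[sample.int(length(cand), 1L)])
        excess <- excess - 1L
      } else {
        pool <- setdiff(seq_along(bags), train_idx)
        counts <- table(factor(y[pool], levels = 0:1))
        cand <- pool[y[pool] == as.integer(names(which.max(counts)))]
        train_idx <- c(train_idx, cand[sample.int(length(cand), 1L)])
        excess <- excess + 1L
      }
    }
    sort(train_idx)
  })
  list(train = bags[idx], test = bags[-idx])
}

# stratified fold assignment: bags of each class are dealt round-robin, the
# cycle continuing across classes so fold sizes stay balanced (differ by at
# most 1) even when a class count is below n_folds
assign_folds <- function(labels, n_folds, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    ord <- unlist(lapply(sample(unique(labels)), function(cls)
      sample(which(labels == cls))), use.names = FALSE)
    fold[ord] <- rep_len(seq_len(n_folds), length(ord))
  })
  fold
}

#' Train a MIL model on one fold
#'
#' Adam optimization of the binary cross-entropy loss on the positive-class
#' probability, one bag per optimization step (bags have variable size, and
#' a whole slide's instances fit in memory at once). Bag order is reshuffled
#' each epoch; everything is deterministic given `config$seed`.
#'
#' @param train_bags bags used for gradient steps.
#' @param val_bags bags used only for validation metrics (may be `NULL`).
#' @param config a [experiment_config()].
#' @param seed optional override of the training seed.
#' @return the fitted `mil_model` with a `loss_trace` (mean training loss per
#'   epoch) and, when validation bags are given, `val_auc` and `val_loss`.
#' @export
train_fold <- function(train_bags, val_bags = NULL, config, seed = config$seed) {
  y <- bag_labels(train_bags)
  check_that(length(unique(y)) == 2L,
             "training set must contain both classes")
  d <- train_bags[[1L]]$d
  model <- mil_model(config$variant, d = d, D = config$D, C = config$C,
                     slope = config$slope, seed = seed,
                     init_sd = config$init_sd)
  if (config$epochs == 0L) {
    model$loss_trace <- numeric(0)
    return(finish_fold(model, val_bags))
  }
  opt <- adam_init(model$params)
  loss_trace <- numeric(config$epochs)
  with_seed(seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(length(train_bags))
      total <- 0
      for (i in ord) {
        gl <- mil_grad(model, train_bags[[i]])
        if (!is.finite(gl$loss)) {
          stop(sprintf("NaN/Inf loss at epoch %d bag %d; lower the learning rate",
                       epoch, i))
        }
        total <- total + gl$loss
        opt <- adam_step(opt, gl$grads, config)
        model$params <- opt$params
      }
      loss_trace[epoch] <- total / length(train_bags)
    }
  })
  model$loss_trace <- loss_trace
  model$trained <- TRUE
  finish_fold(model, val_bags)
}

finish_fold <- function(model, val_bags) {
  if (!is.null(val_bags) && length(val_bags)) {
    scores <- predict(model, val_bags, type = "prob")
    yv <- bag_labels(val_bags)
    model$val_auc <- if (length(unique(yv)) == 2L) {
      evaluate_auc(scores, yv)
    } else NA_real_
    eps <- 1e-12
    model$val_loss <- mean(-(yv * log(pmax(scores, eps)) +
                               (1 - yv) * log(pmax(1 - scores, eps))))
  }
  model
}

# loss and gradients for one bag (full derivation in the methods vignette)
mil_grad <- function(model, bag) {
  p <- model$params
  H <- bag$instances
  n <- nrow(H)
  S <- H %*% t(p$V)                       # n x D
  Tact <- activation_fun(model$activation)(S, model$slope)
  e <- drop(Tact %*% p$w)
  a <- softmax(e)
  z <- drop(crossprod(H, a))              # d
  if (is_additive(model)) {
    bag_logits <- drop(p$U %*% z) + n * p$b
  } else {
    bag_logits <- drop(p$U %*% z) + p$b
  }
  prob <- softmax(bag_logits)
  y <- bag$label
  eps <- 1e-12
  loss <- -(y * log(max(prob[2L], eps)) + (1 - y) * log(max(prob[1L], eps)))
  g <- prob - c(1 - y, y)                 # d loss / d bag_logits
  dU <- tcrossprod(g, z)                  # C x d
  db <- if (is_additive(model)) n * g else g
  dz <- drop(crossprod(p$U, g))           # d
  da <- drop(H %*% dz)                    # n
  de <- a * (da - sum(a * da))            # softmax Jacobian
  dw <- drop(crossprod(Tact, de))         # D
  dS <- tcrossprod(de, p$w) * activation_grad(model$activation)(S, Tact, model$slope)
  dV <- crossprod(dS, H)                  # D x d
  list(loss = loss, grads = list(V = dV, w = dw, U = dU, b = db))
}

adam_init <- function(params) {
  zero <- lapply(params, function(x) x * 0)
  list(params = params, m = zero, v = zero, t = 0L)
}

adam_step <- function(opt, grads, config) {
  opt$t <- opt$t + 1L
  b1 <- config$beta1; b2 <- config$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  for (nm in names(opt$params)) {
    opt$m[[nm]] <- b1 * opt$m[[nm]] + (1 - b1) * grads[[nm]]
    opt$v[[nm]] <- b2 * opt$v[[nm]] + (1 - b2) * grads[[nm]]^2
    mhat <- opt$m[[nm]] / corr1
    vhat <- opt$v[[nm]] / corr2
    opt$params[[nm]] <- opt$params[[nm]] -
      config$lr * mhat / (sqrt(vhat) + config$adam_eps)
  }
  opt
}

#' K-fold cross-validation with best-fold selection
#'
#' Partitions the training bags into stratified folds, trains one model per
#' fold (on the other folds) and records its validation metric; the returned
#' `best_model` is the fold model with the highest validation AUC (lowest
#' final validation loss under `selection = "loss"`), ties going to the
#' lowest fold index. Folds whose validation split holds a single class have
#' an undefined AUC; they are recorded as `NA` and excluded from selection
#' with a warning.
#'
#' @param train_bags list of bags (the training 80%).
#' @param config a [experiment_config()].
#' @param seed optional override of the fold/training seed.
#' @return list with `fold_models`, `fold_metrics` (data.frame: fold,
#'   val_auc, val_loss), `best_model`, `best_fold`.
#' @export
cross_validate <- function(train_bags, config, seed = config$seed) {
  check_that(length(train_bags) >= config$n_folds,
             "need at least n_folds = %d bags", config$n_folds)
  y <- bag_labels(train_bags)
  fold_id <- assign_folds(y, config$n_folds, seed)
  fold_models <- vector("list", config$n_folds)
  val_auc <- val_loss <- rep(NA_real_, config$n_folds)
  for (k in seq_len(config$n_folds)) {
    val <- train_bags[fold_id == k]
    trn <- train_bags[fold_id != k]
    m <- train_fold(trn, val, config, seed = seed + 1000L * k)
    fold_models[[k]] <- m
    val_auc[k] <- m$val_auc %||% NA_real_
    val_loss[k] <- m$val_loss %||% NA_real_
  }
  if (anyNA(val_auc))
    warning("AUC undefined in ", sum(is.na(val_auc)),
            " fold(s) (single-class validation split); excluded from selection")
  crit <- if (config$selection == "loss") -val_loss else val_auc
  check_that(any(!is.na(crit)), "no fold produced a usable validation metric")
  best_fold <- which.max(crit)            # which.max skips NA, lowest index wins
  list(fold_models = fold_models,
       fold_metrics = data.frame(fold = seq_len(config$n_folds),
                                 val_auc = val_auc, val_loss = val_loss),
       best_model = fold_models[[best_fold]], best_fold = best_fold)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Area under the ROC curve
#'
#' Tie-aware rank-based AUC: the Mann-Whitney U statistic normalized by
#' \eqn{n_+ n_-}, with tied positive/negative score pairs counted half. This
#' equals the trapezoidal area under the empirical ROC curve.
#'
#' @param scores numeric scores (higher = more positive), or a `mil_model`
#'   (then `labels` must be a list of bags to score).
#' @param labels 0/1 vector, or a list of bags when `scores` is a model.
#' @return scalar AUC in \[0, 1\].
#' @export
#' @examples
#' evaluate_auc(c(0.9, 0.8, 0.4), c(1, 0, 1))  # 0.5
evaluate_auc <- function(scores, labels) {
  if (inherits(scores, "mil_model")) {
    bags <- labels
    labels <- bag_labels(bags)
    scores <- predict(scores, bags, type = "prob")
  }
  labels <- as.integer(labels)
  check_that(length(scores) == length(labels),
             "scores and labels differ in length")
  n_pos <- sum(labels == 1L); n_neg <- sum(labels == 0L)
  check_that(n_pos > 0L && n_neg > 0L,
             "AUC needs both classes (got %d positive, %d negative)",
             n_pos, n_neg)
  r <- rank(scores)                        # average ranks handle ties at half
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Run the full replicated protocol
#'
#' For each of `n_replicates` seeds: split the bags 80/20, cross-validate on
#' the training set, evaluate the best-fold model on the held-out test set.
#' Reports the per-replicate test AUCs with their mean and standard
#' deviation.
#'
#' @param bags list of `mil_bag`.
#' @param config a [experiment_config()]; replicate r uses `config$seed + r - 1`.
#' @return object of class `mil_replicates`: list with `per_replicate`
#'   (data.frame: replicate, split_seed, best_fold, test_auc), `mean`, `sd`,
#'   `config`, and `models` (best model per replicate).
#' @export
run_replicates <- function(bags, config) {
  res <- vector("list", config$n_replicates)
  models <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    seed_r <- config$seed + r - 1L
    sp <- split_dataset(bags, seed_r, config$train_fraction)
    cv <- cross_validate(sp$train, config, seed = seed_r)
    auc <- evaluate_auc(cv$best_model, sp$test)
    res[[r]] <- data.frame(replicate = r, split_seed = seed_r,
                           best_fold = cv$best_fold, test_auc = auc)
    models[[r]] <- cv$best_model
  }
  per_rep <- do.call(rbind, res)
  structure(list(per_replicate = per_rep,
                 mean = mean(per_rep$test_auc),
                 sd = if (nrow(per_rep) > 1L) sd(per_rep$test_auc) else 0,
                 config = config, models = models),
            class = "mil_replicates")
}

#' @export
print.mil_replicates <- function(x, ...) {
  cat(sprintf("<mil_replicates '%s': test AUC %.3f +/- %.3f over %d run(s)>\n",
              x$config$variant, x$mean, x$sd, nrow(x$per_replicate)))
  invisible(x)
}

#' @export
summary.mil_replicates <- function(object, ...) {
  print(object)
  print(object$per_replicate, row.names = FALSE)
  invisible(object)
}

#' Write replicate results to disk
#'
#' Emits a per-replicate CSV (`replicate, split_seed, best_fold, test_auc`)
#' and a JSON summary (`mean`, `sd`, `per_replicate`).
#'
#' @param result a `mil_replicates`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return invisibly, the summary list.
#' @export
write_results <- function(result, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path))
    utils::write.csv(result$per_replicate, csv_path, row.names = FALSE)
  summ <- list(variant = result$config$variant, mean = result$mean,
               sd = result$sd, per_replicate = result$per_replicate$test_auc)
  if (!is.null(json_path))
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA)
  invisible(summ)
}
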