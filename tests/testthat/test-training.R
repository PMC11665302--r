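make_fixture_bags <- function(n_bags = 40, seed = 11, mu = 2.0) {
  gen_bags(bag_gen_config(n_bags = n_bags, size_range = c(10L, 30L),
                          mu = mu, seed = seed))
}

test_that("the 80/20 split is a stratified deterministic partition", {
  bags <- make_fixture_bags(10)
  sp <- split_dataset(bags, seed = 3)
  expect_length(sp$train, 8)
  expect_length(sp$test, 2)
  ids <- function(bs) sort(vapply(bs, `[[`, character(1), "slide_id"))
  all_ids <- ids(bags)
  expect_identical(sort(c(ids(sp$train), ids(sp$test))), all_ids)
  expect_length(intersect(ids(sp$train), ids(sp$test)), 0)
  sp2 <- split_dataset(bags, seed = 3)
  expect_identical(ids(sp2$train), ids(sp$train))
  # class balance survives the split
  frac <- function(bs) mean(vapply(bs, `[[`, integer(1), "label"))
  expect_equal(frac(sp$train), 0.5, tolerance = 0.13)
  expect_error(split_dataset(bags[1:4], 1), "at least 5")
})

test_that("cross-validation folds partition the training set", {
  bags <- make_fixture_bags(8)
  cfg <- experiment_config("amil", n_folds = 5, epochs = 0, D = 4)
  cv <- suppressWarnings(cross_validate(bags, cfg, seed = 2))
  labels <- vapply(bags, `[[`, integer(1), "label")
  fold_id <- wsimil:::assign_folds(labels, 5, seed = 2)
  expect_identical(sort(as.vector(table(factor(fold_id, levels = 1:5)))),
                   sort(c(2L, 2L, 2L, 1L, 1L)))
  expect_identical(sort(unname(unlist(tapply(seq_along(bags), fold_id, c)))),
                   seq_along(bags))
  expect_length(cv$fold_models, 5)
})

test_that("best-fold ties resolve to the lowest fold index", {
  crit <- c(0.8, 0.9, 0.9, 0.7, NA)
  expect_identical(which.max(crit), 2L)  # documented argmax semantics
  bags <- make_fixture_bags(20)
  cfg <- experiment_config("amil", epochs = 1, D = 4, lr = 0)
  # lr = 0: every fold model equals its initialization; validation AUCs are
  # whatever the untrained nets give, but selection must still be defined
  cv <- suppressWarnings(cross_validate(bags, cfg, seed = 5))
  expect_true(cv$best_fold >= 1 && cv$best_fold <= 5)
  expect_identical(cv$best_model, cv$fold_models[[cv$best_fold]])
})

test_that("rank-based AUC matches hand counts and handles ties", {
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.4), c(1, 0, 1)), 0.5)
  expect_equal(evaluate_auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(evaluate_auc(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), 0.5)
  expect_error(evaluate_auc(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("rank-based AUC equals brute-force pairwise concordance", {
  set.seed(17)
  for (rep in 1:50) {
    n <- sample(4:20, 1)
    labels <- c(0, 1, sample(0:1, n - 2, TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, TRUE)  # coarse grid forces ties
    expect_identical(evaluate_auc(scores, labels),
                     brute_force_auc(scores, labels))
  }
})

test_that("zero-epoch training returns the initialization untouched", {
  bags <- make_fixture_bags(12)
  cfg <- experiment_config("admil", epochs = 0, D = 8)
  m <- train_fold(bags, NULL, cfg, seed = 4)
  expect_identical(m$params, mil_model("admil", d = 32, D = 8, seed = 4)$params)
  expect_length(m$loss_trace, 0)
})

test_that("training is bit-reproducible and reduces the loss on separable bags", {
  bags <- make_fixture_bags(30)
  cfg <- experiment_config("amil", epochs = 10, D = 16)
  m1 <- train_fold(bags, NULL, cfg, seed = 8)
  m2 <- train_fold(bags, NULL, cfg, seed = 8)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  expect_true(all(is.finite(m1$loss_trace)))
  expect_lt(tail(m1$loss_trace, 1), m1$loss_trace[1])
})

test_that("30 epochs on the separable fixture reach high training AUC", {
  bags <- gen_bags(bag_gen_config(n_bags = 200, seed = 11))
  cfg <- experiment_config("amil", epochs = 30, D = 32)
  m <- train_fold(bags, NULL, cfg, seed = 6)
  expect_gte(evaluate_auc(m, bags), 0.95)
})

test_that("replicate runs are deterministic and self-consistent", {
  bags <- make_fixture_bags(30)
  cfg <- experiment_config("amil", n_replicates = 2, epochs = 3, D = 8,
                           seed = 1)
  r1 <- run_replicates(bags, cfg)
  r2 <- run_replicates(bags, cfg)
  expect_identical(r1$per_replicate, r2$per_replicate)
  expect_equal(mean(r1$per_replicate$test_auc), r1$mean, tolerance = 1e-12)
  expect_equal(stats::sd(r1$per_replicate$test_auc), r1$sd, tolerance = 1e-12)
  cfg1 <- experiment_config("amil", n_replicates = 1, epochs = 2, D = 8)
  expect_identical(run_replicates(bags, cfg1)$sd, 0)
})

test_that("results serialize to CSV and JSON summaries", {
  bags <- make_fixture_bags(30)
  r <- run_replicates(bags, experiment_config("amil", n_replicates = 2,
                                              epochs = 2, D = 8))
  csv <- tempfile(fileext = ".csv"); js <- tempfile(fileext = ".json")
  write_results(r, csv, js)
  back <- utils::read.csv(csv)
  expect_equal(back$test_auc, r$per_replicate$test_auc, tolerance = 1e-9)
  summ <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(summ$mean, r$mean, tolerance = 1e-12)
  expect_identical(summ$variant, "amil")
})
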