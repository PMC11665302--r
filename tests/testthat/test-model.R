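test_that("attention logits match hand-evaluated two-layer scorer", {
  # w = 0 kills every logit regardless of input
  H <- matrix(rnorm(12), 3, 4)
  expect_equal(attention_logits(H, matrix(rnorm(8), 2, 4), c(0, 0)),
               c(0, 0, 0))
  # d = 2, D = 1: tanh path
  V <- matrix(c(1, 0), 1, 2); w <- 1
  expect_equal(attention_logits(matrix(c(0.5, 9), 1, 2), V, w, "tanh"),
               tanh(0.5), tolerance = 1e-12)
  # leaky_relu with slope 0.01 on a negative pre-activation
  expect_equal(attention_logits(matrix(c(-1, 0), 1, 2), V, w, "leaky_relu",
                                slope = 0.01),
               -0.01, tolerance = 1e-12)
})

test_that("attention normalization is a softmax over instances", {
  expect_equal(attention_normalize(c(0, 0, 0, 0)), rep(0.25, 4))
  expect_equal(attention_normalize(17.3), 1.0)
  expect_equal(attention_normalize(c(log(2), 0)), c(2 / 3, 1 / 3))
  expect_error(attention_normalize(numeric(0)), "empty")
})

test_that("dimension mismatches are rejected with informative shapes", {
  H <- matrix(rnorm(6), 2, 3)
  expect_error(attention_logits(H, matrix(rnorm(8), 2, 4), c(1, 1)), "V is 2x4")
  expect_error(attention_logits(H, matrix(rnorm(6), 2, 3), c(1, 1, 1)),
               "w has length 3")
})

test_that("additive forward sums patch logits into bag logits", {
  # three patches contributing (+2, -1, +0.5) to the positive class:
  # P(positive) = exp(1.5) / (1 + exp(1.5))
  m <- mil_model("admil", d = 2, D = 2, seed = 1)
  b <- mil_bag(matrix(rnorm(6), 3, 2), 1)
  p <- admil_forward(m, b)
  expect_equal(colSums(p$patch_logits), p$bag_logits, tolerance = 1e-12)
  # class probabilities are the two-class softmax of the summed logits
  expect_equal(p$class_probabilities,
               exp(p$bag_logits) / sum(exp(p$bag_logits)), tolerance = 1e-12)
  # worked case: patch contributions (+2, -1, +0.5) to the positive class
  pl <- rbind(c(0, 2), c(0, -1), c(0, 0.5))
  bag_logits <- c(sum(pl[, 1]), sum(pl[, 2]))
  expect_equal(bag_logits, c(0, 1.5))
  expect_equal(exp(bag_logits[2]) / sum(exp(bag_logits)),
               exp(1.5) / (1 + exp(1.5)), tolerance = 1e-12)
})

test_that("single-instance AMIL bag pools to the instance itself", {
  m <- mil_model("amil", d = 5, D = 3, seed = 7)
  h <- rnorm(5)
  p <- amil_forward(m, mil_bag(matrix(h, 1, 5), 0))
  expect_equal(p$attention, 1.0)
  expect_equal(p$pooled, h)
})

test_that("duplicating every instance leaves class probabilities unchanged", {
  set.seed(21)
  m <- mil_model("amil", d = 6, D = 4, seed = 3)
  H <- matrix(rnorm(30), 5, 6)
  p1 <- mil_forward(m, H)
  p2 <- mil_forward(m, rbind(H, H))
  expect_equal(p2$class_probabilities, p1$class_probabilities,
               tolerance = 1e-12)
  expect_equal(p2$attention, rep(p1$attention / 2, 2), tolerance = 1e-12)
})

test_that("forward passes are permutation invariant for all variants", {
  set.seed(4)
  for (variant in c("amil", "admil", "admil_tanh")) {
    m <- mil_model(variant, d = 8, D = 4, seed = 5)
    for (rep in 1:10) {
      b <- random_bag(sample(2:30, 1), 8)
      perm <- sample(b$n)
      p1 <- mil_forward(m, b)
      p2 <- mil_forward(m, b$instances[perm, , drop = FALSE])
      expect_equal(p2$class_probabilities, p1$class_probabilities,
                   tolerance = 1e-9)
      expect_equal(p2$attention, p1$attention[perm], tolerance = 1e-9)
    }
  }
})

test_that("attention always lies on the simplex", {
  set.seed(11)
  for (rep in 1:20) {
    m <- mil_model(sample(c("amil", "admil", "admil_tanh"), 1),
                   d = 4, D = 3, seed = rep)
    p <- mil_forward(m, random_bag(sample(1:40, 1), 4))
    expect_true(all(p$attention >= 0))
    expect_equal(sum(p$attention), 1, tolerance = 1e-9)
  }
})

test_that("bounded contributions follow the logistic transform and polarity rule", {
  bc <- bound_contributions(matrix(c(0, -2, 2, 0, 0, 0), 3, 2))
  expect_equal(bc$values[1, 1], 0.5)
  expect_equal(bc$values[2, 1], 1 / (1 + exp(2)), tolerance = 1e-9)
  expect_equal(bc$values[3, 1], 1 / (1 + exp(-2)), tolerance = 1e-9)
  # polarity is judged on the positive-class column; 0.5 ties are inhibitory
  bc2 <- bound_contributions(matrix(c(-2, 2, 0), 3, 1))
  expect_equal(bc2$polarity, c("inhibitory", "excitatory", "inhibitory"))
  expect_true(all(bc2$values > 0 & bc2$values < 1))
})

test_that("model construction is seed-deterministic and variant-aware", {
  m1 <- mil_model("amil", d = 16, seed = 9)
  m2 <- mil_model("amil", d = 16, seed = 9)
  expect_identical(m1$params, m2$params)
  a <- mil_model("amil", d = 1024, seed = 2)     # paper-scale embeddings
  b <- mil_model("admil", d = 1024, seed = 2)
  expect_equal(a$d, 1024L)
  expect_identical(a$activation, "tanh")
  expect_identical(b$activation, "leaky_relu")
  expect_null(mil_forward(a, random_bag(2, 1024))$patch_logits)
  expect_false(is.null(mil_forward(b, random_bag(2, 1024))$patch_logits))
  expect_error(mil_model("transformer"), "arg")
})

test_that("variant-mismatched forward wrappers refuse to run", {
  amil <- mil_model("amil", d = 4, D = 2, seed = 1)
  admil <- mil_model("admil", d = 4, D = 2, seed = 1)
  b <- random_bag(3, 4)
  expect_error(amil_forward(admil, b), "variant")
  expect_error(admil_forward(amil, b), "variant")
})

test_that("checkpoints round-trip the model with a JSON sidecar", {
  m <- mil_model("admil_tanh", d = 8, D = 4, seed = 13)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$params, m$params)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$variant, "admil_tanh")
  expect_identical(meta$d, 8L)
})

test_that("forward passes agree with the hand-unrolled scalar oracle", {
  set.seed(31)
  for (variant in c("amil", "admil", "admil_tanh")) {
    for (rep in 1:10) {
      n <- sample(1:3, 1); d <- sample(1:2, 1)
      D <- sample(1:3, 1)
      m <- mil_model(variant, d = d, D = D, seed = rep)
      # tiny integer-valued parameters exercise exact arithmetic
      m$params$V <- matrix(sample(-2:2, D * d, TRUE), D, d)
      m$params$w <- sample(-2:2, D, TRUE)
      m$params$U <- matrix(sample(-2:2, 2 * d, TRUE), 2, d)
      m$params$b <- sample(-1:1, 2, TRUE)
      H <- matrix(sample(-3:3, n * d, TRUE) / 2, n, d)
      got <- mil_forward(m, H)
      want <- scalar_forward(variant, H, m$params$V, m$params$w,
                             m$params$U, m$params$b)
      expect_equal(got$attention, want$attention, tolerance = 1e-9)
      expect_equal(got$bag_logits, want$bag_logits, tolerance = 1e-9)
      expect_equal(got$class_probabilities, want$class_probabilities,
                   tolerance = 1e-9)
      if (!is.null(want$patch_logits))
        expect_equal(got$patch_logits, want$patch_logits, tolerance = 1e-9)
    }
  }
})

test_that("zero attention weights reduce AMIL to mean pooling", {
  set.seed(41)
  m <- mil_model("amil", d = 6, D = 4, seed = 2)
  m$params$w <- rep(0, 4)
  b <- random_bag(9, 6)
  p <- mil_forward(m, b)
  expect_identical(p$attention, rep(1 / 9, 9))
  expect_equal(p$class_probabilities,
               mean_pool_forward(b$instances, m$params$U, m$params$b),
               tolerance = 1e-12)
})
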