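#' Configuration for the synthetic bag generator
#'
#' Describes a desk-scale MIL dataset with a known ground truth: background
#' instances are standard spherical Gaussian noise in `d` dimensions, and
#' each positive bag carries witness instances shifted by `mu` along a fixed
#' (seeded) random unit direction. Positive bags have at least one witness;
#' negative bags have none — the standard MIL assumption by construction.
#'
#' @param n_bags total number of bags.
#' @param size_range integer range (min, max) of instances per bag.
#' @param d embedding dimension.
#' @param mu witness shift, in units of the noise standard deviation along
#'   the witness direction; `mu = 0` gives an indistinguishable null dataset.
#' @param witness_rate expected fraction of witness instances in a positive
#'   bag (at least one witness is always planted).
#' @param balance fraction of positive bags.
#' @param noise_sd standard deviation of the background noise.
#' @param seed generator seed.
#' @return a list of class `bag_gen_config`.
#' @export
bag_gen_config <- function(n_bags = 200L, size_range = c(20L, 100L),
                           d = 32L, mu = 2.0, witness_rate = 0.2,
                           balance = 0.5, noise_sd = 1.0, seed = 1L) {
  check_that(witness_rate > 0 && witness_rate <= 1,
             "witness_rate must be in (0, 1]")
  check_that(balance > 0 && balance < 1, "balance must be in (0, 1)")
  check_that(size_range[1L] >= 1L && size_range[2L] >= size_range[1L],
             "invalid size_range")
  structure(list(n_bags = as.integer(n_bags),
                 size_range = as.integer(size_range), d = as.integer(d),
                 mu = mu, witness_rate = witness_rate, balance = balance,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "bag_gen_config")
}

#' Generate synthetic MIL bags with hidden instance labels
#'
#' @param config a [bag_gen_config()].
#' @return list of `mil_bag` objects; each carries `instance_labels` marking
#'   the planted witnesses (1) vs background (0). Training code never reads
#'   them; tests use them to score witness localization.
#' @export
#' @examples
#' bags <- gen_bags(bag_gen_config(n_bags = 10, seed = 3))
#' table(bag_labels <- sapply(bags, `[[`, "label"))
gen_bags <- function(config) {
  n_pos <- round(config$balance * config$n_bags)
  check_that(n_pos >= 1L && n_pos < config$n_bags,
             "config yields an all-one-class dataset")
  check_that(config$witness_rate * config$size_range[1L] >= 1,
             paste("infeasible config: witness_rate * min bag size < 1,",
                   "positive bags could not carry a witness at the stated rate"))
  with_seed(config$seed, {
    # one witness direction per dataset, unit norm
    u <- rnorm(config$d)
    u <- u / sqrt(sum(u^2))
    labels <- sample(rep(c(1L, 0L), c(n_pos, config$n_bags - n_pos)))
    lapply(seq_len(config$n_bags), function(i) {
      n <- sample(seq(config$size_range[1L], config$size_range[2L]), 1L)
      H <- matrix(rnorm(n * config$d, sd = config$noise_sd), n, config$d)
      inst <- integer(n)
      if (labels[i] == 1L) {
        n_wit <- max(1L, stats::rbinom(1L, n, config$witness_rate))
        wit <- sample(n, n_wit)
        H[wit, ] <- H[wit, ] + rep(config$mu * u, each = n_wit)
        inst[wit] <- 1L
      }
      mil_bag(H, labels[i], instance_labels = inst,
              slide_id = sprintf("synthetic_bag_%03d", i))
    })
  })
}
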