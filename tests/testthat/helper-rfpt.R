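# Small dataset builders shared across the suite.

# one-feature dataset from explicit values and labels
d1 <- function(values, labels) {
  rop_dataset(matrix(values, ncol = 1), labels, require_both_classes = FALSE)
}

# random small instance for property tests: m samples, one feature,
# both classes guaranteed
random_instance <- function(m) {
  x <- matrix(round(stats::rnorm(m), 2), ncol = 1)
  y <- stats::rbinom(m, 1, 0.5)
  if (length(unique(y)) < 2) y[1] <- 1 - y[1]
  rop_dataset(x, y)
}

# a valid random tally respecting all counting identities
random_tally <- function(nf, seed) {
  set.seed(seed)
  times <- sample(50:200, nf, replace = TRUE)
  perfect <- stats::rbinom(nf, times, runif(nf))
  signs <- t(vapply(perfect, function(p)
    as.integer(stats::rmultinom(1, p, prob = c(.2, .25, .25, .15, .15))),
    integer(5)))  # zero, pos, neg, non-mono, mixed (mixed uncounted)
  two_n <- stats::rbinom(nf, perfect, 0.8)
  one_n <- stats::rbinom(nf, two_n, 0.7)
  enum <- stats::rbinom(nf, perfect, 0.9)
  uniq <- stats::rbinom(nf, enum, 0.6)
  data.frame(feature = paste0("f", seq_len(nf)),
             times_selected = times, perfect_trees = perfect,
             all_zero = signs[, 1], all_positive = signs[, 2],
             all_negative = signs[, 3], non_monotone = signs[, 4],
             two_neuron_perfect = two_n, one_neuron_perfect = one_n,
             enumerable_solutions = enum, unique_solution = uniq,
             stringsAsFactors = FALSE)
}
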