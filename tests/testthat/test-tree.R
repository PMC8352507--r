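# Frozen expected values below were derived by brute force over all
# 3 coefficient vectors x all midpoint thresholds (and, for trees, all
# neuron sequences) on these four-sample instances.

test_that("neuron step maximizes error-free finalizations and counts optima", {
  d <- d1(1:4, c(0, 1, 1, 0))
  st <- fit_neuron_step(d, 1, 1:4, "finalize_negative")
  expect_equal(st$count, 1L)                 # best error-free peel is 1 sample
  expect_equal(st$n_optimal, 2)              # (-1) peels x=4, (+1) peels x=1
  expect_equal(unname(st$coefficients), -1)  # tie broken lexicographically
  expect_equal(st$finalized, 4L)
  expect_equal(st$assigned, 0L)

  # pure active set: every vector finalizes everything -> unconstrained
  d0 <- d1(1:4, c(0, 0, 0, 0))
  st0 <- fit_neuron_step(d0, 1, 1:4, "finalize_negative")
  expect_equal(st0$count, 4L)
  expect_equal(st0$n_optimal, Inf)

  d2 <- d1(1:4, c(0, 0, 1, 1))
  st2 <- fit_neuron_step(d2, 1, 1:4, "finalize_positive")
  expect_equal(unname(st2$coefficients), 1)
  expect_equal(st2$threshold, 2.5)
  expect_equal(sort(st2$finalized), c(3L, 4L))

  # empty finalization is legal, not an error
  d3 <- d1(1:4, c(1, 0, 0, 1))
  st3 <- fit_neuron_step(d3, 1, 1:4, "finalize_negative")
  expect_equal(st3$count, 0L)
  expect_length(st3$finalized, 0L)
})

test_that("tree growth reaches perfection within the step budget", {
  # clean split: one neuron finalizes both sides
  tr <- grow_tree(d1(1:4, c(0, 0, 1, 1)), 1)
  expect_true(tr$is_perfect)
  expect_equal(tr$neurons_used, 1L)
  expect_equal(tr$solution_class, "unique")

  # non-monotone labels: peel an end, then split the remainder
  tr2 <- grow_tree(d1(1:4, c(0, 1, 1, 0)), 1)
  expect_true(tr2$is_perfect)
  expect_lte(tr2$neurons_used, 4L)
  expect_true(verify_perfect(tr2, c(0L, 1L, 1L, 0L),
                             d1(1:4, c(0, 1, 1, 0))))
  expect_equal(tr2$solution_class, "finite")
  expect_equal(tr2$solution_multiplicity, 2)

  # pure root: zero-coefficient solution admissible, unconstrained
  tr3 <- grow_tree(d1(1:4, c(0, 0, 0, 0)), 1)
  expect_true(tr3$is_perfect)
  expect_equal(tr3$neurons_used, 1L)
  expect_equal(tr3$solution_class, "unconstrained")

  expect_error(grow_tree(d1(1:4, c(0, 1, 1, 0)), integer(0)), "empty")
})

test_that("perfection verification is a strict independent re-check", {
  d <- d1(1:4, c(0, 1, 1, 0))
  tr <- grow_tree(d, 1)
  expect_true(verify_perfect(tr, d$y, d))
  # a flipped truth label must break sensitivity/specificity
  expect_false(verify_perfect(tr, c(1L, 1L, 1L, 0L), NULL))
  # tampering with a recorded assignment must break the confusion check
  tr_bad <- tr
  tr_bad$neurons[[1]]$assigned <- 1L - tr$neurons[[1]]$assigned
  expect_false(verify_perfect(tr_bad, d$y, NULL))
  # tampering with a threshold must fail the raw-data replay
  tr_bad2 <- tr
  tr_bad2$neurons[[1]]$threshold <- tr$neurons[[1]]$threshold + 100
  expect_false(verify_perfect(tr_bad2, d$y, d))
  # imperfect trees never verify
  d_imp <- d1(c(1, 1), c(0, 1))
  tr_imp <- grow_tree(d_imp, 1)
  expect_false(tr_imp$is_perfect)
  expect_false(verify_perfect(tr_imp, d_imp$y, d_imp))
})

test_that("sign categories are exclusive, exhaustive and as defined", {
  expect_equal(sign_profile(c(1, 1, 1)), "all_positive")
  expect_equal(sign_profile(c(1, 0)), "mixed_with_zero")
  expect_equal(sign_profile(c(1, -1)), "non_monotone")
  expect_equal(sign_profile(c(0, 0)), "all_zero")
  expect_equal(sign_profile(c(-1, -1)), "all_negative")
  expect_equal(sign_profile(c(-1, 0)), "mixed_with_zero")

  set.seed(77)
  cats <- c("all_zero", "all_positive", "all_negative", "non_monotone",
            "mixed_with_zero")
  for (rep in 1:50) {
    co <- sample(c(-1, 0, 1), sample(1:6, 1), replace = TRUE)
    hits <- c(all(co == 0),
              all(co > 0),
              all(co < 0),
              any(co > 0) && any(co < 0))
    got <- sign_profile(co)
    expect_true(got %in% cats)
    expect_equal(got == "all_zero", hits[1])
    expect_equal(got == "all_positive", hits[2])
    expect_equal(got == "all_negative", hits[3])
    expect_equal(got == "non_monotone", hits[4])
    expect_equal(got == "mixed_with_zero", !any(hits))
  }
})

test_that("solution classes follow the per-neuron multiplicity product", {
  expect_equal(count_solutions(grow_tree(d1(1:4, c(0, 0, 1, 1)), 1)),
               list(class = "unique", multiplicity = 1))
  expect_equal(count_solutions(grow_tree(d1(1:4, c(0, 1, 1, 0)), 1)),
               list(class = "finite", multiplicity = 2))
  expect_equal(count_solutions(grow_tree(d1(1:4, rep(0, 4)), 1))$class,
               "unconstrained")
  expect_error(count_solutions(grow_tree(d1(c(1, 1), c(0, 1)), 1)),
               "perfect")
})

test_that("duplicating a sample never destroys perfection", {
  set.seed(303)
  n_checked <- 0
  for (rep in 1:40) {
    d <- random_instance(sample(3:7, 1))
    tr <- grow_tree(d, 1)
    if (!tr$is_perfect) next
    n_checked <- n_checked + 1
    i <- sample(nrow(d$x), 1)
    d_dup <- rop_dataset(rbind(d$x, d$x[i, , drop = FALSE]), c(d$y, d$y[i]))
    expect_true(grow_tree(d_dup, 1)$is_perfect)
  }
  expect_gte(n_checked, 10)
})

test_that("contradictory samples make perfection impossible", {
  set.seed(404)
  for (rep in 1:20) {
    m <- sample(3:6, 1)
    x <- matrix(round(rnorm(m), 2), ncol = 1)
    x <- rbind(x, x[1, , drop = FALSE])       # identical values ...
    y <- rbinom(m, 1, 0.5)
    y <- c(y, 1L - y[1])                      # ... opposite labels
    d <- rop_dataset(x, y)
    expect_false(grow_tree(d, 1)$is_perfect)
    expect_false(perfect_tree_exists(d, 1))
  }
})

test_that("two-feature neurons separate classes no single feature can", {
  # XOR-free two-feature case: class 1 iff x1 + x2 large; each feature
  # alone is ambiguous, the pair splits in one neuron
  x <- rbind(c(1, 5), c(5, 1), c(4, 4), c(5, 5))
  d <- rop_dataset(x, c(0, 0, 1, 1))
  expect_false(grow_tree(d, 1, tree_config(1))$is_perfect ||
               grow_tree(d, 2, tree_config(1))$is_perfect)
  tr <- grow_tree(d, c(1, 2), tree_config(2))
  expect_true(tr$is_perfect)
  expect_true(verify_perfect(tr, d$y, d))
})

test_that("sampled (non-exhaustive) neuron search is flagged and still sound", {
  set.seed(505)
  x <- matrix(rnorm(12 * 9), ncol = 9)
  y <- as.integer(x[, 1] > 0)
  if (length(unique(y)) < 2) y[1] <- 1L - y[1]
  d <- rop_dataset(x, y)
  cfg <- tree_config(9, max_vectors = 500)
  tr <- grow_tree(d, 1:9, cfg)
  expect_false(tr$exhaustive)
  if (tr$is_perfect) expect_true(verify_perfect(tr, d$y, d))
})
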