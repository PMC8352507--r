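test_that("planning honors the per-feature selection quota", {
  p <- plan_forest(3, forest_config(1, min_instances_per_feature = 2, seed = 5))
  expect_true(all(attr(p, "selection_counts") >= 2))
  expect_true(attr(p, "quota_met"))

  # slot arithmetic: 30 features at quota 100 with 15-feature trees needs
  # at least 100 * 30 / 15 = 200 trees
  p2 <- plan_forest(30, forest_config(15, min_instances_per_feature = 100,
                                      seed = 5))
  expect_gte(nrow(p2), 200L)
  expect_true(all(attr(p2, "selection_counts") >= 100))
  # within a tree: no repeated feature
  expect_true(all(apply(p2, 1, anyDuplicated) == 0L))

  # exact tree-count mode overrides the quota
  p3 <- plan_forest(10, forest_config(1, seed = 5, n_trees = 57))
  expect_equal(nrow(p3), 57L)

  # unreachable quota warns rather than fails
  expect_warning(
    plan_forest(5, forest_config(1, min_instances_per_feature = 50,
                                 seed = 5, max_trees = 20)),
    "quota")

  expect_error(plan_forest(3, forest_config(4)), "exceeds")
})

test_that("planning is reproducible from the master seed alone", {
  cfg <- forest_config(2, min_instances_per_feature = 10, seed = 99)
  expect_identical(plan_forest(20, cfg), plan_forest(20, cfg))
  cfg2 <- forest_config(2, min_instances_per_feature = 10, seed = 100)
  expect_false(identical(plan_forest(20, cfg), plan_forest(20, cfg2)))
  # adjusted mode draws exactly as standard: only the label differs
  cfg_adj <- forest_config(2, min_instances_per_feature = 10, seed = 99,
                           mode = "adjusted")
  expect_equal(unclass(plan_forest(20, cfg))[, ],
               unclass(plan_forest(20, cfg_adj))[, ])
})

test_that("stratified trees carry exactly one previously selected feature", {
  sel <- c(2L, 5L, 9L)
  cfg <- forest_config(4, min_instances_per_feature = 5, seed = 7,
                       mode = "stratified", selected = sel)
  p <- plan_forest(12, cfg)
  in_sel <- apply(p, 1, function(r) sum(r %in% sel))
  expect_true(all(in_sel == 1L))
  expect_true(all(apply(p, 1, anyDuplicated) == 0L))
  expect_error(forest_config(4, mode = "stratified"), "selected")
})

test_that("a separating feature is perfect in every tree it enters", {
  sep <- c(1, 2, 3, 10, 11, 12)
  set.seed(1)
  noise <- rnorm(6)
  d <- rop_dataset(cbind(sep = sep, noise = noise), c(0, 0, 0, 1, 1, 1))
  f <- build_forest(d, forest_config(1, min_instances_per_feature = 50,
                                     seed = 42))
  tal <- f$tally
  row <- tal[tal$feature == "sep", ]
  expect_equal(row$perfect_trees, row$times_selected)   # NIC1 ratio 1.0
  expect_equal(row$one_neuron_perfect, row$perfect_trees)
  expect_equal(row$all_positive, row$perfect_trees)
  expect_equal(row$unique_solution, row$perfect_trees)
  validate_tally(tal)
})

test_that("tied values across classes forbid perfection for a noise feature", {
  # duplicated values shared between the classes: no threshold sequence can
  # ever separate them
  x <- cbind(good = c(1, 2, 3, 10, 11, 12),
             bad = c(5, 6, 7, 5, 6, 7))
  d <- rop_dataset(x, c(0, 0, 0, 1, 1, 1))
  f <- build_forest(d, forest_config(1, min_instances_per_feature = 20,
                                     seed = 3))
  bad <- f$tally[f$tally$feature == "bad", ]
  expect_equal(bad$perfect_trees, 0L)
  expect_lt(bad$perfect_trees, bad$times_selected)
})

test_that("forests are bitwise reproducible under a fixed seed", {
  g <- generate_dataset(synth_spec(n_samples = 24, n_features = 8,
                                   n_separable = 1, seed = 11))
  cfg <- forest_config(2, min_instances_per_feature = 10, seed = 123)
  f1 <- build_forest(g$data, cfg)
  f2 <- build_forest(g$data, cfg)
  expect_identical(f1$tally, f2$tally)
  expect_identical(f1$n_perfect, f2$n_perfect)
})

test_that("multi-feature forests keep every tally identity", {
  g <- generate_dataset(synth_spec(n_samples = 20, n_features = 10,
                                   n_separable = 1, n_paradoxical = 2,
                                   n_monotone_weak = 2, seed = 21))
  for (n_per in 1:3) {
    f <- build_forest(g$data,
                      forest_config(n_per, min_instances_per_feature = 15,
                                    seed = 8))
    expect_true(validate_tally(f$tally))
    expect_equal(sum(f$tally$times_selected), f$n_trees * n_per)
  }
})

test_that("single-class outcomes are rejected", {
  d <- rop_dataset(matrix(rnorm(12), 6, 2), rep(1L, 6),
                   require_both_classes = FALSE)
  expect_error(build_forest(d, forest_config(1, min_instances_per_feature = 2)),
               "both outcome classes")
})

test_that("the tree log is one valid JSON record per tree", {
  d <- rop_dataset(cbind(a = c(1, 2, 3, 10, 11, 12),
                         b = c(2, 1, 3, 1, 2, 3)),
                   c(0, 0, 0, 1, 1, 1))
  log <- tempfile(fileext = ".jsonl")
  f <- build_forest(d, forest_config(1, min_instances_per_feature = 5,
                                     seed = 2), log_file = log)
  lines <- readLines(log)
  expect_length(lines, f$n_trees)
  rec <- jsonlite::fromJSON(lines[1])
  expect_true(all(c("features", "neurons", "is_perfect", "sign_profile") %in%
                  names(rec)))
})
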