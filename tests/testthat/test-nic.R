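test_that("published tally rows reproduce their criterion ratios", {
  tal <- published_tally()
  nics <- compute_nics(tal)

  bbox1 <- nics[nics$feature == "205363_at", ]
  expect_equal(bbox1$nic1, 1.0)
  expect_equal(bbox1$nic2, 0)
  expect_equal(bbox1$nic3, 1.0)
  expect_equal(bbox1$nic4, 0)
  expect_equal(bbox1$nic5, 0)
  expect_equal(bbox1$nic6, 0)
  expect_equal(bbox1$nic7, 1.0)
  expect_equal(bbox1$nic8, 1.0)
  expect_equal(bbox1$nic9, 1.0)
  expect_equal(bbox1$nic10, 1.0)

  # consistently protective probe: all-negative, never all-positive
  erap2 <- nics[nics$feature == "227462_at", ]
  expect_equal(erap2$nic4, 1.0)
  expect_equal(erap2$nic3, 0)
  expect_equal(erap2$nic5, 0)
})

test_that("features without perfect trees are zeroed and flagged", {
  tal <- data.frame(feature = "none", times_selected = 30L,
                    perfect_trees = 0L, all_zero = 0L, all_positive = 0L,
                    all_negative = 0L, non_monotone = 0L,
                    two_neuron_perfect = 0L, one_neuron_perfect = 0L,
                    enumerable_solutions = 0L, unique_solution = 0L)
  row <- compute_nics(tal)
  expect_true(row$no_pt)
  expect_equal(unlist(row[paste0("nic", 1:10)]),
               setNames(rep(0, 10), paste0("nic", 1:10)))
  tal$times_selected <- 0L
  expect_error(compute_nics(tal), "selected at least once")
})

test_that("the composite score follows its defining sum", {
  tal <- published_tally()
  nics <- compute_nics(tal)
  expect_equal(nics$nic_score,
               nics$nic1 - nics$nic2 - nics$nic6 + nics$nic8 + nics$nic9 +
                 nics$nic10)
  # an always-perfect but multi-neuron, non-unique feature scores 1
  one <- data.frame(feature = "f", nic1 = 1, nic2 = 0, nic3 = 0, nic4 = 0,
                    nic5 = 0, nic6 = 0, nic7 = 0, nic8 = 0, nic9 = 0,
                    nic10 = 0)
  expect_equal(nic_score(one), 1.0)
})

test_that("criterion identities hold on randomized valid tallies", {
  for (seed in 1:5) {
    tal <- random_tally(40, seed)
    validate_tally(tal)
    nics <- compute_nics(tal)
    ratios <- as.matrix(nics[paste0("nic", 1:10)])
    expect_true(all(ratios >= 0 & ratios <= 1))
    expect_equal(nics$nic5, nics$nic3 * nics$nic4)
    expect_true(all(nics$nic8 <= nics$nic7 + 1e-12))
    expect_true(all(nics$nic10 <= nics$nic9 + 1e-12))
    expect_true(all(nics$nic2 + nics$nic3 + nics$nic4 + nics$nic6 <= 1 + 1e-12))
    expect_true(all(nics$nic_score >= -2 & nics$nic_score <= 4))
  }
})

test_that("hierarchical ranking is a stable descending lexicographic sort", {
  tal <- published_tally()
  nics <- compute_nics(tal)
  hr <- hierarchical_rank(nics)
  # the twelve selected probes (maximal on all four keys) precede every
  # plain probe, whose one-neuron criterion is zero
  sel <- tal$feature[tal$selected == 1]
  expect_setequal(hr[1:12], sel)
  expect_true(which(hr == "205363_at") < which(hr == "1553875_s_at"))

  # stability: identical rows preserve input order
  two <- rbind(tal[1, ], tal[1, ])
  two$feature <- c("first", "second")
  expect_equal(hierarchical_rank(compute_nics(two)), c("first", "second"))

  one <- compute_nics(tal[3, ])
  expect_equal(hierarchical_rank(one), tal$feature[3])
  expect_equal(one$hierarchical_rank, 1L)

  expect_error(hierarchical_rank(nics, keys = "nic99"), "unknown")

  # features without perfect trees rank last despite 1 - nic2 = 1 formally
  tal_no <- tal[1:2, ]
  tal_no[2, c("perfect_trees", "all_zero", "all_positive", "all_negative",
              "non_monotone", "two_neuron_perfect", "one_neuron_perfect",
              "enumerable_solutions", "unique_solution")] <- 0L
  nics_no <- compute_nics(tal_no)
  expect_equal(hierarchical_rank(nics_no)[2], tal_no$feature[2])
})

test_that("gap selection cuts at the first clear score drop", {
  scores <- c(rep(4.00, 12), rep(3.99, 4), rep(2.00, 10), rep(1.2, 5))
  names(scores) <- paste0("p", seq_along(scores))
  sel <- select_by_gap(scores, min_gap = 1)
  expect_length(sel$selected, 16L)
  expect_false(sel$no_gap)
  expect_equal(sel$threshold, 3.99)

  flat <- setNames(rep(2, 5), paste0("q", 1:5))
  sel_flat <- select_by_gap(flat)
  expect_length(sel_flat$selected, 5L)
  expect_true(sel_flat$no_gap)

  expect_equal(select_by_gap(c(a = 4, b = 2))$selected, "a")
  expect_length(select_by_gap(numeric(0))$selected, 0L)
  expect_error(select_by_gap(c(a = 1), min_gap = 0), "positive")
})
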