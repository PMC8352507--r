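#' Forest configuration
#'
#' A random forest of perfect trees draws uniform feature subsets — without
#' replacement within a tree, with replacement across trees — and grows every
#' tree on all observations (no bootstrapping: resampling would give
#' observations unequal weights). Drawing continues until every feature has
#' been selected at least `min_instances_per_feature` times (default 100),
#' unless an exact `n_trees` is requested or the `max_trees` guard is hit.
#'
#' Modes differ only in how subsets are drawn: `"standard"` and
#' `"adjusted"` draw freely from all features (adjusted analyses are
#' standard forests rerun at larger `n_features_per_neuron`, e.g. 2, 3 or
#' 15, to confirm a prior single-feature selection); `"stratified"` puts
#' exactly one feature from the previously `selected` set and
#' `n_features_per_neuron - 1` unselected features into every tree.
#'
#' @param n_features_per_neuron Features randomized into each neuron.
#' @param min_instances_per_feature Selection quota per feature (default
#'   100): the minimum number of trees each feature must be drawn into.
#' @param mode `"standard"`, `"adjusted"` or `"stratified"`.
#' @param selected Feature indices or names of the previously selected set;
#'   required for stratified mode.
#' @param seed Master seed; together with the configuration it fully
#'   determines the forest.
#' @param n_trees Optional exact tree count, overriding the quota rule
#'   (large published forests overshoot the quota; this reproduces such
#'   designs).
#' @param max_trees Runaway guard; defaults to `quota x n_features x 10`.
#' @param tree A [tree_config()]; its `n_features_per_neuron` is kept in
#'   sync.
#' @param chunk_size Trees per RNG substream. Subset draws use independent
#'   substreams seeded by a deterministic mix of the master seed and the
#'   chunk index, so the plan is reproducible regardless of how chunks are
#'   distributed over workers.
#' @return An object of class `rop_forest_config`.
#' @export
forest_config <- function(n_features_per_neuron = 1L,
                          min_instances_per_feature = 100L,
                          mode = c("standard", "adjusted", "stratified"),
                          selected = NULL,
                          seed = 1L,
                          n_trees = NULL,
                          max_trees = NULL,
                          tree = tree_config(n_features_per_neuron),
                          chunk_size = 8192L) {
  mode <- match.arg(mode)
  n <- as.integer(n_features_per_neuron)
  if (is.na(n) || n < 1L) stop("n_features_per_neuron must be >= 1", call. = FALSE)
  if (min_instances_per_feature < 1L)
    stop("min_instances_per_feature must be >= 1", call. = FALSE)
  if (mode == "stratified" && length(selected) == 0L)
    stop("stratified mode requires a nonempty selected feature set", call. = FALSE)
  tree$n_features_per_neuron <- n
  structure(list(n_features_per_neuron = n,
                 min_instances_per_feature = as.integer(min_instances_per_feature),
                 mode = mode,
                 selected = selected,
                 seed = as.integer(seed),
                 n_trees = if (is.null(n_trees)) NULL else as.double(n_trees),
                 max_trees = if (is.null(max_trees)) NULL else as.double(max_trees),
                 tree = tree,
                 chunk_size = as.integer(chunk_size)),
            class = "rop_forest_config")
}

# Deterministic substream seed from (master seed, stream index, tag), kept
# below 2^31 via multiplicative mixing on a Mersenne-prime modulus.
substream_seed <- function(master, index, tag = 0L) {
  m31 <- 2147483647
  s <- (as.double(master) %% m31 + 1) * 48271 %% m31
  s <- (s + as.double(index) * 69621 + as.double(tag) * 9973) %% m31
  s <- (s * 16807) %% m31
  as.integer(s)
}

#' Plan the feature subsets of a forest
#'
#' Draws the stream of per-tree feature subsets for a configuration,
#' continuing until every feature's selection count reaches the quota (or
#' `n_trees` / `max_trees` is reached). Fully determined by the master seed.
#'
#' @param n_features_total Number of features in the dataset.
#' @param config A [forest_config()].
#' @return Integer matrix, one row per tree, `n_features_per_neuron`
#'   columns, with attributes `selection_counts` (per-feature tally of the
#'   plan) and `quota_met` (logical). If the quota is unreachable under the
#'   tree cap a warning is issued and `quota_met` is `FALSE`.
#' @examples
#' p <- plan_forest(3, forest_config(1, min_instances_per_feature = 2, seed = 7))
#' attr(p, "selection_counts")
#' @export
plan_forest <- function(n_features_total, config) {
  nf <- as.integer(n_features_total)
  n <- config$n_features_per_neuron
  if (n > nf)
    stop("n_features_per_neuron exceeds the number of features", call. = FALSE)
  quota <- config$min_instances_per_feature
  max_trees <- config$max_trees
  if (is.null(max_trees)) max_trees <- as.double(quota) * nf * 10
  exact <- config$n_trees
  if (!is.null(exact)) max_trees <- exact

  if (config$mode == "stratified") {
    sel <- config$selected
    if (is.character(sel)) stop("stratified planning needs integer feature indices; resolve names first", call. = FALSE)
    sel <- as.integer(sel)
    if (any(sel < 1L | sel > nf)) stop("selected index out of range", call. = FALSE)
    pool <- setdiff(seq_len(nf), sel)
    if (n > 1L && length(pool) < n - 1L)
      stop("unselected pool too small for stratified trees", call. = FALSE)
  }

  counts <- integer(nf)
  chunks <- list()
  n_drawn <- 0
  chunk_i <- 0L
  # quota is checked between chunks; a chunk no larger than the feature
  # count keeps the overshoot past the quota small for narrow datasets
  b_chunk <- min(config$chunk_size, max(64L, nf))
  repeat {
    if (is.null(exact) && all(counts >= quota)) break
    if (n_drawn >= max_trees) break
    chunk_i <- chunk_i + 1L
    b <- as.integer(min(b_chunk, max_trees - n_drawn))
    set.seed(substream_seed(config$seed, chunk_i, tag = 0L))
    block <- if (config$mode == "stratified") {
      s_col <- sel[sample.int(length(sel), b, replace = TRUE)]
      if (n == 1L) matrix(s_col, ncol = 1L)
      else {
        rest <- t(vapply(seq_len(b),
                         function(i) pool[sample.int(length(pool), n - 1L)],
                         integer(n - 1L)))
        cbind(s_col, rest, deparse.level = 0L)
      }
    } else if (n == 1L) {
      matrix(sample.int(nf, b, replace = TRUE), ncol = 1L)
    } else {
      t(vapply(seq_len(b), function(i) sample.int(nf, n), integer(n)))
    }
    tb <- tabulate(block, nbins = nf)
    counts <- counts + tb
    chunks[[chunk_i]] <- block
    n_drawn <- n_drawn + b
  }
  plan <- do.call(rbind, chunks)
  quota_met <- all(counts >= quota)
  if (!quota_met && is.null(exact))
    warning(sprintf("selection quota not reached for %d feature(s) within the %.0f-tree cap",
                    sum(counts < quota), max_trees), call. = FALSE)
  attr(plan, "selection_counts") <- counts
  attr(plan, "quota_met") <- quota_met
  plan
}

empty_tally <- function(feature_names) {
  nf <- length(feature_names)
  data.frame(feature = feature_names,
             times_selected = integer(nf),
             perfect_trees = integer(nf),
             all_zero = integer(nf),
             all_positive = integer(nf),
             all_negative = integer(nf),
             non_monotone = integer(nf),
             two_neuron_perfect = integer(nf),
             one_neuron_perfect = integer(nf),
             enumerable_solutions = integer(nf),
             unique_solution = integer(nf),
             stringsAsFactors = FALSE)
}

tally_columns <- c("times_selected", "perfect_trees", "all_zero",
                   "all_positive", "all_negative", "non_monotone",
                   "two_neuron_perfect", "one_neuron_perfect",
                   "enumerable_solutions", "unique_solution")

#' Build a random forest of perfect trees
#'
#' Grows one tree per planned feature subset — every tree on all
#' observations — and accumulates the per-feature event tally that the
#' information criteria are computed from. For each tree, every involved
#' feature's selection count increments; if the tree is perfect, the
#' feature's sign-profile counter (all-zero / all-positive / all-negative /
#' non-monotone; one-sign-plus-zeros profiles increment none), the
#' neuron-count counters (perfect within two neurons; within one) and the
#' solution counters (enumerable; unique) increment as well. Identical seed
#' and configuration reproduce the tally exactly.
#'
#' @param data An [rop_dataset()] with both classes present.
#' @param config A [forest_config()].
#' @param keep_trees Keep the grown `rop_tree` objects (memory-heavy; for
#'   small forests only).
#' @param log_file Optional path: one JSON line per tree (feature indices,
#'   coefficients, thresholds, finalized counts, perfection flag, sign
#'   profile, solution class).
#' @param progress Emit a progress message every 1e5 trees.
#' @return An object of class `rop_forest`: `tally` (data frame, one row
#'   per feature with the ten event counters), `n_trees`, `n_perfect`,
#'   `config`, `quota_met`, and optionally `trees`.
#' @examples
#' d <- rop_dataset(cbind(sep = c(1, 2, 3, 10, 11, 12),
#'                        noise = c(5, 1, 4, 2, 6, 3)),
#'                  c(0, 0, 0, 1, 1, 1))
#' f <- build_forest(d, forest_config(1, min_instances_per_feature = 5, seed = 42))
#' f$tally
#' @export
build_forest <- function(data, config = forest_config(), keep_trees = FALSE,
                         log_file = NULL, progress = FALSE) {
  stopifnot(inherits(data, "rop_dataset"))
  if (length(unique(data$y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (config$mode == "stratified" && is.character(config$selected))
    config$selected <- resolve_features(data, config$selected)
  nf <- ncol(data$x)
  plan <- plan_forest(nf, config)
  n_trees <- nrow(plan)

  tal <- matrix(0, nrow = nf, ncol = length(tally_columns),
                dimnames = list(NULL, tally_columns))
  trees <- if (keep_trees) vector("list", n_trees) else NULL
  con <- if (!is.null(log_file)) file(log_file, open = "wt") else NULL
  on.exit(if (!is.null(con)) close(con), add = TRUE)
  n_perfect <- 0L
  heuristic <- !is.null(config$tree$max_vectors)

  for (i in seq_len(n_trees)) {
    feats <- plan[i, ]
    if (heuristic) set.seed(substream_seed(config$seed, i, tag = 1L))
    tr <- grow_tree(data, feats, config$tree)
    tal[feats, "times_selected"] <- tal[feats, "times_selected"] + 1
    if (tr$is_perfect) {
      n_perfect <- n_perfect + 1L
      tal[feats, "perfect_trees"] <- tal[feats, "perfect_trees"] + 1
      prof <- feature_sign_profiles(tr)
      for (j in seq_along(feats)) {
        col <- switch(prof[j],
                      all_zero = "all_zero",
                      all_positive = "all_positive",
                      all_negative = "all_negative",
                      non_monotone = "non_monotone",
                      mixed_with_zero = NA_character_)
        if (!is.na(col)) tal[feats[j], col] <- tal[feats[j], col] + 1
      }
      if (tr$neurons_used <= 2L)
        tal[feats, "two_neuron_perfect"] <- tal[feats, "two_neuron_perfect"] + 1
      if (tr$neurons_used == 1L)
        tal[feats, "one_neuron_perfect"] <- tal[feats, "one_neuron_perfect"] + 1
      if (!is.na(tr$solution_class) && tr$solution_class %in% c("unique", "finite"))
        tal[feats, "enumerable_solutions"] <- tal[feats, "enumerable_solutions"] + 1
      if (!is.na(tr$solution_class) && tr$solution_class == "unique")
        tal[feats, "unique_solution"] <- tal[feats, "unique_solution"] + 1
    }
    if (keep_trees) trees[[i]] <- tr
    if (!is.null(con)) writeLines(tree_log_line(tr), con)
    if (progress && i %% 1e5L == 0L)
      message(sprintf("  %d / %d trees grown (%d perfect)", i, n_trees, n_perfect))
  }

  tally <- empty_tally(data$feature_names)
  tally[tally_columns] <- as.data.frame(tal)
  structure(list(tally = tally,
                 n_trees = n_trees,
                 n_perfect = n_perfect,
                 config = config,
                 quota_met = attr(plan, "quota_met"),
                 trees = trees),
            class = "rop_forest")
}

#' @export
print.rop_forest <- function(x, ...) {
  cat(sprintf("rop_forest: %d trees over %d features, %d perfect (%.2f%%), mode %s\n",
              x$n_trees, nrow(x$tally), x$n_perfect,
              100 * x$n_perfect / max(1L, x$n_trees), x$config$mode))
  invisible(x)
}

# one JSON-lines record per tree
tree_log_line <- function(tr) {
  jsonlite::toJSON(list(
    features = tr$features,
    neurons = lapply(tr$neurons, function(nr)
      list(coefficients = nr$coefficients, threshold = nr$threshold,
           policy = nr$policy, n_finalized = length(nr$finalized))),
    is_perfect = tr$is_perfect,
    sign_profile = tr$sign_profile,
    solution_class = tr$solution_class),
    auto_unbox = TRUE, digits = NA, null = "null")
}

#' Validate the internal consistency of a feature tally
#'
#' Asserts the counting identities every forest must satisfy: no counter
#' exceeds the perfect-tree count, the four sign-profile counters sum to at
#' most the perfect-tree count, one-neuron perfection implies two-neuron
#' perfection, and unique solutions are a subset of enumerable ones.
#'
#' @param tally A tally data frame as returned in `build_forest()$tally`.
#' @return Invisibly `TRUE`; otherwise an error naming the violated rule.
#' @export
validate_tally <- function(tally) {
  stopifnot(all(tally_columns %in% names(tally)))
  with(tally, {
    if (any(perfect_trees > times_selected))
      stop("perfect_trees exceeds times_selected", call. = FALSE)
    others <- cbind(all_zero, all_positive, all_negative, non_monotone,
                    two_neuron_perfect, one_neuron_perfect,
                    enumerable_solutions, unique_solution)
    if (any(others > perfect_trees))
      stop("an event counter exceeds perfect_trees", call. = FALSE)
    if (any(all_zero + all_positive + all_negative + non_monotone > perfect_trees))
      stop("sign-profile counters exceed perfect_trees", call. = FALSE)
    if (any(one_neuron_perfect > two_neuron_perfect))
      stop("one_neuron_perfect exceeds two_neuron_perfect", call. = FALSE)
    if (any(unique_solution > enumerable_solutions))
      stop("unique_solution exceeds enumerable_solutions", call. = FALSE)
  })
  invisible(TRUE)
}
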