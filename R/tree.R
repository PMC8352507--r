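#' Tree growth configuration
#'
#' A tree is a half Christmas tree: a fixed-depth chain of neuron nodes in
#' which each node finalizes one prediction class and reinjects the other
#' into the trunk. Depth is fixed in advance — the default three cycles of
#' two steps give at most six neurons — and no pruning is ever performed;
#' bounding the depth is the overfitting control.
#'
#' @param n_features_per_neuron Number of features randomized into every
#'   neuron of the tree.
#' @param max_cycles Number of finalization cycles; one cycle is one
#'   negative-finalizing step plus one positive-finalizing step.
#' @param steps_per_cycle Steps per cycle (default 2, one per polarity).
#' @param coefficient_range Allowed neuron coefficients; the default ternary
#'   range \{-1, 0, +1\} keeps effects directly interpretable and the
#'   per-neuron search space at `3^n`.
#' @param search_mode `"exhaustive_greedy"` (default) fits each neuron by
#'   exhaustive search over all coefficient vectors and thresholds, greedily
#'   maximizing error-free finalizations step by step.
#'   `"full_enumeration"` searches over entire neuron sequences and is exact
#'   for perfect-tree existence; it is only feasible for small problems and
#'   serves as an independent oracle.
#' @param max_vectors Optional cap on coefficient vectors examined per
#'   neuron. When set below `length(range)^n` a uniform sample of distinct
#'   vectors is searched instead of the full enumeration; the search is then
#'   explicitly non-exhaustive (trees are flagged, and solution counts refer
#'   to the sampled set only). Intended for `n >= ~8`, where `3^n` is out of
#'   reach.
#' @return An object of class `rop_tree_config`.
#' @export
tree_config <- function(n_features_per_neuron = 1L,
                        max_cycles = 3L,
                        steps_per_cycle = 2L,
                        coefficient_range = c(-1, 0, 1),
                        search_mode = c("exhaustive_greedy", "full_enumeration"),
                        max_vectors = NULL) {
  search_mode <- match.arg(search_mode)
  n <- as.integer(n_features_per_neuron)
  if (is.na(n) || n < 1L) stop("n_features_per_neuron must be >= 1", call. = FALSE)
  if (max_cycles < 1L || steps_per_cycle < 1L)
    stop("max_cycles and steps_per_cycle must be >= 1", call. = FALSE)
  range <- sort(unique(as.numeric(coefficient_range)))
  if (length(range) < 2L)
    stop("coefficient range must contain at least two values", call. = FALSE)
  if (!is.null(max_vectors) && max_vectors < 1L)
    stop("max_vectors must be >= 1 when given", call. = FALSE)
  structure(list(n_features_per_neuron = n,
                 max_cycles = as.integer(max_cycles),
                 steps_per_cycle = as.integer(steps_per_cycle),
                 coefficient_range = range,
                 search_mode = search_mode,
                 max_vectors = if (is.null(max_vectors)) NULL else as.integer(max_vectors)),
            class = "rop_tree_config")
}

max_steps_of <- function(config) config$max_cycles * config$steps_per_cycle

# Candidate coefficient vectors for one neuron under a config. Returns the
# matrix plus whether it is the complete enumeration.
candidate_vectors <- function(config) {
  n <- config$n_features_per_neuron
  total <- length(config$coefficient_range)^n
  if (is.null(config$max_vectors) || config$max_vectors >= total) {
    if (total > 2^24)
      stop(sprintf("full enumeration of %.3g coefficient vectors is infeasible; set max_vectors for a sampled search",
                   total), call. = FALSE)
    return(list(vectors = enumerate_coefficient_vectors(n, config$coefficient_range),
                exhaustive = TRUE))
  }
  # uniform sample of distinct vectors, decoded from base-|range| indices
  b <- length(config$coefficient_range)
  idx <- sample.int(total, config$max_vectors) - 1
  v <- matrix(0, nrow = length(idx), ncol = n)
  for (j in n:1) {
    v[, j] <- config$coefficient_range[(idx %% b) + 1L]
    idx <- idx %/% b
  }
  list(vectors = v, exhaustive = FALSE)
}

# One-sided best finalization for a single score vector.
# side "neg": finalized = {score <= t}, admissible iff all finalized truly 0;
# side "pos": finalized = {score > t}, admissible iff all finalized truly 1.
# Thresholds range over midpoints between distinct sorted scores plus one
# value below the minimum and one above the maximum, so every achievable
# dichotomy is considered. Returns the maximal error-free finalization.
best_side_finalization <- function(s, y, side) {
  m <- length(s)
  ord <- order(s, method = "radix")
  ss <- s[ord]
  ys <- y[ord]
  # k = number of samples at or below the threshold; valid k are group
  # boundaries of tied scores (plus 0 and m)
  valid <- c(TRUE, ss[-m] < ss[-1L], TRUE)   # validity of k = 0..m
  if (side == "neg") {
    ok <- c(TRUE, cumsum(ys) == 0L)          # prefix of k all truly class 0
    k <- max(which(valid & ok)) - 1L
    count <- k
    idx <- if (k > 0L) ord[seq_len(k)] else integer(0)
  } else {
    zeros_after <- rev(cumsum(rev(1L - ys))) # zeros in suffix starting at k+1
    ok <- c(zeros_after == 0L, TRUE)         # suffix after k all truly class 1
    k <- min(which(valid & ok)) - 1L
    count <- m - k
    idx <- if (count > 0L) ord[(k + 1L):m] else integer(0)
  }
  threshold <- if (k == 0L) ss[1L] - 1 else if (k == m) ss[m] + 1
               else (ss[k] + ss[k + 1L]) / 2
  list(count = count, threshold = unname(threshold), idx = idx)
}

# Error-free dichotomy of the whole active set by one neuron, if any:
# sorted labels must form a 0-block then a 1-block split at a boundary of
# distinct scores. Returns the threshold or NULL.
full_split_threshold <- function(s, y) {
  m <- length(s)
  ord <- order(s, method = "radix")
  ss <- s[ord]
  ys <- y[ord]
  if (is.unsorted(ys)) return(NULL)
  k0 <- sum(ys == 0L)
  if (k0 > 0L && k0 < m && ss[k0] >= ss[k0 + 1L]) return(NULL)
  unname(if (k0 == 0L) ss[1L] - 1 else if (k0 == m) ss[m] + 1
         else (ss[k0] + ss[k0 + 1L]) / 2)
}

#' Fit one neuron step of a half Christmas tree
#'
#' Searches every candidate coefficient vector and every achievable
#' threshold for the neuron that finalizes the largest number of active
#' samples with zero false finalizations. Under `"finalize_negative"` the
#' predicted-negative samples are finalized as class 0 and a candidate is
#' admissible only if all of them truly are class 0; symmetric for
#' `"finalize_positive"`. An empty finalization is a legal result.
#'
#' Ties among equally optimal coefficient vectors break to the first in
#' lexicographic enumeration order (-1 < 0 < +1); for a given vector the
#' smallest optimal threshold is kept. Determinism of these tie-breaks is
#' what makes forests reproducible.
#'
#' @param data An [rop_dataset()].
#' @param features Feature indices or names defining the neuron's inputs.
#' @param active Integer vector of active sample indices.
#' @param policy `"finalize_negative"` or `"finalize_positive"`.
#' @param config A [tree_config()].
#' @return A list: `coefficients`, `threshold`, `finalized` (absolute sample
#'   indices), `assigned` (the finalized label), `count`, and `n_optimal` —
#'   the number of distinct coefficient vectors attaining the maximum, or
#'   `Inf` when every enumerated vector attains it (the unconstrained case).
#' @export
fit_neuron_step <- function(data, features, active,
                            policy = c("finalize_negative", "finalize_positive"),
                            config = tree_config(length(features))) {
  policy <- match.arg(policy)
  features <- resolve_features(data, features)
  cv <- candidate_vectors(config)
  st <- step_search(data$x[, features, drop = FALSE], data$y, active,
                    if (policy == "finalize_negative") "neg" else "pos",
                    cv$vectors)
  st$policy <- policy
  st$assigned <- if (policy == "finalize_negative") 0L else 1L
  st$exhaustive <- cv$exhaustive
  st
}

# workhorse shared by fit_neuron_step and grow_tree; x restricted to the
# tree's features, absolute sample indexing
step_search <- function(x, y, active, side, vectors) {
  if (length(active) == 0L) stop("active sample set is empty", call. = FALSE)
  s_all <- x[active, , drop = FALSE] %*% t(vectors)   # samples x vectors
  ya <- y[active]
  best <- NULL
  best_count <- -1L
  n_attain <- 0L
  for (v in seq_len(nrow(vectors))) {
    r <- best_side_finalization(s_all[, v], ya, side)
    if (r$count > best_count) {
      best_count <- r$count
      best <- list(v = v, r = r)
      n_attain <- 1L
    } else if (r$count == best_count) {
      n_attain <- n_attain + 1L
    }
  }
  list(coefficients = vectors[best$v, ],
       threshold = best$r$threshold,
       finalized = active[best$r$idx],
       count = best_count,
       n_optimal = if (n_attain == nrow(vectors)) Inf else n_attain)
}

# search for a neuron splitting the whole active set without error
both_search <- function(x, y, active, vectors) {
  s_all <- x[active, , drop = FALSE] %*% t(vectors)
  ya <- y[active]
  best <- NULL
  n_attain <- 0L
  for (v in seq_len(nrow(vectors))) {
    t0 <- full_split_threshold(s_all[, v], ya)
    if (!is.null(t0)) {
      n_attain <- n_attain + 1L
      if (is.null(best)) best <- list(v = v, threshold = t0)
    }
  }
  if (is.null(best)) return(NULL)
  list(coefficients = vectors[best$v, ],
       threshold = best$threshold,
       finalized = active,
       count = length(active),
       n_optimal = if (n_attain == nrow(vectors)) Inf else n_attain)
}

resolve_features <- function(data, features) {
  if (is.character(features)) {
    idx <- match(features, data$feature_names)
    if (anyNA(idx))
      stop(sprintf("unknown feature: %s", features[is.na(idx)][1L]), call. = FALSE)
    return(idx)
  }
  features <- as.integer(features)
  if (length(features) == 0L) stop("empty feature subset", call. = FALSE)
  if (any(features < 1L | features > ncol(data$x)))
    stop("feature index out of range", call. = FALSE)
  features
}

#' Grow a single tree of neuron nodes over a fixed feature subset
#'
#' Steps alternate finalization polarity, starting with the negative side:
#' each neuron finalizes its error-free side and reinjects the surviving
#' samples into the trunk as the next step's active set. Before every step
#' the grower first checks whether some neuron classifies the entire active
#' set without error; if so it is applied with both sides finalized and the
#' tree terminates. The tree is perfect when the active set empties within
#' the step budget — by construction every finalized label then equals the
#' truth, i.e. sensitivity and specificity are both 100%. Neurons that
#' finalize zero samples still consume a step.
#'
#' @param data An [rop_dataset()].
#' @param features The tree's feature subset (indices or names); its length
#'   must equal `config$n_features_per_neuron`.
#' @param config A [tree_config()]. With `search_mode = "full_enumeration"`
#'   the grower instead searches all neuron sequences (all coefficient
#'   vectors x all threshold dichotomies at every step, with memoization on
#'   the residual active set) and returns a witness tree iff a perfect tree
#'   exists — exact, but only feasible for small problems.
#' @return An object of class `rop_tree`: `features`, `neurons` (each with
#'   `coefficients`, `threshold`, `policy`, `finalized`, `assigned`,
#'   `n_optimal`), `neurons_used`, `is_perfect`, `solution_class`
#'   (`"unique"`, `"finite"` or `"unconstrained"`), `solution_multiplicity`,
#'   `sign_profile`, and `exhaustive`.
#' @examples
#' d <- rop_dataset(matrix(1:4, ncol = 1), c(0, 0, 1, 1))
#' grow_tree(d, 1)
#' @export
grow_tree <- function(data, features, config = tree_config(length(features))) {
  features <- resolve_features(data, features)
  if (length(features) != config$n_features_per_neuron)
    stop("feature subset size must equal n_features_per_neuron", call. = FALSE)
  if (config$search_mode == "full_enumeration")
    return(grow_tree_enum(data, features, config))

  x <- data$x[, features, drop = FALSE]
  y <- data$y
  m <- nrow(x)
  cv <- candidate_vectors(config)
  vectors <- cv$vectors
  active <- seq_len(m)
  neurons <- list()
  for (step in seq_len(max_steps_of(config))) {
    bs <- both_search(x, y, active, vectors)
    if (!is.null(bs)) {
      bs$policy <- "finalize_both"
      bs$assigned <- y[active]
      neurons[[step]] <- bs
      active <- integer(0)
      break
    }
    side <- if (step %% 2L == 1L) "neg" else "pos"
    st <- step_search(x, y, active, side, vectors)
    st$policy <- if (side == "neg") "finalize_negative" else "finalize_positive"
    st$assigned <- if (side == "neg") 0L else 1L
    neurons[[step]] <- st
    active <- setdiff(active, st$finalized)
    if (length(active) == 0L) break
  }
  finish_tree(features, data$feature_names[features], neurons,
              is_perfect = length(active) == 0L, n_samples = m,
              exhaustive = cv$exhaustive, search_mode = "exhaustive_greedy")
}

finish_tree <- function(features, feature_names, neurons, is_perfect,
                        n_samples, exhaustive, search_mode) {
  coefs <- do.call(rbind, lapply(neurons, `[[`, "coefficients"))
  counts <- vapply(neurons, function(nr) as.double(nr$n_optimal), double(1))
  if (is_perfect && !anyNA(counts)) {
    mult <- prod(counts)
    sclass <- if (any(is.infinite(counts))) "unconstrained"
              else if (mult == 1) "unique" else "finite"
  } else {
    mult <- NA_real_
    sclass <- NA_character_
  }
  structure(list(features = features,
                 feature_names = feature_names,
                 neurons = neurons,
                 neurons_used = length(neurons),
                 is_perfect = is_perfect,
                 n_samples = n_samples,
                 per_neuron_solution_count = counts,
                 solution_class = sclass,
                 solution_multiplicity = mult,
                 sign_profile = classify_signs(as.numeric(coefs)),
                 exhaustive = exhaustive,
                 search_mode = search_mode),
            class = "rop_tree")
}

#' @export
print.rop_tree <- function(x, ...) {
  cat(sprintf("rop_tree over %d feature(s): %s, %d neuron(s), %s\n",
              length(x$features), paste(x$feature_names, collapse = ", "),
              x$neurons_used,
              if (x$is_perfect) sprintf("PERFECT (solutions: %s)", x$solution_class)
              else "imperfect"))
  invisible(x)
}

# ---- exact full-enumeration search (test oracle) --------------------------

# All distinct admissible finalization residuals for one side step: for every
# vector, every valid threshold position whose finalized side is error-free.
admissible_residuals <- function(x, y, active, side, vectors) {
  s_all <- x[active, , drop = FALSE] %*% t(vectors)
  ya <- y[active]
  m <- length(active)
  seen <- new.env(parent = emptyenv())
  out <- list()
  for (v in seq_len(nrow(vectors))) {
    s <- s_all[, v]
    ord <- order(s, method = "radix")
    ss <- s[ord]
    ys <- ya[ord]
    valid <- c(TRUE, ss[-m] < ss[-1L], TRUE)
    if (side == "neg") {
      ok <- c(TRUE, cumsum(ys) == 0L)
      ks <- which(valid & ok) - 1L
      for (k in ks) {
        res <- if (k == 0L) active else active[-match(ord[seq_len(k)], seq_len(m))]
        res <- sort(res)
        key <- paste(res, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1L]] <- list(
            residual = res, v = v,
            threshold = if (k == 0L) ss[1L] - 1 else if (k == m) ss[m] + 1
                        else (ss[k] + ss[k + 1L]) / 2,
            finalized = active[ord[seq_len(k)]])
        }
      }
    } else {
      zeros_after <- rev(cumsum(rev(1L - ys)))
      ok <- c(zeros_after == 0L, TRUE)
      ks <- which(valid & ok) - 1L
      for (k in ks) {
        fin <- if (k < m) ord[(k + 1L):m] else integer(0)
        res <- sort(active[setdiff(seq_len(m), fin)])
        key <- paste(res, collapse = ",")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          out[[length(out) + 1L]] <- list(
            residual = res, v = v,
            threshold = if (k == 0L) ss[1L] - 1 else if (k == m) ss[m] + 1
                        else (ss[k] + ss[k + 1L]) / 2,
            finalized = active[fin])
        }
      }
    }
  }
  # larger finalizations first: deepest peels explored first
  out[order(vapply(out, function(o) length(o$residual), integer(1)))]
}

grow_tree_enum <- function(data, features, config) {
  x <- data$x[, features, drop = FALSE]
  y <- data$y
  m <- nrow(x)
  vectors <- enumerate_coefficient_vectors(config$n_features_per_neuron,
                                           config$coefficient_range)
  memo <- new.env(parent = emptyenv())
  max_steps <- max_steps_of(config)

  rec <- function(active, step) {
    if (step > max_steps) return(NULL)
    key <- paste0(step, ":", paste(active, collapse = ","))
    hit <- memo[[key]]
    if (!is.null(hit)) return(if (identical(hit, FALSE)) NULL else hit)
    bs <- both_search(x, y, active, vectors)
    if (!is.null(bs)) {
      bs$policy <- "finalize_both"
      bs$assigned <- y[active]
      bs$n_optimal <- NA_real_
      memo[[key]] <- list(bs)
      return(list(bs))
    }
    side <- if (step %% 2L == 1L) "neg" else "pos"
    for (cand in admissible_residuals(x, y, active, side, vectors)) {
      if (length(cand$residual) == 0L || length(cand$residual) < length(active)) {
        tail_neurons <- if (length(cand$residual) == 0L) list()
                        else rec(cand$residual, step + 1L)
        if (!is.null(tail_neurons) || length(cand$residual) == 0L) {
          nr <- list(coefficients = vectors[cand$v, ],
                     threshold = cand$threshold,
                     finalized = cand$finalized,
                     count = length(cand$finalized),
                     n_optimal = NA_real_,
                     policy = if (side == "neg") "finalize_negative" else "finalize_positive",
                     assigned = if (side == "neg") 0L else 1L)
          res <- c(list(nr), tail_neurons)
          memo[[key]] <- res
          return(res)
        }
      } else if (length(cand$residual) == length(active)) {
        # a wasted step: only useful to flip polarity
        tail_neurons <- rec(cand$residual, step + 1L)
        if (!is.null(tail_neurons)) {
          nr <- list(coefficients = vectors[cand$v, ],
                     threshold = cand$threshold,
                     finalized = integer(0), count = 0L,
                     n_optimal = NA_real_,
                     policy = if (side == "neg") "finalize_negative" else "finalize_positive",
                     assigned = if (side == "neg") 0L else 1L)
          res <- c(list(nr), tail_neurons)
          memo[[key]] <- res
          return(res)
        }
      }
    }
    memo[[key]] <- FALSE
    NULL
  }

  witness <- rec(seq_len(m), 1L)
  if (is.null(witness)) {
    finish_tree(features, data$feature_names[features], list(),
                is_perfect = FALSE, n_samples = m, exhaustive = TRUE,
                search_mode = "full_enumeration")
  } else {
    finish_tree(features, data$feature_names[features], witness,
                is_perfect = TRUE, n_samples = m, exhaustive = TRUE,
                search_mode = "full_enumeration")
  }
}

#' Does any perfect tree exist over a feature subset?
#'
#' Exact answer by full enumeration of neuron sequences; see
#' [grow_tree()] with `search_mode = "full_enumeration"`.
#'
#' @inheritParams grow_tree
#' @return Logical.
#' @export
perfect_tree_exists <- function(data, features, config = tree_config(length(features))) {
  config$search_mode <- "full_enumeration"
  grow_tree(data, features, config)$is_perfect
}

# ---- verification, sign profile, solution counting ------------------------

#' Independently verify that a tree is perfect
#'
#' Re-checks a grown tree against the truth without reusing the growth code
#' path: finalized sets must be pairwise disjoint, cover every sample, and
#' carry assigned labels identical to the true labels (sensitivity and
#' specificity both 100%). When `data` is supplied, each neuron's
#' predictions are additionally recomputed from the raw feature values and
#' compared to the recorded finalizations.
#'
#' @param tree An `rop_tree`.
#' @param truth Integer 0/1 vector of true labels.
#' @param data Optional [rop_dataset()] for the full replay.
#' @return Logical.
#' @export
verify_perfect <- function(tree, truth, data = NULL) {
  fin <- unlist(lapply(tree$neurons, `[[`, "finalized"))
  if (anyDuplicated(fin) > 0L) return(FALSE)
  if (length(fin) != tree$n_samples || !setequal(fin, seq_len(tree$n_samples)))
    return(FALSE)
  assigned <- integer(tree$n_samples)
  for (nr in tree$neurons) assigned[nr$finalized] <- nr$assigned
  tp <- sum(assigned == 1L & truth == 1L); fp <- sum(assigned == 1L & truth == 0L)
  tn <- sum(assigned == 0L & truth == 0L); fn <- sum(assigned == 0L & truth == 1L)
  if (fp > 0L || fn > 0L) return(FALSE)
  if (sum(truth == 1L) > 0L && tp / sum(truth == 1L) != 1) return(FALSE)
  if (sum(truth == 0L) > 0L && tn / sum(truth == 0L) != 1) return(FALSE)
  if (!is.null(data)) {
    active <- seq_len(tree$n_samples)
    xm <- data$x[, tree$features, drop = FALSE]
    for (nr in tree$neurons) {
      sc <- numeric(length(active))
      for (i in seq_along(active))   # deliberately plain replay
        sc[i] <- sum(xm[active[i], ] * nr$coefficients)
      pred <- as.integer(sc > nr$threshold)
      fin_i <- switch(nr$policy,
                      finalize_negative = active[pred == 0L],
                      finalize_positive = active[pred == 1L],
                      finalize_both = active)
      if (!setequal(fin_i, nr$finalized)) return(FALSE)
      if (nr$policy == "finalize_both" &&
          !all(pred == truth[active])) return(FALSE)
      active <- setdiff(active, fin_i)
    }
    if (length(active) != 0L) return(FALSE)
  }
  TRUE
}

# classify a flat coefficient vector into the five sign categories
classify_signs <- function(coefs) {
  if (length(coefs) == 0L) return(NA_character_)
  has_pos <- any(coefs > 0); has_neg <- any(coefs < 0); has_zero <- any(coefs == 0)
  if (!has_pos && !has_neg) "all_zero"
  else if (has_pos && has_neg) "non_monotone"
  else if (has_pos && !has_zero) "all_positive"
  else if (has_neg && !has_zero) "all_negative"
  else "mixed_with_zero"
}

#' Sign profile of a tree's coefficients
#'
#' Classifies coefficients into one of five mutually exclusive, exhaustive
#' categories: `"all_zero"` (the feature never contributes — a potential
#' confounder or intermediate), `"all_positive"` / `"all_negative"`
#' (consistent risk / protective direction), `"non_monotone"` (both signs
#' occur — a within-tree interaction signature), or `"mixed_with_zero"` (one
#' sign plus zeros; counted in none of the first four).
#'
#' @param x An `rop_tree` (all coefficients of all used neurons pooled) or a
#'   numeric vector/matrix of coefficients.
#' @return A single category string.
#' @seealso [feature_sign_profiles()] for the per-feature classification a
#'   forest tallies.
#' @export
sign_profile <- function(x) {
  if (inherits(x, "rop_tree"))
    x <- unlist(lapply(x$neurons, `[[`, "coefficients"))
  classify_signs(as.numeric(x))
}

#' Per-feature sign profiles within one tree
#'
#' For each of the tree's features, classifies that feature's coefficient
#' across all used neurons (the column of the coefficient matrix). This is
#' the classification a forest accumulates per feature.
#'
#' @param tree An `rop_tree`.
#' @return Character vector, one category per tree feature, named by the
#'   feature names.
#' @export
feature_sign_profiles <- function(tree) {
  coefs <- do.call(rbind, lapply(tree$neurons, `[[`, "coefficients"))
  out <- vapply(seq_along(tree$features),
                function(j) classify_signs(coefs[, j]), character(1))
  names(out) <- tree$feature_names
  out
}

#' Solution multiplicity of a perfect tree
#'
#' The number of distinct coefficient-vector sequences attaining the grown
#' tree (thresholds form continuous intervals and are never counted): the
#' product of per-neuron optimal-vector counts. `"unique"` when the product
#' is 1, `"finite"` otherwise, and `"unconstrained"` when any neuron's
#' optimum is attained by every enumerated vector (the model does not
#' converge on a solution — the analogue of infinitely many solutions).
#'
#' @param tree A perfect `rop_tree` grown in greedy mode.
#' @return A list with `class` (`"unique"`, `"finite"`, `"unconstrained"`)
#'   and `multiplicity` (`Inf` when unconstrained).
#' @export
count_solutions <- function(tree) {
  if (!isTRUE(tree$is_perfect))
    stop("solution counting is defined only for perfect trees", call. = FALSE)
  counts <- tree$per_neuron_solution_count
  if (anyNA(counts))
    stop("solution counts are not available for full-enumeration witnesses",
         call. = FALSE)
  if (any(is.infinite(counts))) return(list(class = "unconstrained", multiplicity = Inf))
  mult <- prod(counts)
  list(class = if (mult == 1) "unique" else "finite", multiplicity = mult)
}
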