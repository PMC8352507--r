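#' Compute the ten information criteria from a forest tally
#'
#' Converts per-feature event counts into the ten criteria, proportions in
#' \[0, 1\] describing three dimensions of a feature's relation to the
#' outcome:
#'
#' * predictive quality — `nic1`, the probability of an error-free
#'   classification when the feature is drawn (perfect trees / selections);
#'   `nic2`, all coefficients zero in all neurons (no independent
#'   information — a potential confounder or intermediate); `nic3` / `nic4`,
#'   consistently positive / negative coefficients (risk / protection);
#'   `nic5 = nic3 x nic4`, the between-tree paradoxical-effect product;
#'   `nic6`, non-monotone coefficients within a tree (interaction signature);
#' * proximity to the outcome — `nic7` / `nic8`, perfection within two
#'   neurons / one neuron;
#' * complexity — `nic9`, an enumerable (non-infinite) solution set;
#'   `nic10`, a unique solution.
#'
#' `nic1` divides by the selection count; all other ratios divide by the
#' perfect-tree count. Features never involved in a perfect tree are flagged
#' `no_pt` with all criteria set to 0: such features are deliberately kept —
#' a feature with no perfect tree (or with all-zero coefficients) may still
#' be an essential intermediate, so it is retained and ranked last rather
#' than dropped.
#'
#' @param tally Tally data frame from [build_forest()] (or hand-built with
#'   the same columns). Every `times_selected` must be positive.
#' @param min_gap Gap threshold forwarded to [select_by_gap()] when ranking.
#' @return A `nic_table` data frame: `feature`, `nic1`..`nic10`, `no_pt`,
#'   `nic_score`, `hierarchical_rank`, `score_rank`.
#' @examples
#' tal <- data.frame(feature = "BBOX1", times_selected = 160L,
#'                   perfect_trees = 160L, all_zero = 0L, all_positive = 160L,
#'                   all_negative = 0L, non_monotone = 0L,
#'                   two_neuron_perfect = 160L, one_neuron_perfect = 160L,
#'                   enumerable_solutions = 160L, unique_solution = 160L)
#' compute_nics(tal)
#' @export
compute_nics <- function(tally, min_gap = 1) {
  validate_tally(tally)
  if (any(tally$times_selected <= 0L))
    stop("every feature must have been selected at least once", call. = FALSE)
  pt <- tally$perfect_trees
  denom <- ifelse(pt > 0L, pt, 1L)   # no_pt rows are zeroed below anyway
  out <- data.frame(
    feature = tally$feature,
    nic1 = tally$perfect_trees / tally$times_selected,
    nic2 = tally$all_zero / denom,
    nic3 = tally$all_positive / denom,
    nic4 = tally$all_negative / denom,
    nic6 = tally$non_monotone / denom,
    nic7 = tally$two_neuron_perfect / denom,
    nic8 = tally$one_neuron_perfect / denom,
    nic9 = tally$enumerable_solutions / denom,
    nic10 = tally$unique_solution / denom,
    stringsAsFactors = FALSE)
  out$nic5 <- out$nic3 * out$nic4
  out$no_pt <- pt == 0L
  zero_cols <- c("nic2", "nic3", "nic4", "nic5", "nic6", "nic7", "nic8",
                 "nic9", "nic10")
  out[out$no_pt, zero_cols] <- 0
  out <- out[, c("feature", paste0("nic", 1:10), "no_pt")]
  out$nic_score <- nic_score(out)
  hr <- hierarchical_rank(out)
  out$hierarchical_rank <- match(out$feature, hr)
  sr <- hierarchical_rank(out, keys = "nic_score")
  out$score_rank <- match(out$feature, sr)
  class(out) <- c("nic_table", "data.frame")
  out
}

#' Composite score over the three criterion dimensions
#'
#' `nic1 - nic2 - nic6 + nic8 + nic9 + nic10`: predictive quality rewarded
#' and penalized by the null-information and interaction probabilities, plus
#' the proximity and complexity criteria. `nic5` is excluded (its
#' rescaling to a 0–100% range is not defined) and `nic7` is excluded as
#' nested within `nic8`. The score lies in \[-2, 4\]; 4 is attained only by
#' features that are always perfect, single-neuron and unique-solution. Full
#' precision is kept internally; tables print two decimals.
#'
#' @param table A `nic_table` (or any data frame with the `nic*` columns).
#' @return Numeric vector of scores.
#' @export
nic_score <- function(table) {
  with(table, nic1 - nic2 - nic6 + nic8 + nic9 + nic10)
}

nic_rank_keys <- function(table) {
  list(one_minus_nic2 = 1 - table$nic2,
       nic1 = table$nic1, nic2 = table$nic2, nic3 = table$nic3,
       nic4 = table$nic4, nic5 = table$nic5, nic6 = table$nic6,
       nic7 = table$nic7, nic8 = table$nic8, nic9 = table$nic9,
       nic10 = table$nic10,
       nic_score = if ("nic_score" %in% names(table)) table$nic_score
                   else nic_score(table))
}

#' Hierarchical feature ranking
#'
#' Stable descending lexicographic sort on a sequence of criterion keys; the
#' default order `(1 - nic2, nic1, nic10, nic8)` gives performance the lead,
#' then uniqueness, then single-neuron proximity. Features flagged `no_pt`
#' always rank last (they carry no criterion information but are preserved);
#' remaining ties keep input order.
#'
#' @param table A `nic_table`.
#' @param keys Character vector of key names drawn from `"one_minus_nic2"`,
#'   `"nic1"`..`"nic10"`, `"nic_score"`.
#' @return Character vector of feature identifiers, best first.
#' @export
hierarchical_rank <- function(table,
                              keys = c("one_minus_nic2", "nic1", "nic10", "nic8")) {
  avail <- nic_rank_keys(table)
  bad <- setdiff(keys, names(avail))
  if (length(bad))
    stop(sprintf("unknown ranking key: %s", bad[1L]), call. = FALSE)
  no_pt <- if ("no_pt" %in% names(table)) table$no_pt else rep(FALSE, nrow(table))
  ord_args <- c(list(no_pt), lapply(avail[keys], function(k) -k))
  ord_args$method <- "radix"   # stable
  ord <- do.call(order, ord_args)
  as.character(table$feature[ord])
}

#' Select features by the first clear score gap
#'
#' Sorts scores descending and cuts at the first consecutive drop of at
#' least `min_gap`, returning the features above the cut. With no such drop,
#' all features are returned and the result is flagged `no_gap`.
#'
#' @param scores Named numeric vector (names are feature identifiers), or a
#'   `nic_table` whose `nic_score` column is used.
#' @param min_gap Minimum consecutive difference treated as a gap
#'   (default 1).
#' @return A list: `selected` (character vector, best first), `no_gap`
#'   (logical), `cut` (number selected), `threshold` (score of the last
#'   selected feature, `NA` when empty).
#' @examples
#' select_by_gap(c(a = 4, b = 4, c = 2, d = 1.5))
#' @export
select_by_gap <- function(scores, min_gap = 1) {
  if (min_gap <= 0) stop("min_gap must be positive", call. = FALSE)
  if (inherits(scores, "nic_table") ||
      (is.data.frame(scores) && all(c("feature", "nic_score") %in% names(scores))))
    scores <- stats::setNames(scores$nic_score, scores$feature)
  if (length(scores) == 0L)
    return(list(selected = character(0), no_gap = FALSE, cut = 0L,
                threshold = NA_real_))
  ord <- order(-scores, method = "radix")
  s <- scores[ord]
  gaps <- which(-diff(s) >= min_gap)
  if (length(gaps) == 0L)
    return(list(selected = names(s), no_gap = TRUE, cut = length(s),
                threshold = unname(s[length(s)])))
  cut <- gaps[1L]
  list(selected = names(s)[seq_len(cut)], no_gap = FALSE, cut = cut,
       threshold = unname(s[cut]))
}
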