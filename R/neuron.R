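#' Enumerate all ternary coefficient vectors of a neuron
#'
#' A neuron over `n` features carries one coefficient per feature, each drawn
#' from a small finite range — by default \{-1, 0, +1\}, the restriction that
#' keeps the model robust, directly interpretable (each feature acts as risk,
#' protection or silence) and cheap: a neuron has exactly `3^n` candidate
#' coefficient vectors.
#'
#' @param n Number of features per neuron (non-negative integer).
#' @param range Finite set of allowed coefficient values.
#' @return A numeric matrix with `length(range)^n` rows and `n` columns,
#'   rows in lexicographic order with the range sorted ascending (so for the
#'   default range the first row is all -1 and the last all +1). `n = 0`
#'   yields a single empty vector (one row, zero columns).
#' @examples
#' enumerate_coefficient_vectors(2)
#' @export
enumerate_coefficient_vectors <- function(n, range = c(-1, 0, 1)) {
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    stop("n must be a single non-negative integer", call. = FALSE)
  range <- sort(unique(as.numeric(range)))
  if (length(range) == 0L) stop("coefficient range must be nonempty", call. = FALSE)
  n <- as.integer(n)
  if (n == 0L) return(matrix(numeric(0), nrow = 1L, ncol = 0L))
  g <- expand.grid(rep(list(range), n), KEEP.OUT.ATTRS = FALSE)
  # expand.grid varies the first column fastest; lexicographic order needs
  # the first coordinate slowest, so reverse the column roles
  m <- as.matrix(g[, rev(seq_len(n)), drop = FALSE])
  dimnames(m) <- NULL
  m
}

#' Threshold candidates for a score vector
#'
#' Midpoints between consecutive distinct sorted scores, plus one value below
#' the minimum and one above the maximum. This finite set realizes every
#' dichotomy of the samples achievable by thresholding the scores, so an
#' exhaustive search over it is an exhaustive search over all dichotomies.
#'
#' @param scores Numeric vector of projection scores.
#' @return Numeric vector of candidate thresholds, ascending.
#' @export
candidate_thresholds <- function(scores) {
  u <- sort(unique(scores))
  if (length(u) == 0L) stop("no scores supplied", call. = FALSE)
  if (length(u) == 1L) return(c(u - 1, u + 1))
  c(u[1L] - 1, (u[-1L] + u[-length(u)]) / 2, u[length(u)] + 1)
}

#' Predict with a single neuron
#'
#' Each sample's projection score is the coefficient-weighted sum of its
#' feature values; the neuron classifies a sample positive when the score
#' strictly exceeds the threshold (ties go negative).
#'
#' @param coefficients Numeric coefficient vector, one entry per feature
#'   column of `x`.
#' @param threshold Real threshold on the projection score.
#' @param x Numeric matrix (samples x features), restricted to the neuron's
#'   features.
#' @param active Optional integer vector of sample indices to predict for;
#'   defaults to all rows.
#' @return Integer vector of predicted labels (0/1) named by the active
#'   indices.
#' @examples
#' neuron_predict(c(1, -1), 0, rbind(c(3, 1), c(1, 3)))
#' @export
neuron_predict <- function(coefficients, threshold, x, active = NULL) {
  x <- as.matrix(x)
  if (length(coefficients) != ncol(x))
    stop("coefficient vector length must equal feature count", call. = FALSE)
  if (is.null(active)) active <- seq_len(nrow(x))
  if (length(active) == 0L) stop("active sample set is empty", call. = FALSE)
  xa <- x[active, , drop = FALSE]
  if (anyNA(xa)) stop("missing value in feature data", call. = FALSE)
  s <- drop(xa %*% coefficients)
  out <- as.integer(s > threshold)
  names(out) <- active
  out
}
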