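#' Binary-outcome feature table
#'
#' Container for a complete real-valued feature matrix plus a binary outcome,
#' the universe a forest of perfect trees samples from. Observations are never
#' bootstrapped: every tree sees all samples exactly once, so the container is
#' validated strictly up front — missing values are rejected (the perfect-tree
#' calculus has no notion of a central value to impute towards).
#'
#' @param x Numeric matrix, samples in rows, features in columns.
#' @param y Outcome vector with one value per sample, coded 0/1 (logicals and
#'   two-level factors are accepted and recoded).
#' @param feature_names,sample_names Optional identifiers; default to the
#'   matrix dimnames, then to `f1..fp` / `s1..sn`.
#' @param require_both_classes If `TRUE` (default), reject single-class
#'   outcomes; forest building is meaningless without both classes.
#'
#' @return An object of class `rop_dataset`: a list with elements `x`
#'   (numeric matrix with dimnames set), `y` (integer 0/1), `feature_names`
#'   and `sample_names`.
#' @examples
#' d <- rop_dataset(matrix(rnorm(40), 10, 4), rep(c(0, 1), each = 5))
#' d
#' @export
rop_dataset <- function(x, y, feature_names = NULL, sample_names = NULL,
                        require_both_classes = TRUE) {
  x <- as.matrix(x)
  if (!is.numeric(x))
    stop("feature matrix must be numeric", call. = FALSE)
  if (anyNA(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-finite value at sample %d, feature %d: missing data are not supported",
                 bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.factor(y)) {
    if (nlevels(y) != 2L)
      stop("factor outcome must have exactly two levels", call. = FALSE)
    y <- as.integer(y) - 1L
  }
  if (is.logical(y)) y <- as.integer(y)
  if (anyNA(y)) stop("outcome contains missing values", call. = FALSE)
  if (!all(y %in% c(0, 1)))
    stop("outcome must be coded 0/1", call. = FALSE)
  y <- as.integer(y)
  if (length(y) != nrow(x))
    stop(sprintf("outcome length (%d) does not match sample count (%d)",
                 length(y), nrow(x)), call. = FALSE)
  if (require_both_classes && length(unique(y)) < 2L)
    stop("both outcome classes must be present", call. = FALSE)
  if (is.null(feature_names)) feature_names <- colnames(x)
  if (is.null(feature_names)) feature_names <- paste0("f", seq_len(ncol(x)))
  if (is.null(sample_names)) sample_names <- rownames(x)
  if (is.null(sample_names)) sample_names <- paste0("s", seq_len(nrow(x)))
  if (length(feature_names) != ncol(x) || anyDuplicated(feature_names))
    stop("feature names must be unique and match the feature count", call. = FALSE)
  if (length(sample_names) != nrow(x))
    stop("sample names must match the sample count", call. = FALSE)
  dimnames(x) <- list(sample_names, feature_names)
  structure(list(x = x, y = y,
                 feature_names = as.character(feature_names),
                 sample_names = as.character(sample_names)),
            class = "rop_dataset")
}

#' @export
print.rop_dataset <- function(x, ...) {
  cat(sprintf("rop_dataset: %d samples x %d features (outcome 1: %d, 0: %d)\n",
              nrow(x$x), ncol(x$x), sum(x$y == 1L), sum(x$y == 0L)))
  invisible(x)
}

#' @export
dim.rop_dataset <- function(x) dim(x$x)
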