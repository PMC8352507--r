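#' Confusion-matrix metrics for binary predictions
#'
#' Matthews correlation coefficient, classification accuracy, sensitivity
#' and specificity. MCC is `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`,
#' with the convention MCC = 0 when any denominator factor is zero (e.g.
#' all samples predicted one class). Sensitivity/specificity are `NA` when
#' a class is absent from the truth.
#'
#' @param truth,predicted Equal-length 0/1 vectors.
#' @return Named numeric vector: `mcc`, `ca`, `sensitivity`, `specificity`.
#' @examples
#' confusion_metrics(c(1, 1, 0, 0), c(1, 0, 0, 0))
#' @export
confusion_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (length(truth) == 0L) stop("empty input", call. = FALSE)
  truth <- as.integer(truth); predicted <- as.integer(predicted)
  tp <- sum(truth == 1L & predicted == 1L)
  tn <- sum(truth == 0L & predicted == 0L)
  fp <- sum(truth == 0L & predicted == 1L)
  fn <- sum(truth == 1L & predicted == 0L)
  den <- as.double(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (as.double(tp) * tn - as.double(fp) * fn) / sqrt(den)
  c(mcc = mcc,
    ca = (tp + tn) / length(truth),
    sensitivity = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_)
}

#' Repeated stratified cross-validation protocol
#'
#' @param folds Number of folds (default 3), stratified by class.
#' @param repeats Number of repeats (default 20).
#' @param seed Seed; folds are identical across every feature set and
#'   classifier compared under the same protocol.
#' @param classifiers Any of `"logistic"`, `"svm"` (quadratic-kernel
#'   max-margin, via e1071), `"rf"` (random forest, via randomForest).
#' @return An object of class `cv_protocol`.
#' @export
cv_protocol <- function(folds = 3L, repeats = 20L, seed = 1L,
                        classifiers = c("logistic", "svm", "rf")) {
  if (folds < 2L) stop("folds must be >= 2", call. = FALSE)
  if (repeats < 1L) stop("repeats must be >= 1", call. = FALSE)
  classifiers <- match.arg(classifiers, several.ok = TRUE)
  structure(list(folds = as.integer(folds), repeats = as.integer(repeats),
                 seed = as.integer(seed), classifiers = classifiers),
            class = "cv_protocol")
}

# Stratified fold assignment; regenerated from the next substream (logged)
# if any training fold would be single-class.
make_folds <- function(y, folds, seed, repeat_i) {
  for (attempt in 0:50) {
    set.seed(substream_seed(seed, repeat_i * 1000L + attempt, tag = 3L))
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    ok <- all(vapply(seq_len(folds), function(k)
      length(unique(y[fold != k])) == 2L, logical(1)))
    if (ok) return(fold)
    message(sprintf("single-class training fold at repeat %d; regenerated with next substream",
                    repeat_i))
  }
  stop("could not stratify folds; too few samples per class", call. = FALSE)
}

fit_predict <- function(classifier, x_tr, y_tr, x_te) {
  df_tr <- as.data.frame(x_tr); df_te <- as.data.frame(x_te)
  names(df_te) <- names(df_tr)
  switch(classifier,
    logistic = {
      df_tr$.y <- y_tr
      fit <- suppressWarnings(stats::glm(.y ~ ., data = df_tr,
                                         family = stats::binomial()))
      as.integer(suppressWarnings(
        stats::predict(fit, newdata = df_te, type = "response")) > 0.5)
    },
    svm = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop("classifier 'svm' requires the e1071 package", call. = FALSE)
      fit <- e1071::svm(x_tr, factor(y_tr, levels = c(0, 1)),
                        kernel = "polynomial", degree = 2, scale = FALSE)
      as.integer(as.character(stats::predict(fit, x_te)))
    },
    rf = {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("classifier 'rf' requires the randomForest package", call. = FALSE)
      fit <- randomForest::randomForest(x_tr, factor(y_tr, levels = c(0, 1)))
      as.integer(as.character(stats::predict(fit, x_te)))
    },
    stop(sprintf("unknown classifier '%s'", classifier), call. = FALSE))
}

#' Compare feature sets by repeated cross-validation
#'
#' Evaluates each named feature subset with each classifier on identical
#' stratified folds (same seed for every combination), reporting the mean
#' and standard deviation of MCC and accuracy over folds x repeats in the
#' conventional "value +/- sd" presentation.
#'
#' @param data An [rop_dataset()].
#' @param feature_sets Named list of nonempty feature index/name vectors.
#' @param protocol A [cv_protocol()].
#' @return Data frame: `set`, `classifier`, `mcc_mean`, `mcc_sd`,
#'   `ca_mean`, `ca_sd`, `summary` (formatted percentages).
#' @export
compare_selectors <- function(data, feature_sets, protocol = cv_protocol()) {
  stopifnot(inherits(data, "rop_dataset"))
  if (is.null(names(feature_sets)) || any(!nzchar(names(feature_sets))))
    stop("feature_sets must be a named list", call. = FALSE)
  if (any(vapply(feature_sets, length, integer(1)) == 0L))
    stop("every feature subset must be nonempty", call. = FALSE)
  sets <- lapply(feature_sets, function(f) resolve_features(data, f))
  y <- data$y

  fold_plan <- lapply(seq_len(protocol$repeats), function(r)
    make_folds(y, protocol$folds, protocol$seed, r))

  out <- list()
  for (set_name in names(sets)) {
    xs <- data$x[, sets[[set_name]], drop = FALSE]
    for (clf in protocol$classifiers) {
      mccs <- cas <- numeric(0)
      for (r in seq_len(protocol$repeats)) {
        fold <- fold_plan[[r]]
        for (k in seq_len(protocol$folds)) {
          te <- fold == k
          set.seed(substream_seed(protocol$seed, r * 100L + k, tag = 4L))
          pred <- fit_predict(clf, xs[!te, , drop = FALSE], y[!te],
                              xs[te, , drop = FALSE])
          m <- confusion_metrics(y[te], pred)
          mccs <- c(mccs, m[["mcc"]]); cas <- c(cas, m[["ca"]])
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        set = set_name, classifier = clf,
        mcc_mean = mean(mccs), mcc_sd = stats::sd(mccs),
        ca_mean = mean(cas), ca_sd = stats::sd(cas),
        summary = sprintf("MCC %.1f%%+/-%.1f%%, CA %.1f%%+/-%.1f%%",
                          100 * mean(mccs), 100 * stats::sd(mccs),
                          100 * mean(cas), 100 * stats::sd(cas)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Stepwise AIC curve along a feature ranking
#'
#' For `k = 0..k_max`, fits a maximum-likelihood logistic model on the top
#' `k` features of the ranking and records `AIC = 2(k + 1) - 2 logLik`
#' (parameter count includes the intercept; `k = 0` is the null model). A
#' fast-dropping curve means the ranking front-loads informative features.
#' Complete separation is flagged; the AIC is then the value at the fitting
#' routine's convergence cap.
#'
#' @param data An [rop_dataset()].
#' @param ranking Ordered feature indices or names, best first.
#' @param k_max Deepest model size (default: full ranking; keep small
#'   relative to the sample count).
#' @return Data frame: `k`, `feature` (the feature entering at step `k`),
#'   `aic`, `separation` (logical).
#' @export
stepwise_aic_curve <- function(data, ranking, k_max = length(ranking)) {
  stopifnot(inherits(data, "rop_dataset"))
  ranking <- resolve_features(data, ranking)
  if (k_max > length(ranking))
    stop("k_max exceeds the ranking length", call. = FALSE)
  y <- data$y
  out <- vector("list", k_max + 1L)
  for (k in 0:k_max) {
    df <- if (k == 0L) data.frame(.y = y)
          else cbind(data.frame(.y = y),
                     as.data.frame(data$x[, ranking[seq_len(k)], drop = FALSE]))
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.y ~ ., data = df, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    out[[k + 1L]] <- data.frame(
      k = k,
      feature = if (k == 0L) NA_character_ else data$feature_names[ranking[k]],
      aic = stats::AIC(fit),
      separation = separated,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Gini-importance feature ranking (baseline)
#'
#' Standard random-forest mean-decrease-in-Gini ranking, the conventional
#' importance baseline the perfect-tree criteria are compared against.
#'
#' @param data An [rop_dataset()].
#' @param n_trees Trees in the baseline forest (default 500).
#' @param seed Seed.
#' @return Character vector of feature names, most important first.
#' @export
gini_ranking <- function(data, n_trees = 500L, seed = 1L) {
  if (!requireNamespace("randomForest", quietly = TRUE))
    stop("gini_ranking requires the randomForest package", call. = FALSE)
  set.seed(seed)
  fit <- randomForest::randomForest(data$x, factor(data$y, levels = c(0, 1)),
                                    ntree = n_trees)
  imp <- randomForest::importance(fit)[, "MeanDecreaseGini"]
  data$feature_names[order(-imp, method = "radix")]
}

#' SVM-RFE feature ranking (baseline)
#'
#' Recursive feature elimination with a quadratic-kernel max-margin
#' classifier: repeatedly fits the SVM, scores each remaining feature by
#' the drop in the kernel-space margin objective
#' `W^2 = sum alpha_i alpha_j y_i y_j K(x_i, x_j)` when the feature is
#' removed, and eliminates the least-contributing feature. Composed from
#' standard kernel machinery; present so selector comparisons can follow
#' the published protocol shape.
#'
#' @param data An [rop_dataset()].
#' @param eliminate_frac Fraction of remaining features dropped per round
#'   (default 1/3 of the remainder, at least one) — chunked elimination
#'   keeps the cost workable at array scale.
#' @return Character vector of feature names, most important first
#'   (reverse elimination order, last survivor first).
#' @export
svm_rfe_ranking <- function(data, eliminate_frac = 1 / 3) {
  if (!requireNamespace("e1071", quietly = TRUE))
    stop("svm_rfe_ranking requires the e1071 package", call. = FALSE)
  remaining <- seq_len(ncol(data$x))
  eliminated <- integer(0)
  yf <- factor(data$y, levels = c(0, 1))
  ysign <- ifelse(data$y == 1L, 1, -1)
  poly_k <- function(m) (1 + m %*% t(m))^2
  while (length(remaining) > 1L) {
    xs <- data$x[, remaining, drop = FALSE]
    fit <- e1071::svm(xs, yf, kernel = "polynomial", degree = 2, gamma = 1,
                      coef0 = 1, scale = FALSE)
    sv <- fit$index
    a <- numeric(length(sv))
    a <- abs(fit$coefs[, 1L])                    # alpha_i (sign folded below)
    ay <- a * ysign[sv]
    xsv <- xs[sv, , drop = FALSE]
    w2_full <- drop(t(ay) %*% poly_k(xsv) %*% ay)
    crit <- vapply(seq_along(remaining), function(j) {
      w2_j <- drop(t(ay) %*% poly_k(xsv[, -j, drop = FALSE]) %*% ay)
      abs(w2_full - w2_j)                        # small change => uninformative
    }, numeric(1))
    n_drop <- max(1L, floor(length(remaining) * eliminate_frac))
    n_drop <- min(n_drop, length(remaining) - 1L)
    drop_idx <- order(crit, method = "radix")[seq_len(n_drop)]
    eliminated <- c(remaining[drop_idx], eliminated)
    remaining <- remaining[-drop_idx]
  }
  data$feature_names[c(remaining, eliminated)]
}
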