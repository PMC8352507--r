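#' Specification of a synthetic binary-outcome dataset
#'
#' Describes a reproducible dataset with planted feature archetypes that
#' emulate the statistical structures the criteria are designed to detect in
#' expression-array data (continuous class-conditional Gaussian features,
#' binary outcome):
#'
#' * `separable` — class-1 mean shifted by `delta` over noise `sigma`; with
#'   `delta/sigma >= 10` the class ranges essentially never overlap at
#'   n <= 200, so single-feature trees are perfect with a unique solution;
#' * `monotone_weak` — the same shift at small `delta/sigma`: informative
#'   but rarely perfect alone;
#' * `paradoxical` — the sign of the class shift depends on a latent binary
#'   context per sample, so the feature helps in one direction in some trees
#'   and the other in others (the between-tree `nic5` / within-tree `nic6`
#'   behaviour);
#' * `intermediate_null` — a deterministic average of two planted features:
#'   carries no independent information beyond them (the all-zero
#'   coefficient discussion);
#' * `noise` — label-independent `N(0, 1)`.
#'
#' @param n_samples,n_features Dataset dimensions.
#' @param prevalence Probability of outcome 1 (in (0, 1)).
#' @param n_separable,n_monotone_weak,n_paradoxical,n_intermediate_null
#'   Archetype counts; the remainder of `n_features` is noise.
#' @param delta Strong class shift (default 10).
#' @param delta_weak Weak class shift (default 0.5).
#' @param sigma Within-class standard deviation (default 1).
#' @param heavy_tails Use t(3) noise instead of Gaussian (robustness
#'   checks).
#' @param seed Seed making generation deterministic.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_samples = 40L, n_features = 50L, prevalence = 0.5,
                       n_separable = 1L, n_monotone_weak = 0L,
                       n_paradoxical = 0L, n_intermediate_null = 0L,
                       delta = 10, delta_weak = 0.5, sigma = 1,
                       heavy_tails = FALSE, seed = 1L) {
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must lie strictly between 0 and 1", call. = FALSE)
  if (sigma <= 0) stop("sigma must be positive", call. = FALSE)
  planted <- n_separable + n_monotone_weak + n_paradoxical + n_intermediate_null
  if (planted > n_features)
    stop("archetype counts exceed n_features", call. = FALSE)
  if (n_intermediate_null > 0L && n_separable + n_monotone_weak + n_paradoxical < 2L)
    stop("intermediate_null features need at least two planted parents", call. = FALSE)
  structure(list(n_samples = as.integer(n_samples),
                 n_features = as.integer(n_features),
                 prevalence = prevalence,
                 n_separable = as.integer(n_separable),
                 n_monotone_weak = as.integer(n_monotone_weak),
                 n_paradoxical = as.integer(n_paradoxical),
                 n_intermediate_null = as.integer(n_intermediate_null),
                 delta = delta, delta_weak = delta_weak, sigma = sigma,
                 heavy_tails = heavy_tails, seed = as.integer(seed)),
            class = "synth_spec")
}

#' Generate a synthetic dataset with planted archetypes
#'
#' Deterministic given the spec's seed. Labels are Bernoulli draws at the
#' specified prevalence, redrawn (next substream) in the rare event that a
#' class is empty, so the returned dataset always carries both classes.
#'
#' @param spec A [synth_spec()].
#' @return A list: `data` (an [rop_dataset()]) and `archetypes` (data frame
#'   mapping every feature to its ground-truth archetype).
#' @examples
#' g <- generate_dataset(synth_spec(n_samples = 30, n_features = 10, seed = 7))
#' table(g$archetypes$archetype)
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  ns <- spec$n_samples
  nf <- spec$n_features
  rnoise <- if (spec$heavy_tails) function(n) stats::rt(n, df = 3)
            else function(n) stats::rnorm(n)

  for (attempt in 0:100) {
    set.seed(substream_seed(spec$seed, attempt, tag = 7L))
    y <- stats::rbinom(ns, 1L, spec$prevalence)
    if (length(unique(y)) == 2L) break
  }
  if (length(unique(y)) < 2L)
    stop("could not draw both outcome classes; increase n_samples", call. = FALSE)

  arch <- c(rep("separable", spec$n_separable),
            rep("monotone_weak", spec$n_monotone_weak),
            rep("paradoxical", spec$n_paradoxical),
            rep("intermediate_null", spec$n_intermediate_null))
  arch <- c(arch, rep("noise", nf - length(arch)))

  x <- matrix(0, nrow = ns, ncol = nf)
  parents <- which(arch %in% c("separable", "monotone_weak", "paradoxical"))
  for (j in seq_len(nf)) {
    x[, j] <- switch(arch[j],
      separable = spec$sigma * rnoise(ns) + spec$delta * y,
      monotone_weak = spec$sigma * rnoise(ns) + spec$delta_weak * y,
      paradoxical = {
        ctx <- stats::rbinom(ns, 1L, 0.5) * 2L - 1L   # latent context +/-1
        spec$sigma * rnoise(ns) + spec$delta * ctx * y
      },
      intermediate_null = {
        p <- sample(parents, 2L)
        (x[, p[1L]] + x[, p[2L]]) / 2
      },
      noise = rnoise(ns))
  }
  feature_names <- sprintf("%s_%02d", abbreviate_archetype(arch), seq_len(nf))
  list(data = rop_dataset(x, y, feature_names = feature_names),
       archetypes = data.frame(feature = feature_names, archetype = arch,
                               stringsAsFactors = FALSE))
}

abbreviate_archetype <- function(a) {
  c(separable = "sep", monotone_weak = "weak", paradoxical = "para",
    intermediate_null = "inull", noise = "noise")[a]
}
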