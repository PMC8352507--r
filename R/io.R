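#' Read a delimited feature matrix plus labels into a dataset
#'
#' Expression-matrix convention: features in rows by default (first column
#' = feature identifier, remaining columns = samples), with an explicit
#' orientation flag for samples-in-rows tables. The labels file has two
#' columns, sample identifier and label in \{0, 1\}; samples are matched by
#' name when the matrix carries sample identifiers, otherwise by order.
#' Missing or non-numeric cells are hard errors naming the offending cell —
#' the method does not support missing data.
#'
#' @param matrix_path Path to the delimited numeric matrix (with header and
#'   row identifiers in the first column).
#' @param labels_path Path to the two-column labels file.
#' @param orientation `"features_in_rows"` (default) or `"samples_in_rows"`.
#' @param sep Field delimiter (default tab).
#' @return An [rop_dataset()].
#' @export
read_dataset <- function(matrix_path, labels_path,
                         orientation = c("features_in_rows", "samples_in_rows"),
                         sep = "\t") {
  orientation <- match.arg(orientation)
  raw <- utils::read.table(matrix_path, header = TRUE, sep = sep,
                           row.names = 1L, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw),
              dimnames = dimnames(raw))
  for (j in seq_len(ncol(raw))) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("non-numeric or missing value '%s' at row '%s', column '%s' of %s",
                   raw[i, j], rownames(raw)[i], colnames(raw)[j], matrix_path),
           call. = FALSE)
    }
    m[, j] <- v
  }
  if (orientation == "features_in_rows") m <- t(m)

  lab <- utils::read.table(labels_path, header = TRUE, sep = sep,
                           check.names = FALSE, comment.char = "",
                           stringsAsFactors = FALSE)
  if (ncol(lab) < 2L)
    stop("labels file must have two columns: sample, label", call. = FALSE)
  if (nrow(lab) != nrow(m))
    stop(sprintf("label count (%d) does not match sample count (%d); check the orientation flag",
                 nrow(lab), nrow(m)), call. = FALSE)
  y <- lab[[2L]]
  if (all(lab[[1L]] %in% rownames(m))) {
    y <- y[match(rownames(m), lab[[1L]])]
  }
  rop_dataset(m, y, sample_names = rownames(m),
              require_both_classes = FALSE)
}

#' Blind feature identities
#'
#' Renames features `a1..aN` in order, so downstream selection runs fully
#' blinded, and returns the reversible mapping (optionally persisted as a
#' two-column TSV).
#'
#' @param data An [rop_dataset()].
#' @param map_path Optional path to write the mapping TSV.
#' @return A list: `data` (renamed dataset) and `map` (data frame with
#'   `anonymized`, `original`).
#' @examples
#' d <- rop_dataset(matrix(rnorm(20), 5, 4,
#'                         dimnames = list(NULL, c("w", "x", "y", "z"))),
#'                  c(0, 1, 0, 1, 0))
#' anonymize_features(d)$map
#' @export
anonymize_features <- function(data, map_path = NULL) {
  stopifnot(inherits(data, "rop_dataset"))
  map <- data.frame(anonymized = paste0("a", seq_along(data$feature_names)),
                    original = data$feature_names, stringsAsFactors = FALSE)
  out <- data
  out$feature_names <- map$anonymized
  colnames(out$x) <- map$anonymized
  if (!is.null(map_path))
    utils::write.table(map, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  list(data = out, map = map)
}

#' Restore original feature names from an anonymization map
#'
#' @param data An anonymized [rop_dataset()].
#' @param map Mapping data frame from [anonymize_features()] (or read back
#'   from its TSV).
#' @return The dataset with original names restored.
#' @export
deanonymize_features <- function(data, map) {
  idx <- match(data$feature_names, map$anonymized)
  if (anyNA(idx)) stop("feature not present in the mapping", call. = FALSE)
  data$feature_names <- map$original[idx]
  colnames(data$x) <- data$feature_names
  data
}

#' Write the per-feature report table
#'
#' One row per feature, ordered by score rank: the selection count, the ten
#' event numerators, the criterion ratios, and the composite score printed
#' to two decimals (ratios keep full precision; two-decimal rounding is a
#' presentation choice only — comparisons inside the package always use
#' full precision).
#'
#' @param nics A `nic_table` from [compute_nics()].
#' @param tally The matching tally from [build_forest()].
#' @param path Output TSV path.
#' @return The written data frame, invisibly.
#' @export
write_nic_table <- function(nics, tally, path) {
  if (!setequal(nics$feature, tally$feature))
    stop("nic table and tally cover different features", call. = FALSE)
  tally <- tally[match(nics$feature, tally$feature), ]
  out <- cbind(tally,
               nics[, c(paste0("nic", 1:10), "no_pt",
                        "hierarchical_rank", "score_rank")],
               nic_score = sprintf("%.2f", nics$nic_score))
  out <- out[order(nics$score_rank), ]
  tryCatch(
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop(sprintf("cannot write '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  invisible(out)
}

#' Read back a per-feature report table
#'
#' @param path TSV written by [write_nic_table()].
#' @return Data frame with the table's columns (scores as printed).
#' @export
read_nic_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a matrix + labels pair in the package's exchange format
#'
#' Features-in-rows TSV plus a two-column labels TSV, the same layout
#' [read_dataset()] reads — the generator and the readers round-trip.
#'
#' @param data An [rop_dataset()].
#' @param matrix_path,labels_path Output paths.
#' @return Invisibly `NULL`.
#' @export
write_dataset <- function(data, matrix_path, labels_path) {
  m <- t(data$x)
  df <- data.frame(feature = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(sample = data$sample_names, label = data$y),
                     labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Run manifest for reproducibility
#'
#' JSON document recording the configuration, seed and versions sufficient
#' to reproduce a run bitwise.
#'
#' @param config A forest/tree configuration (any list).
#' @param seed Master seed of the run.
#' @param path Output JSON path.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(config, seed, path) {
  manifest <- list(
    package = "rfpt",
    version = as.character(utils::packageVersion("rfpt")),
    r_version = R.version.string,
    seed = seed,
    config = config,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(manifest)
}
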