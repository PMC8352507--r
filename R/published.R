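#' Published per-probe tally of the taxane-response application
#'
#' The top-20 probe rows of the published single-probe forest on the
#' GSE22513 breast-cancer expression study (28 arrays, 54,675 probes;
#' pathologic complete response as the binary outcome): for each probe, the
#' selection count and the ten event numerators, plus the gene symbol, the
#' blinded identifier and whether the probe made the published selection.
#' Useful as a worked example for [compute_nics()] without any download.
#'
#' @return Data frame with the tally columns plus `gene_symbol`,
#'   `anonymized` and `selected`.
#' @examples
#' tal <- published_tally()
#' nics <- compute_nics(tal)
#' head(nics[, c("feature", "nic_score")])
#' @export
published_tally <- function() {
  path <- system.file("extdata", "gse22513_top20_published_tally.tsv",
                      package = "rfpt", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
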