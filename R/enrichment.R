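#' Cytogenetic-band over-representation analysis
#'
#' Hypergeometric upper-tail test of whether a gene list contains more
#' members of each cytogenetic band than expected given the universe of
#' analyzed genes (a local reimplementation of chromosomal-location
#' over-representation as offered by web enrichment services, so results
#' are fully reproducible offline). For a band with `K` universe genes, a
#' list of size `n` drawn from a universe of size `N`, and `k` list genes
#' on the band, `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#' Benjamini-Hochberg adjustment is applied across all tested bands.
#'
#' List genes outside the universe are dropped with a warning, as are
#' universe genes without a band annotation (each gene maps to exactly one
#' band).
#'
#' @param genes Character vector: the query gene list (e.g. up- and
#'   downregulated genes combined).
#' @param universe Character vector: all analyzed genes.
#' @param annotation Tibble from [read_band_annotation()] (`gene_id`,
#'   `band`).
#' @param min_size Minimum band size `K` for testing (default 1).
#' @return A tibble sorted by ascending p: `band`, `k`, `K`, `n`, `N`, `p`,
#'   `fdr`.
#' @export
cytoband_ora <- function(genes, universe, annotation, min_size = 1) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (!length(genes)) {
    abort("empty query gene list", class = "epichron_error_empty_list")
  }
  if (!length(universe)) {
    abort("empty universe", class = "epichron_error_empty_list")
  }
  outside <- setdiff(genes, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) not in the universe dropped", length(outside)))
    genes <- intersect(genes, universe)
  }
  ann <- setNames(annotation$band, annotation$gene_id)
  unannotated <- universe[!universe %in% names(ann)]
  if (length(unannotated)) {
    warn(sprintf("%d universe gene(s) without band annotation dropped",
                 length(unannotated)))
    universe <- setdiff(universe, unannotated)
    genes <- intersect(genes, universe)
  }
  N <- length(universe)
  n <- length(genes)
  band_universe <- table(ann[universe])
  band_hits <- table(factor(ann[genes], levels = names(band_universe)))
  out <- tibble(band = names(band_universe),
                k = as.integer(band_hits),
                K = as.integer(band_universe),
                n = n, N = N) %>%
    filter(.data$K >= min_size) %>%
    mutate(p = phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                      lower.tail = FALSE),
           fdr = bh_adjust(.data$p)) %>%
    arrange(.data$p, .data$band)
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate adjustment with monotonicity enforcement;
#' the input order is preserved in the output.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]", class = "epichron_error_bad_value")
  }
  p.adjust(pvalues, method = "BH")
}
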