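#' Filter low-expressed genes
#'
#' Retains genes expressed above a CPM threshold in at least a given
#' fraction of samples: a gene is kept when the number of samples with
#' value strictly above `cpm_threshold` (or `>=` with `cmp = "ge"`) is at
#' least `ceiling(min_fraction * n_samples)`. With the defaults (CPM > 1 in
#' at least 50% of samples) and 16 samples this requires 8 qualifying
#' samples. The filter always reads raw (pre-log) values; sample set and
#' gene order are preserved.
#'
#' @param expr Expression tibble (`gene_id` + sample columns), raw scale.
#' @param cpm_threshold Expression threshold, default 1.
#' @param min_fraction Minimum fraction of samples above threshold, in
#'   (0, 1]; default 0.5.
#' @param cmp `"gt"` (strict `>`, default) or `"ge"` (`>=`) at the
#'   threshold boundary.
#' @return The filtered expression tibble.
#' @export
filter_low_expressed <- function(expr, cpm_threshold = 1, min_fraction = 0.5,
                                 cmp = c("gt", "ge")) {
  cmp <- match.arg(cmp)
  stopifnot(cpm_threshold >= 0, min_fraction > 0, min_fraction <= 1)
  m <- expr_values(expr)
  hits <- if (cmp == "gt") m > cpm_threshold else m >= cpm_threshold
  need <- ceiling(min_fraction * ncol(m))
  keep <- rowSums(hits) >= need
  if (!any(keep)) warn("expression filter removed every gene")
  expr[keep, , drop = FALSE]
}

#' Dataset-derived pseudocount
#'
#' The pseudocount added before log transformation is the smallest strictly
#' positive value in the matrix divided by `divisor` (default 1000), so it
#' is guaranteed to be small relative to every observed expression value.
#'
#' @param expr Expression tibble, raw scale.
#' @param divisor Positive divisor, default 1000.
#' @return A positive scalar.
#' @export
compute_pseudocount <- function(expr, divisor = 1000) {
  stopifnot(divisor > 0)
  m <- expr_values(expr)
  pos <- m[m > 0]
  if (!length(pos)) {
    abort("cannot derive a pseudocount: the matrix has no positive value",
          class = "epichron_error_all_zero")
  }
  min(pos) / divisor
}

#' Log2 transform an expression matrix
#'
#' Replaces every value `v` by `log2(v + pseudocount)`. The result carries a
#' `log_scale` attribute so downstream differential expression can check it
#' received log-scale input. The transform is strictly monotone, so
#' rank-based statistics (Spearman screening) are unchanged by it.
#'
#' @param expr Expression tibble, raw scale.
#' @param pseudocount Positive offset; default [compute_pseudocount()] of
#'   `expr`.
#' @return The transformed tibble with attributes `log_scale = TRUE` and
#'   `pseudocount`.
#' @export
log_transform <- function(expr, pseudocount = compute_pseudocount(expr)) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 ||
      pseudocount <= 0) {
    abort("pseudocount must be a single positive number",
          class = "epichron_error_bad_pseudocount")
  }
  out <- expr
  out[-1] <- log2(as.matrix(expr[-1]) + pseudocount)
  attr(out, "log_scale") <- TRUE
  attr(out, "pseudocount") <- pseudocount
  out
}

is_log_scale <- function(expr) isTRUE(attr(expr, "log_scale"))
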