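#' Two-group differential expression on a log2 matrix
#'
#' Per gene, computes the log2 fold change as the mean of the high group
#' minus the mean of the low group (high = above the stratification
#' threshold, so long-duration minus short-duration, or AOE minus ChOE),
#' and a two-sided p-value from either Welch's unequal-variance t-test on
#' the log2 values (default) or the tie/continuity-corrected Mann-Whitney
#' test. Genes with zero variance in both groups under Welch get p = 1 by
#' convention. Significance status is assigned by [classify_volcano()].
#'
#' Because the input is on the log2 scale, the fold change equals the log2
#' ratio of within-group geometric means of the (pseudocounted) expression.
#'
#' @param expr Log2-scale expression tibble (see [log_transform()]).
#' @param cohort Output of [stratify()]; both groups must have >= 2
#'   samples.
#' @param test `"welch_t"` (default) or `"mann_whitney"`.
#' @param p_threshold,lfc_threshold Volcano thresholds, defaults 0.05 and
#'   0.5.
#' @param p_adjust `"none"` (default; raw p-values drive classification) or
#'   `"BH"` (adds Benjamini-Hochberg `p_adj` used for classification).
#' @return A tibble with one row per gene in input order: `gene_id`,
#'   `log2_fc`, `statistic`, `p` (plus `p_adj` when requested) and `status`.
#' @export
group_de <- function(expr, cohort, test = c("welch_t", "mann_whitney"),
                     p_threshold = 0.05, lfc_threshold = 0.5,
                     p_adjust = c("none", "BH")) {
  test <- match.arg(test)
  p_adjust <- match.arg(p_adjust)
  if (!is_log_scale(expr)) {
    warn("expression matrix is not marked log-scale; fold changes assume log2 input")
  }
  m <- expr_values(expr)
  grp <- setNames(as.character(cohort$group), cohort$sample_id)[colnames(m)]
  if (anyNA(grp)) {
    abort("cohort does not cover every expression sample",
          class = "epichron_error_missing_value")
  }
  lo <- m[, grp == "low", drop = FALSE]
  hi <- m[, grp == "high", drop = FALSE]
  n1 <- ncol(hi); n2 <- ncol(lo)
  if (n1 < 2 || n2 < 2) {
    abort("each group needs at least 2 samples for differential expression",
          class = "epichron_error_small_group")
  }
  lfc <- rowMeans(hi) - rowMeans(lo)
  if (test == "welch_t") {
    v1 <- apply(hi, 1, var); v2 <- apply(lo, 1, var)
    se2 <- v1 / n1 + v2 / n2
    t_stat <- ifelse(se2 > 0, lfc / sqrt(se2), 0)
    df <- ifelse(se2 > 0,
                 se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1)),
                 1)
    p <- ifelse(se2 > 0, 2 * pt(-abs(t_stat), df), 1)
  } else {
    res <- apply(m, 1, function(g) {
      ts <- rank_sum_test(g[grp == "high"], g[grp == "low"])
      c(ts$U, ts$p)
    })
    t_stat <- res[1, ]
    p <- res[2, ]
  }
  out <- tibble(gene_id = rownames(m), log2_fc = unname(lfc),
                statistic = unname(t_stat), p = unname(p))
  if (p_adjust == "BH") out$p_adj <- bh_adjust(out$p)
  classify_volcano(out, p_threshold = p_threshold,
                   lfc_threshold = lfc_threshold)
}

#' Volcano-style significance classification
#'
#' Labels each gene `up` when p < `p_threshold` and log2 fold change >
#' `lfc_threshold`, `down` when p < `p_threshold` and log2 fold change <
#' `-lfc_threshold`, and `ns` otherwise (both inequalities strict). When a
#' `p_adj` column is present it is used in place of raw `p`.
#'
#' @param records Tibble with columns `p` and `log2_fc` (optionally
#'   `p_adj`).
#' @param p_threshold,lfc_threshold Positive thresholds, defaults 0.05 and
#'   0.5.
#' @return `records` with a `status` column (`up`/`down`/`ns`).
#' @export
classify_volcano <- function(records, p_threshold = 0.05,
                             lfc_threshold = 0.5) {
  stopifnot(p_threshold > 0, lfc_threshold > 0)
  pv <- if ("p_adj" %in% names(records)) records$p_adj else records$p
  records$status <- case_when(
    pv < p_threshold & records$log2_fc > lfc_threshold ~ "up",
    pv < p_threshold & records$log2_fc < -lfc_threshold ~ "down",
    TRUE ~ "ns"
  )
  records
}

#' Volcano plot of differential expression results
#'
#' @param records Output of [group_de()].
#' @param label_top Number of most significant non-`ns` genes to label.
#' @return A ggplot object: -log10(p) against log2 fold change, colored by
#'   status.
#' @export
plot_volcano <- function(records, label_top = 0) {
  dat <- mutate(records, neg_log10_p = -log10(pmax(.data$p, 1e-300)))
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$log2_fc, .data$neg_log10_p,
                                         colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "#c0392b", down = "#1e8449", ns = "grey60")) +
    ggplot2::labs(x = expression(log[2] ~ "fold change"),
                  y = expression(-log[10] ~ italic(p)), colour = NULL) +
    ggplot2::theme_minimal()
  if (label_top > 0) {
    lab <- dat %>% filter(.data$status != "ns") %>%
      arrange(.data$p) %>% head(label_top)
    p <- p + ggplot2::geom_text(data = lab,
                                ggplot2::aes(label = .data$gene_id),
                                vjust = -0.6, size = 3, show.legend = FALSE)
  }
  p
}
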