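#' Spearman rank correlation with t-approximation p-value
#'
#' Computes Spearman's r as the Pearson correlation of midranks and a
#' two-sided p-value from the t-approximation
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom. When
#' either vector is constant, r is undefined (`NA`) and p = 1; when |r| = 1
#' the p-value is 0.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @param df Degrees of freedom for the t-approximation; default
#'   `length(x) - 2`.
#' @return A one-row tibble with columns `r` and `p`.
#' @export
spearman_cor <- function(x, y, df = length(x) - 2) {
  stopifnot(length(x) == length(y), length(x) >= 4)
  if (var(x) == 0 || var(y) == 0) {
    return(tibble(r = NA_real_, p = 1))
  }
  r <- cor(rank(x), rank(y))
  tibble(r = r, p = spearman_p(r, df))
}

spearman_p <- function(r, df) {
  denom <- 1 - r^2
  ifelse(is.na(r), 1,
         ifelse(denom <= .Machine$double.eps, 0,
                pmin(1, 2 * pt(-abs(r) * sqrt(df / denom), df))))
}

#' Screen all genes for correlation with a clinical trait
#'
#' Computes per-gene Spearman correlation between expression and a clinical
#' trait (raw years of epilepsy duration or onset age), with the joint
#' significance rule |r| > `r_threshold` and p < `p_threshold` (both
#' strict). Because Spearman correlation depends only on ranks, the screen
#' gives identical results on CPM and on log2(CPM + pseudocount) input.
#'
#' @param expr Expression tibble (raw or log scale).
#' @param clinical Clinical tibble covering every expression sample.
#' @param trait `"duration"` or `"onset_age"`, or a numeric vector named by
#'   sample.
#' @param r_threshold,p_threshold Joint significance thresholds, defaults
#'   0.5 and 0.05.
#' @return A tibble in gene input order: `gene_id`, `r`, `p`, `significant`
#'   (logical; `FALSE` for constant genes) and `direction`
#'   (`positive`/`negative`/`NA`).
#' @export
screen_genes <- function(expr, clinical, trait = c("duration", "onset_age"),
                         r_threshold = 0.5, p_threshold = 0.05) {
  stopifnot(r_threshold > 0, r_threshold < 1, p_threshold > 0)
  m <- expr_values(expr)
  tv <- trait_values(clinical, trait, colnames(m))
  n <- ncol(m)
  r <- row_spearman(m, tv)
  p <- spearman_p(r, n - 2)
  tibble(gene_id = rownames(m), r = unname(r), p = unname(p),
         significant = !is.na(r) & abs(r) > r_threshold & p < p_threshold,
         direction = ifelse(is.na(r), NA_character_,
                            ifelse(r >= 0, "positive", "negative")))
}

trait_values <- function(clinical, trait, samples) {
  if (is.character(trait) && length(trait) == 1 &&
      trait %in% c("duration", "onset_age")) {
    tv <- setNames(clinical[[trait]], clinical$sample_id)[samples]
  } else {
    tv <- trait[samples]
  }
  if (anyNA(tv)) {
    abort("trait is undefined for at least one expression sample",
          class = "epichron_error_missing_value")
  }
  unname(tv)
}

# rowwise Spearman of a gene x sample matrix against one trait vector;
# constant rows give NA
row_spearman <- function(m, tv) {
  rx <- t(apply(m, 1, rank))
  if (ncol(m) == 1) rx <- t(rx)
  ry <- rank(tv)
  rx_c <- rx - rowMeans(rx)
  ry_c <- ry - mean(ry)
  ss_x <- rowSums(rx_c^2)
  r <- as.vector(rx_c %*% ry_c) / sqrt(ss_x * sum(ry_c^2))
  r[ss_x == 0 | sum(ry_c^2) == 0] <- NA_real_
  setNames(r, rownames(m))
}

#' Flag and set aside age-associated genes
#'
#' Marks records whose gene is in an exclusion list (typically a published
#' set of whole-blood age-associated genes) with `age_associated = TRUE`.
#' All records are retained so the unfiltered results remain available;
#' [reported_genes()] gives the reported view with flagged genes removed.
#'
#' @param records Per-gene result tibble with a `gene_id` column.
#' @param exclusion Character vector of gene identifiers (possibly empty).
#' @return `records` with an added/updated `age_associated` column.
#' @export
exclude_genes <- function(records, exclusion) {
  mutate(records, age_associated = .data$gene_id %in% exclusion)
}

#' Reported view of screened genes
#'
#' Drops records flagged `age_associated` (no-op if the flag is absent).
#'
#' @param records Per-gene result tibble.
#' @return The records not flagged as age-associated.
#' @export
reported_genes <- function(records) {
  if (!"age_associated" %in% names(records)) return(records)
  filter(records, !.data$age_associated)
}

#' Build a covariate design matrix
#'
#' Builds an ordinary-least-squares design from clinical covariates: an
#' intercept, numeric covariates as given, and indicator columns for each
#' categorical covariate with the most frequent level as the reference.
#' Constant non-intercept columns are dropped with a warning, as are
#' collinearity-induced rank deficiencies at fit time (residuals are
#' unaffected by which least-squares solution is used).
#'
#' @param clinical Clinical tibble.
#' @param covariates Column names, default `c("age", "gender", "etiology")`.
#' @return A numeric design matrix with one row per sample, rownames =
#'   sample IDs.
#' @export
build_design <- function(clinical, covariates = c("age", "gender", "etiology")) {
  if (!length(covariates)) {
    return(matrix(1, nrow(clinical), 1,
                  dimnames = list(clinical$sample_id, "(Intercept)")))
  }
  missing <- setdiff(covariates, names(clinical))
  if (length(missing)) {
    abort(paste0("unknown covariate(s): ", paste(missing, collapse = ", ")),
          class = "epichron_error_missing_column")
  }
  dat <- clinical[covariates]
  single <- vapply(dat, function(v) {
    !is.numeric(v) && length(unique(v)) < 2
  }, logical(1))
  if (any(single)) {
    warn(paste0("dropping constant covariate column(s): ",
                paste(covariates[single], collapse = ", ")))
    dat <- dat[!single]
    if (!ncol(dat)) {
      return(matrix(1, nrow(clinical), 1,
                    dimnames = list(clinical$sample_id, "(Intercept)")))
    }
  }
  for (v in names(dat)) {
    if (!is.numeric(dat[[v]])) {
      f <- factor(dat[[v]])
      ref <- names(sort(table(f), decreasing = TRUE))[1]
      dat[[v]] <- stats::relevel(f, ref = ref)
    }
  }
  X <- model.matrix(~ ., data = dat)
  rownames(X) <- clinical$sample_id
  const <- apply(X[, -1, drop = FALSE], 2, function(col) var(col) == 0)
  if (any(const)) {
    warn(paste0("dropping constant covariate column(s): ",
                paste(names(const)[const], collapse = ", ")))
    X <- X[, c(TRUE, !const), drop = FALSE]
  }
  X
}

#' Residualize a variable against covariates
#'
#' Ordinary-least-squares residuals of `y` on a covariate design matrix.
#' Rank-deficient designs are handled by pivoted QR (residuals are unique
#' even when coefficients are not); a warning reports the deficiency.
#'
#' @param y Numeric vector (or matrix with one column per variable), one
#'   row/element per sample.
#' @param design Design matrix from [build_design()] (or any numeric matrix
#'   including an intercept).
#' @return Residuals `y - y_hat`, same shape as `y`; orthogonal to every
#'   design column.
#' @export
residualize <- function(y, design) {
  y_mat <- as.matrix(y)
  stopifnot(nrow(y_mat) == nrow(design))
  qr_x <- qr(design)
  if (qr_x$rank < ncol(design)) {
    warn(sprintf("covariate design is rank-deficient (rank %d of %d columns); pivoted least squares used",
                 qr_x$rank, ncol(design)))
  }
  res <- qr.resid(qr_x, y_mat)
  if (is.vector(y)) as.vector(res) else res
}

#' Covariate-adjusted partial Spearman correlation
#'
#' For each gene, both the expression values and the clinical trait are
#' regressed (ordinary least squares) against the same covariates — by
#' default age at sampling, gender and epilepsy etiology — and the Spearman
#' correlation between the two residual vectors is taken as the
#' covariate-adjusted association. The p-value uses the same t-approximation
#' on `n - 2` degrees of freedom as the plain screen (the residual pair is
#' treated as an ordinary bivariate sample); `df_adjust = TRUE` instead
#' reduces the degrees of freedom by the number of fitted non-intercept
#' covariate columns.
#'
#' Unlike the plain screen, this is not invariant to monotone transforms of
#' the expression values, because residualization precedes ranking.
#'
#' @param expr Expression tibble.
#' @param clinical Clinical tibble covering every expression sample.
#' @param trait `"duration"` or `"onset_age"` (or numeric vector named by
#'   sample).
#' @param covariates Covariate column names for [build_design()].
#' @param r_threshold,p_threshold Joint significance thresholds.
#' @param df_adjust Reduce t-approximation degrees of freedom by the number
#'   of non-intercept covariate columns (default `FALSE`).
#' @param keep_residuals Attach the residual matrices (attribute
#'   `residuals`: list with `trait` and `expression`) for residual-residual
#'   plotting.
#' @return A tibble in gene input order: `gene_id`, `r_partial`, `p`,
#'   `significant`, `direction`.
#' @export
partial_spearman <- function(expr, clinical,
                             trait = c("duration", "onset_age"),
                             covariates = c("age", "gender", "etiology"),
                             r_threshold = 0.5, p_threshold = 0.05,
                             df_adjust = FALSE, keep_residuals = FALSE) {
  m <- expr_values(expr)
  samples <- colnames(m)
  clin <- clinical[match(samples, clinical$sample_id), ]
  if (anyNA(clin$sample_id)) {
    abort("clinical table does not cover every expression sample",
          class = "epichron_error_missing_value")
  }
  tv <- trait_values(clin, trait, samples)
  X <- build_design(clin, covariates)
  qr_x <- qr(X)
  trait_res <- qr.resid(qr_x, tv)
  expr_res <- t(qr.resid(qr_x, t(m)))
  n <- length(tv)
  df <- if (df_adjust) n - 2 - qr_x$rank + 1 else n - 2
  r <- row_spearman(expr_res, trait_res)
  p <- spearman_p(r, df)
  out <- tibble(gene_id = rownames(m), r_partial = unname(r), p = unname(p),
                significant = !is.na(r) & abs(r) > r_threshold & p < p_threshold,
                direction = ifelse(is.na(r), NA_character_,
                                   ifelse(r >= 0, "positive", "negative")))
  if (keep_residuals) {
    attr(out, "residuals") <- list(trait = setNames(trait_res, samples),
                                   expression = expr_res)
  }
  out
}

#' Directional overlap of two gene lists
#'
#' Intersection of two gene lists, sorted lexicographically. Used to compare
#' directionally opposed results, e.g. genes positively correlated with
#' epilepsy duration against genes negatively correlated with onset age.
#'
#' @param a,b Character vectors of gene identifiers.
#' @param label Optional label recording the direction semantics of the two
#'   inputs; stored as an attribute.
#' @return Sorted character vector of shared identifiers.
#' @export
overlap_sets <- function(a, b, label = NULL) {
  out <- sort(intersect(a, b))
  if (!is.null(label)) attr(out, "label") <- label
  out
}

#' Residual-residual scatter plot for a partial correlation
#'
#' Plots residualized expression of one gene against the residualized trait
#' with a least-squares line, so the visual trend reflects the partial
#' correlation after covariate adjustment. Requires
#' `partial_spearman(..., keep_residuals = TRUE)`.
#'
#' @param partial Output of [partial_spearman()] with residuals attached.
#' @param gene Gene identifier to plot.
#' @return A ggplot object.
#' @export
plot_partial_residuals <- function(partial, gene) {
  res <- attr(partial, "residuals")
  if (is.null(res)) {
    abort("no residuals attached; rerun partial_spearman(keep_residuals = TRUE)",
          class = "epichron_error_missing_value")
  }
  if (!gene %in% rownames(res$expression)) {
    abort(paste0("gene not found: ", gene),
          class = "epichron_error_missing_value")
  }
  dat <- tibble(trait_residual = unname(res$trait),
                expression_residual = res$expression[gene, ])
  r <- partial$r_partial[partial$gene_id == gene]
  ggplot2::ggplot(dat, ggplot2::aes(.data$trait_residual,
                                    .data$expression_residual)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE,
                         colour = "#c0392b") +
    ggplot2::labs(title = gene,
                  subtitle = sprintf("partial Spearman r = %.2f", r),
                  x = "residualized trait", y = "residualized expression") +
    ggplot2::theme_minimal()
}
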