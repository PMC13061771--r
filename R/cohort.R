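#' Stratify a cohort by a clinical variable
#'
#' Splits samples into a low group (value `<=` threshold) and a high group
#' (value `>` threshold). The study stratifications are epilepsy duration at
#' 20 years (short vs. long duration) and onset age at 12 years (childhood-
#' vs. adolescent-onset, ChOE vs. AOE); boundary values fall in the low
#' group, so a patient with onset age exactly 12 is childhood-onset.
#'
#' @param clinical Clinical tibble (see [read_clinical_table()]).
#' @param variable `"duration"` or `"onset_age"`.
#' @param threshold Cut-point in years.
#' @return A tibble with columns `sample_id`, `value` and `group`
#'   (factor `low`/`high`), carrying `variable` and `threshold` attributes.
#' @export
stratify <- function(clinical, variable = c("duration", "onset_age"),
                     threshold) {
  variable <- match.arg(variable)
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  v <- clinical[[variable]]
  if (anyNA(v)) {
    abort(sprintf("missing %s for sample '%s'", variable,
                  clinical$sample_id[which(is.na(v))[1]]),
          class = "epichron_error_missing_value")
  }
  out <- tibble(
    sample_id = clinical$sample_id,
    value = v,
    group = factor(ifelse(v <= threshold, "low", "high"),
                   levels = c("low", "high"))
  )
  attr(out, "variable") <- variable
  attr(out, "threshold") <- threshold
  out
}

#' Descriptive statistics of one group
#'
#' Count, mean, sample standard deviation (n-1 denominator; `NA` for a
#' single observation), minimum and maximum.
#'
#' @param values Non-empty numeric vector.
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `min`, `max`.
#' @export
describe_group <- function(values) {
  stopifnot(length(values) >= 1, is.numeric(values))
  tibble(n = length(values), mean = mean(values),
         sd = if (length(values) >= 2) sd(values) else NA_real_,
         min = min(values), max = max(values))
}

#' Two-group rank-sum (Mann-Whitney U) test
#'
#' Two-sided Mann-Whitney comparison with midranks for ties. The default
#' normal approximation uses the tie-corrected variance
#' `n1*n2/12 * ((N+1) - sum(t^3 - t)/(N*(N-1)))` and a 0.5 continuity
#' correction toward the null mean `n1*n2/2`. `method = "exact"` instead
#' enumerates all assignments of the pooled values to the two groups and
#' returns the exact two-sided permutation p-value of U (feasible for small
#' groups; used as a cross-check).
#'
#' If every pooled value is identical the variance is zero and p = 1 by
#' convention.
#'
#' @param a,b Numeric vectors, each non-empty.
#' @param method `"normal"` (default) or `"exact"`.
#' @return An object of class `rank_sum_test` with elements `U` (statistic
#'   of group `a`), `z` (standardized statistic; `NA` for the exact method),
#'   `p`, `n1`, `n2`, `method`.
#' @export
rank_sum_test <- function(a, b, method = c("normal", "exact")) {
  method <- match.arg(method)
  stopifnot(length(a) >= 1, length(b) >= 1)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (method == "exact") {
    d <- abs(rank_sum_null_U(r, n1) - mu)
    p <- mean(d >= abs(U - mu) - 1e-9)
    z <- NA_real_
  } else {
    ties <- table(pooled)
    tie_term <- sum(ties^3 - ties)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
    if (sigma2 <= 0) {
      z <- 0
      p <- 1
    } else {
      cc <- sign(U - mu) * 0.5
      z <- (U - mu - cc) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  structure(list(U = U, z = z, p = p, n1 = n1, n2 = n2, method = method),
            class = "rank_sum_test")
}

# all U values over assignments of the pooled midranks to group 1
rank_sum_null_U <- function(r, n1) {
  N <- length(r)
  if (choose(N, n1) > 5e5) {
    abort("exact rank-sum enumeration infeasible for this group size",
          class = "epichron_error_infeasible")
  }
  idx <- utils::combn(N, n1)
  colSums(matrix(r[idx], nrow = n1)) - n1 * (n1 + 1) / 2
}

#' @export
print.rank_sum_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney rank-sum test (%s)\n", x$method))
  cat(sprintf("  U = %g (n1 = %d, n2 = %d)", x$U, x$n1, x$n2))
  if (!is.na(x$z)) cat(sprintf(", z = %.4f", x$z))
  cat(sprintf("\n  two-sided p = %.4g\n", x$p))
  invisible(x)
}

#' @export
tidy.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$U, z = x$z, p.value = x$p,
         method = paste0("Mann-Whitney (", x$method, ")"))
}

#' @export
glance.rank_sum_test <- function(x, ...) {
  tibble(statistic = x$U, z = x$z, p.value = x$p, n1 = x$n1, n2 = x$n2,
         method = x$method)
}

#' Seizure-frequency category
#'
#' Classifies baseline seizure frequency into the low (`<= 2`
#' seizures/month) or high (`> 2` seizures/month) seizure group.
#'
#' @param freq Non-negative seizure frequency in seizures/month.
#' @return Factor with levels `low`, `high`.
#' @export
seizure_category <- function(freq) {
  if (any(freq < 0)) {
    abort("seizure frequency must be non-negative",
          class = "epichron_error_bad_value")
  }
  factor(ifelse(freq <= 2, "low", "high"), levels = c("low", "high"))
}

#' Clinical comparison of two strata
#'
#' Reproduces the layout of a clinical descriptive-statistics table for a
#' stratified cohort: per-group descriptive statistics for epilepsy
#' duration, baseline seizure frequency, age and onset age; a two-sided
#' rank-sum p-value per variable (computed also for the stratifying
#' variable, though a published table would omit it there); gender counts
#' per group; and the percentage of each group in the high/low seizure
#' category.
#'
#' @param clinical Clinical tibble.
#' @param cohort Output of [stratify()] on the same samples.
#' @return An object of class `clinical_comparison` with components
#'   `stats`, `tests`, `gender`, `seizure`, and attributes `variable` and
#'   `threshold`. Use [tidy()] for a flat tibble.
#' @export
clinical_comparison_table <- function(clinical, cohort) {
  dat <- left_join(clinical, cohort[c("sample_id", "group")], by = "sample_id")
  if (anyNA(dat$group)) {
    abort("cohort does not cover every clinical sample",
          class = "epichron_error_missing_value")
  }
  if (any(table(dat$group) == 0)) {
    warn("degenerate stratification: one group is empty")
  }
  vars <- c("duration", "seizure_frequency", "age", "onset_age")
  stats <- purrr::map_dfr(vars, function(v) {
    dat %>%
      group_by(.data$group) %>%
      summarise(describe_group(.data[[v]]), .groups = "drop") %>%
      mutate(variable = v, .before = 1)
  })
  tests <- purrr::map_dfr(vars, function(v) {
    lo <- dat[[v]][dat$group == "low"]
    hi <- dat[[v]][dat$group == "high"]
    if (!length(lo) || !length(hi)) {
      return(tibble(variable = v, U = NA_real_, z = NA_real_, p = NA_real_))
    }
    ts <- rank_sum_test(lo, hi)
    tibble(variable = v, U = ts$U, z = ts$z, p = ts$p)
  })
  gender <- dat %>%
    group_by(.data$group) %>%
    summarise(F = sum(.data$gender == "F"), M = sum(.data$gender == "M"),
              .groups = "drop") %>%
    tidyr::complete(group = factor(c("low", "high"), levels = c("low", "high")),
                    fill = list(F = 0L, M = 0L))
  seizure <- dat %>%
    mutate(cat = seizure_category(.data$seizure_frequency)) %>%
    group_by(.data$group) %>%
    summarise(pct_high = 100 * mean(.data$cat == "high"),
              pct_low = 100 * mean(.data$cat == "low"), .groups = "drop")
  structure(list(stats = stats, tests = tests, gender = gender,
                 seizure = seizure),
            variable = attr(cohort, "variable"),
            threshold = attr(cohort, "threshold"),
            class = "clinical_comparison")
}

#' @export
print.clinical_comparison <- function(x, ...) {
  variable <- attr(x, "variable")
  cat(sprintf("Clinical comparison stratified by %s at %g years\n",
              variable, attr(x, "threshold")))
  fmt_p <- function(p) ifelse(p < 0.1, signif(p, 2), round(p, 2))
  for (v in unique(x$stats$variable)) {
    s <- x$stats[x$stats$variable == v, ]
    cat(sprintf("\n%s (n = %s)\n", v, paste(s$n, collapse = " / ")))
    cat(sprintf("  mean %s | sd %s | min %s | max %s\n",
                paste(round(s$mean, 2), collapse = " / "),
                paste(round(s$sd, 2), collapse = " / "),
                paste(round(s$min, 2), collapse = " / "),
                paste(round(s$max, 2), collapse = " / ")))
    if (v != variable) {
      p <- x$tests$p[x$tests$variable == v]
      cat(sprintf("  rank-sum p = %s\n", fmt_p(p)))
    }
  }
  cat("\ngender (F/M): ",
      paste(sprintf("%s: %d/%d", x$gender$group, x$gender$F, x$gender$M),
            collapse = ", "), "\n", sep = "")
  cat("high seizure group (%): ",
      paste(sprintf("%s: %g", x$seizure$group, x$seizure$pct_high),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.clinical_comparison <- function(x, ...) {
  left_join(x$stats, x$tests, by = "variable")
}

#' @export
glance.clinical_comparison <- function(x, ...) {
  tibble(variable = attr(x, "variable"), threshold = attr(x, "threshold"),
         n_low = sum(x$gender$F[x$gender$group == "low"],
                     x$gender$M[x$gender$group == "low"]),
         n_high = sum(x$gender$F[x$gender$group == "high"],
                      x$gender$M[x$gender$group == "high"]))
}
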