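#' Packaged 16-patient clinical fixture
#'
#' The clinical metadata of the 16 temporal-lobe-epilepsy patients used as
#' the reference cohort: GEO sample accession, baseline seizure frequency
#' (seizures/month), gender, age at sampling, epilepsy duration and onset
#' age (years), and etiology (Unk = unknown, TBI = traumatic brain injury,
#' CVA = stroke, Abor = abortion, Ecl = preeclampsia, Inf = infection).
#' Onset age plus duration equals age within the 1-year rounding of the
#' recorded values.
#'
#' @return A 16-row clinical tibble (see [read_clinical_table()] for the
#'   column contract).
#' @export
fixture_clinical_table <- function() {
  as_clinical_table(tibble(
    sample_id = c("GSM6725527", "GSM6725534", "GSM6725528", "GSM6725532",
                  "GSM6725529", "GSM6725530", "GSM6725524", "GSM6725537",
                  "GSM6725536", "GSM6725525", "GSM6725531", "GSM6725538",
                  "GSM6725539", "GSM6725533", "GSM6725526", "GSM6725535"),
    seizure_frequency = c(1, 60, 0.33, 4, 4, 1, 3, 1,
                          2, 0.25, 1, 4, 2, 2, 0.25, 2),
    gender = c("M", "M", "F", "F", "M", "F", "M", "M",
               "M", "M", "F", "M", "F", "M", "M", "F"),
    age = c(26, 19, 32, 45, 16, 35, 38, 26,
            32, 37, 54, 45, 58, 46, 60, 62),
    duration = c(4, 7, 8, 8, 10, 13, 17, 19,
                 25, 35, 36, 37, 37, 43, 47, 61),
    onset_age = c(22, 12, 24, 37, 6, 22, 21, 7,
                  7, 2, 18, 8, 21, 3, 13, 1),
    etiology = c("Unk", "TBI", "CVA", "Abor", "Unk", "Unk", "Unk", "Unk",
                 "Unk", "Unk", "Ecl", "Unk", "Unk", "Unk", "Unk", "Inf")
  ))
}

#' Generate a synthetic epilepsy cohort
#'
#' Draws a clinical table with the dependence structure of the reference
#' cohort: age uniform on 16-62 years, onset age uniform on 1 to age - 3,
#' duration = age - onset age exactly (which induces the natural positive
#' age-duration association that motivates covariate adjustment), gender
#' Bernoulli(1/2), etiology sampled from the fixture's empirical label
#' frequencies, and baseline seizure frequency log-uniform on 0.25-60
#' seizures/month.
#'
#' @param n Number of samples, at least 6.
#' @param seed Integer seed; the same seed reproduces the same table.
#' @return A clinical tibble with sample IDs `S01`, `S02`, ...
#' @export
generate_cohort <- function(n = 16, seed = 1) {
  if (n < 6) {
    abort("a synthetic cohort needs at least 6 samples",
          class = "epichron_error_bad_value")
  }
  set.seed(seed)
  age <- runif(n, 16, 62)
  onset <- runif(n, 1, age - 3)
  etio <- fixture_clinical_table()$etiology
  as_clinical_table(tibble(
    sample_id = sprintf("S%02d", seq_len(n)),
    seizure_frequency = exp(runif(n, log(0.25), log(60))),
    gender = sample(c("F", "M"), n, replace = TRUE),
    age = age,
    duration = age - onset,
    onset_age = onset,
    etiology = sample(etio, n, replace = TRUE)
  ))
}

#' Specification of spiked genes for the expression generator
#'
#' Describes a synthetic gene-by-sample expression matrix on the log2
#' scale: `n_genes` total genes of which fixed numbers have a linear
#' log2-scale dependence on epilepsy duration (positive/negative slope),
#' onset age (positive/negative), or — to emulate age confounding — on age
#' at sampling; all remaining genes are null. Each spiked gene has slope
#' `+/- effect` log2 units per year; every gene gets a baseline drawn from
#' Normal(`baseline_mean_log2`, `baseline_sd_log2`) and i.i.d. Normal(0,
#' `noise_sd`) log2-scale noise.
#'
#' @param n_genes Total gene count (default 2000).
#' @param n_duration_pos,n_duration_neg Genes with positive/negative
#'   dependence on duration (defaults 20/20).
#' @param n_onset_pos,n_onset_neg Same for onset age (defaults 20/20).
#' @param n_age_confounded Genes driven purely by age (default 20).
#' @param effect Slope magnitude, log2 units per year (default 0.05).
#' @param noise_sd Log2-scale noise standard deviation (default 0.5).
#' @param baseline_mean_log2,baseline_sd_log2 Baseline distribution
#'   (defaults 5 and 2).
#' @param seed Integer seed (default 1).
#' @return A validated list of class `spike_spec`.
#' @export
spike_spec <- function(n_genes = 2000,
                       n_duration_pos = 20, n_duration_neg = 20,
                       n_onset_pos = 20, n_onset_neg = 20,
                       n_age_confounded = 20,
                       effect = 0.05, noise_sd = 0.5,
                       baseline_mean_log2 = 5, baseline_sd_log2 = 2,
                       seed = 1) {
  counts <- c(n_duration_pos, n_duration_neg, n_onset_pos, n_onset_neg,
              n_age_confounded)
  if (any(counts < 0) || sum(counts) > n_genes) {
    abort("spiked gene counts must be non-negative and sum to at most n_genes",
          class = "epichron_error_bad_value")
  }
  if (noise_sd < 0 || effect < 0 || baseline_sd_log2 < 0) {
    abort("effect, noise_sd and baseline_sd_log2 must be non-negative",
          class = "epichron_error_bad_value")
  }
  structure(list(n_genes = n_genes,
                 n_duration_pos = n_duration_pos,
                 n_duration_neg = n_duration_neg,
                 n_onset_pos = n_onset_pos,
                 n_onset_neg = n_onset_neg,
                 n_age_confounded = n_age_confounded,
                 effect = effect, noise_sd = noise_sd,
                 baseline_mean_log2 = baseline_mean_log2,
                 baseline_sd_log2 = baseline_sd_log2,
                 seed = seed),
            class = "spike_spec")
}

#' Generate a synthetic expression matrix with ground truth
#'
#' For each gene g and sample s, log2 expression is
#' `baseline_g + beta_g * driver_s + noise`, where the driver is epilepsy
#' duration, onset age, or age at sampling according to the gene's class,
#' `beta_g = +/- effect` for spiked classes and 0 for null genes. The
#' matrix is exported on the CPM-like raw scale `2^log2value` (so all
#' values are strictly positive and the pseudocount/log-transform path is
#' exercised), together with a truth table recording every gene's class and
#' slope. Output is deterministic for a fixed (clinical, spec) pair.
#'
#' @param clinical Clinical tibble providing the drivers.
#' @param spec A [spike_spec()].
#' @return A list with elements `expression` (tibble, `gene_id` + one
#'   column per sample, raw scale) and `truth` (tibble `gene_id`, `class`,
#'   `beta` with class one of `null`, `duration_pos`, `duration_neg`,
#'   `onset_pos`, `onset_neg`, `age_confounded`).
#' @export
generate_expression <- function(clinical, spec = spike_spec()) {
  stopifnot(inherits(spec, "spike_spec"))
  n <- nrow(clinical)
  if (n < 4) {
    abort("clinical table too small for expression generation",
          class = "epichron_error_bad_value")
  }
  set.seed(spec$seed)
  classes <- rep(c("duration_pos", "duration_neg", "onset_pos", "onset_neg",
                   "age_confounded", "null"),
                 times = c(spec$n_duration_pos, spec$n_duration_neg,
                           spec$n_onset_pos, spec$n_onset_neg,
                           spec$n_age_confounded,
                           spec$n_genes - spec$n_duration_pos -
                             spec$n_duration_neg - spec$n_onset_pos -
                             spec$n_onset_neg - spec$n_age_confounded))
  beta <- c(duration_pos = spec$effect, duration_neg = -spec$effect,
            onset_pos = spec$effect, onset_neg = -spec$effect,
            age_confounded = spec$effect, null = 0)[classes]
  driver <- rbind(duration_pos = clinical$duration,
                  duration_neg = clinical$duration,
                  onset_pos = clinical$onset_age,
                  onset_neg = clinical$onset_age,
                  age_confounded = clinical$age,
                  null = rep(0, n))[classes, , drop = FALSE]
  baseline <- rnorm(spec$n_genes, spec$baseline_mean_log2,
                    spec$baseline_sd_log2)
  noise <- matrix(rnorm(spec$n_genes * n, 0, spec$noise_sd), spec$n_genes, n)
  log2_expr <- baseline + beta * driver + noise
  gene_id <- sprintf("G%0*d", nchar(spec$n_genes), seq_len(spec$n_genes))
  expr <- tibble(gene_id = gene_id)
  expr[clinical$sample_id] <- as.data.frame(2^log2_expr)
  list(expression = expr,
       truth = tibble(gene_id = gene_id, class = unname(classes),
                      beta = unname(beta)))
}
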