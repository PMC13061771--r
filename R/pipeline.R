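#' Run the full duration / onset-age transcriptome analysis
#'
#' Executes the complete workflow on an expression matrix and clinical
#' table: expression filtering and log2 transformation; clinical comparison
#' tables for the duration (20-year) and onset-age (12-year)
#' stratifications; differential expression for both stratifications;
#' Spearman trait screening for duration and onset age with optional
#' exclusion of age-associated genes; covariate-adjusted partial Spearman
#' for both traits; directional overlaps (duration-positive vs.
#' onset-negative and duration-negative vs. onset-positive, taken on the
#' reported screening views); and, when a band annotation is supplied,
#' cytogenetic-band over-representation of the combined differentially
#' expressed genes for each stratification. Every table is written as TSV
#' to `out_dir` along with a JSON manifest recording the parameters,
#' stages and files. Inputs are never modified; rerunning with the same
#' inputs and parameters reproduces the outputs byte for byte.
#'
#' @param expr_path Path to the expression matrix (CSV/TSV).
#' @param clinical_path Path to the clinical table.
#' @param out_dir Output directory (created if needed).
#' @param exclusion_path Optional path to an age-associated gene list.
#' @param annotation_path Optional path to a gene-band annotation TSV.
#' @param cpm_threshold,min_fraction,cmp Filtering parameters
#'   (see [filter_low_expressed()]).
#' @param duration_threshold,onset_threshold Stratification cut-points in
#'   years (defaults 20 and 12).
#' @param de_test Per-gene test for [group_de()].
#' @param p_threshold,lfc_threshold,r_threshold Significance thresholds
#'   (defaults 0.05, 0.5, 0.5).
#' @param covariates Covariates for [partial_spearman()].
#' @return Invisibly, a named list of the computed results plus the
#'   manifest.
#' @export
run_epilepsy_pipeline <- function(expr_path, clinical_path, out_dir,
                                  exclusion_path = NULL,
                                  annotation_path = NULL,
                                  cpm_threshold = 1, min_fraction = 0.5,
                                  cmp = "gt",
                                  duration_threshold = 20,
                                  onset_threshold = 12,
                                  de_test = "welch_t",
                                  p_threshold = 0.05, lfc_threshold = 0.5,
                                  r_threshold = 0.5,
                                  covariates = c("age", "gender", "etiology")) {
  for (p in c(expr_path, clinical_path, exclusion_path, annotation_path)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("input file not found: ", p),
            class = "epichron_error_missing_file")
    }
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stages <- character(0)
  files <- character(0)
  results <- list()
  emit <- function(tbl, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write_result_table(tbl, path)
    files[[name]] <<- path
  }
  stage <- function(name, fun) {
    out <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)),
            class = "epichron_error_stage")
    })
    stages <<- c(stages, name)
    out
  }

  clinical <- stage("read", function() {
    results$clinical <<- read_clinical_table(clinical_path)
    results$expression <<- read_expression_matrix(expr_path)
    results$clinical
  })
  expr_log <- stage("preprocess", function() {
    filtered <- filter_low_expressed(results$expression,
                                     cpm_threshold = cpm_threshold,
                                     min_fraction = min_fraction, cmp = cmp)
    pc <- compute_pseudocount(filtered)
    out <- log_transform(filtered, pc)
    results$pseudocount <<- pc
    results$filtered_log <<- out
    emit(out, "filtered_log")
    out
  })
  cohorts <- stage("clinical_stats", function() {
    out <- list(
      duration = stratify(clinical, "duration", duration_threshold),
      onset_age = stratify(clinical, "onset_age", onset_threshold))
    for (v in names(out)) {
      cmp_tab <- clinical_comparison_table(clinical, out[[v]])
      results[[paste0("comparison_", v)]] <<- cmp_tab
      emit(tidy(cmp_tab), paste0("clinical_", v))
    }
    out
  })
  results$cohorts <- cohorts
  de <- stage("diffexp", function() {
    out <- purrr::map(cohorts, function(co) {
      group_de(expr_log, co, test = de_test, p_threshold = p_threshold,
               lfc_threshold = lfc_threshold)
    })
    for (v in names(out)) emit(out[[v]], paste0("de_", v))
    results$de <<- out
    out
  })
  exclusion <- if (!is.null(exclusion_path)) {
    read_gene_list(exclusion_path, label = "age-associated")
  } else character(0)
  screens <- stage("correlate", function() {
    out <- purrr::map(
      setNames(c("duration", "onset_age"), c("duration", "onset_age")),
      function(tr) {
        exclude_genes(
          screen_genes(expr_log, clinical, tr, r_threshold = r_threshold,
                       p_threshold = p_threshold),
          exclusion)
      })
    for (v in names(out)) emit(out[[v]], paste0("corr_", v))
    results$screens <<- out
    out
  })
  partials <- stage("partial_correlate", function() {
    out <- purrr::map(
      setNames(c("duration", "onset_age"), c("duration", "onset_age")),
      function(tr) {
        partial_spearman(expr_log, clinical, tr, covariates = covariates,
                         r_threshold = r_threshold,
                         p_threshold = p_threshold)
      })
    for (v in names(out)) emit(out[[v]], paste0("partial_", v))
    results$partials <<- out
    out
  })
  stage("overlap", function() {
    rep_dur <- reported_genes(screens$duration)
    rep_ons <- reported_genes(screens$onset_age)
    sig <- function(scr, dir) scr$gene_id[scr$significant & scr$direction == dir]
    overlaps <- tibble(
      comparison = c("duration_pos_vs_onset_neg", "duration_neg_vs_onset_pos"),
      genes = c(paste(overlap_sets(sig(rep_dur, "positive"),
                                   sig(rep_ons, "negative")), collapse = ","),
                paste(overlap_sets(sig(rep_dur, "negative"),
                                   sig(rep_ons, "positive")), collapse = ",")))
    overlaps$n_genes <- lengths(strsplit(overlaps$genes, ","))
    overlaps$n_genes[!nzchar(overlaps$genes)] <- 0L
    results$overlaps <<- overlaps
    emit(overlaps, "overlaps")
    overlaps
  })
  if (!is.null(annotation_path)) {
    stage("ora", function() {
      annotation <- read_band_annotation(annotation_path)
      universe <- expr_log$gene_id
      out <- purrr::map(de, function(d) {
        hits <- d$gene_id[d$status != "ns"]
        if (!length(hits)) return(tibble())
        cytoband_ora(hits, universe, annotation)
      })
      for (v in names(out)) emit(out[[v]], paste0("ora_", v))
      results$ora <<- out
      out
    })
  }
  manifest <- list(
    package = "epichron",
    version = as.character(utils::packageVersion("epichron")),
    parameters = list(cpm_threshold = cpm_threshold,
                      min_fraction = min_fraction, cmp = cmp,
                      duration_threshold = duration_threshold,
                      onset_threshold = onset_threshold, de_test = de_test,
                      p_threshold = p_threshold,
                      lfc_threshold = lfc_threshold,
                      r_threshold = r_threshold, covariates = covariates,
                      pseudocount = results$pseudocount),
    stages = stages,
    files = as.list(files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
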