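#' Read a gene-by-sample expression matrix
#'
#' Reads a delimited text export of normalized expression (CPM or any
#' non-negative unit) in the dialect used by GREIN gene-level exports:
#' row 1 is a header of sample identifiers, column 1 holds gene identifiers,
#' and every remaining cell is numeric. The delimiter is auto-detected
#' (comma vs. tab) unless given.
#'
#' Duplicated gene identifiers are kept: later occurrences are suffixed with
#' `.1`, `.2`, ... and a warning is emitted, so that gene counts downstream
#' are not silently changed by an identifier collision.
#'
#' @param path Path to a CSV/TSV file.
#' @param delim Field delimiter. `NULL` (default) auto-detects `,` vs tab
#'   from the header line.
#' @return A tibble with a character `gene_id` column followed by one
#'   numeric column per sample, validated so that all values are finite and
#'   non-negative.
#' @export
read_expression_matrix <- function(path, delim = NULL) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(paste0("expression file not found: ", path),
          class = "epichron_error_missing_file")
  }
  if (is.null(delim)) delim <- detect_delim(path)
  dat <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE,
                           name_repair = "minimal")
  as_expression_matrix(dat)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Validate a data frame as an expression matrix
#'
#' Coerces a data frame whose first column holds gene identifiers and whose
#' remaining columns are numeric sample values into the validated layout
#' used throughout the package. Used by [read_expression_matrix()] and by
#' the synthetic generator.
#'
#' @param dat A data frame; column 1 = gene identifiers, the rest numeric.
#' @return A validated expression tibble (`gene_id` + sample columns).
#' @export
as_expression_matrix <- function(dat) {
  if (ncol(dat) < 2) {
    abort("expression table has no sample columns",
          class = "epichron_error_no_samples")
  }
  dat <- as_tibble(dat, .name_repair = "minimal")
  names(dat)[1] <- "gene_id"
  gene_id <- trimws(as.character(dat[[1]]))
  vals <- dat[-1]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad)) {
        abort(sprintf(
          "non-numeric expression value '%s' at gene '%s', sample '%s'",
          col[bad[1]], gene_id[bad[1]], names(vals)[j]),
          class = "epichron_error_non_numeric")
      }
      vals[[j]] <- num
    }
  }
  m <- as.matrix(vals)
  if (anyNA(m) || any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("missing or non-finite expression value at gene '%s', sample '%s'",
                  gene_id[idx[1]], colnames(m)[idx[2]]),
          class = "epichron_error_non_numeric")
  }
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    abort(sprintf("negative expression value at gene '%s', sample '%s'",
                  gene_id[idx[1]], colnames(m)[idx[2]]),
          class = "epichron_error_negative_value")
  }
  if (anyDuplicated(gene_id)) {
    dups <- unique(gene_id[duplicated(gene_id)])
    warn(sprintf("%d duplicated gene identifier(s) suffixed: %s",
                 length(dups), paste(head(dups, 5), collapse = ", ")))
    gene_id <- deduplicate_ids(gene_id)
  }
  if (anyDuplicated(names(vals))) {
    abort("duplicated sample identifiers in header",
          class = "epichron_error_duplicate_samples")
  }
  out <- tibble(gene_id = gene_id)
  out[names(vals)] <- as.data.frame(m)
  out
}

# "a","a","b","a" -> "a","a.1","b","a.2"
deduplicate_ids <- function(ids) {
  counts <- new.env(parent = emptyenv())
  vapply(ids, function(id) {
    k <- if (is.null(counts[[id]])) 0L else counts[[id]]
    counts[[id]] <- k + 1L
    if (k == 0L) id else paste0(id, ".", k)
  }, character(1), USE.NAMES = FALSE)
}

expr_values <- function(expr) {
  m <- as.matrix(expr[-1])
  rownames(m) <- expr$gene_id
  m
}

expr_samples <- function(expr) names(expr)[-1]

#' Read a per-sample clinical metadata table
#'
#' Expects one row per sample with columns for the sample identifier,
#' baseline seizure frequency (seizures/month), gender (`F`/`M`), age
#' (years), epilepsy duration (years), onset age (years) and etiology.
#' Header matching is case-insensitive and ignores whitespace and
#' punctuation, so GEO-style headers such as "Sample GEO accession" or
#' "Baseline seizure frequency (Seizure/month)" are recognized. Etiology
#' labels are kept verbatim.
#'
#' @param path Path to a CSV/TSV file (delimiter auto-detected).
#' @return A tibble with columns `sample_id`, `seizure_frequency`, `gender`,
#'   `age`, `duration`, `onset_age`, `etiology`.
#' @export
read_clinical_table <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(paste0("clinical file not found: ", path),
          class = "epichron_error_missing_file")
  }
  # read as character so a single-sex cohort's "F" column is not guessed
  # as logical; the validator retypes the numeric fields
  dat <- readr::read_delim(path, delim = detect_delim(path),
                           show_col_types = FALSE, progress = FALSE,
                           trim_ws = TRUE,
                           col_types = readr::cols(.default = "c"))
  norm <- gsub("[^a-z0-9]", "", tolower(names(dat)))
  pick <- function(pattern, what) {
    hit <- which(grepl(pattern, norm))
    if (!length(hit)) {
      abort(paste0("clinical table is missing a column for ", what),
            class = "epichron_error_missing_column")
    }
    hit[1]
  }
  i_onset <- pick("onset", "onset age")
  i_dur <- pick("duration", "epilepsy duration")
  i_sample <- pick("sample|accession|^id$", "sample identifier")
  i_freq <- pick("freq", "seizure frequency")
  i_gender <- pick("gender|sex", "gender")
  i_etio <- pick("etiolog|aetiolog", "etiology")
  i_age <- setdiff(which(grepl("age", norm)), c(i_onset, i_dur))
  if (!length(i_age)) {
    abort("clinical table is missing a column for age",
          class = "epichron_error_missing_column")
  }
  as_clinical_table(tibble(
    sample_id = as.character(dat[[i_sample]]),
    seizure_frequency = dat[[i_freq]],
    gender = as.character(dat[[i_gender]]),
    age = dat[[i_age[1]]],
    duration = dat[[i_dur]],
    onset_age = dat[[i_onset]],
    etiology = as.character(dat[[i_etio]])
  ))
}

as_clinical_table <- function(dat) {
  for (col in c("seizure_frequency", "age", "duration", "onset_age")) {
    v <- dat[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (anyNA(num) && !anyNA(v)) {
        abort(sprintf("non-numeric %s for sample '%s'", col,
                      dat$sample_id[which(is.na(num))[1]]),
              class = "epichron_error_non_numeric")
      }
      dat[[col]] <- num
    }
  }
  if (anyNA(dat)) {
    abort("clinical table contains missing values",
          class = "epichron_error_missing_value")
  }
  if (anyDuplicated(dat$sample_id)) {
    abort("duplicated sample identifiers in clinical table",
          class = "epichron_error_duplicate_samples")
  }
  dat$gender <- toupper(trimws(dat$gender))
  bad <- which(!dat$gender %in% c("F", "M"))
  if (length(bad)) {
    abort(sprintf("unknown gender code '%s' for sample '%s'",
                  dat$gender[bad[1]], dat$sample_id[bad[1]]),
          class = "epichron_error_bad_gender")
  }
  if (any(dat$duration <= 0)) {
    abort(sprintf("non-positive epilepsy duration for sample '%s'",
                  dat$sample_id[which(dat$duration <= 0)[1]]),
          class = "epichron_error_bad_value")
  }
  if (any(dat$onset_age < 0) || any(dat$age <= 0) ||
      any(dat$seizure_frequency < 0)) {
    abort("clinical table contains a negative age, onset age or seizure frequency",
          class = "epichron_error_bad_value")
  }
  dat
}

#' Read a plain-text gene list
#'
#' One identifier per line; blank lines and `#` comments are ignored;
#' duplicate identifiers are collapsed.
#'
#' @param path Path to a text file.
#' @param label Optional free-text label describing the list (e.g.
#'   "age-associated"); stored as an attribute.
#' @return A character vector of unique gene identifiers.
#' @export
read_gene_list <- function(path, label = NULL) {
  if (!file.exists(path)) {
    abort(paste0("gene list not found: ", path),
          class = "epichron_error_missing_file")
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  ids <- unique(lines[nzchar(lines)])
  if (!is.null(label)) attr(ids, "label") <- label
  ids
}

#' Read a gene-to-cytogenetic-band annotation
#'
#' Two-column tab-delimited file mapping each gene identifier to exactly one
#' cytogenetic band (e.g. `6p21`). A header row with names matching
#' `gene`/`band` is accepted and skipped; a gene mapped to two different
#' bands is an error.
#'
#' @param path Path to a two-column TSV.
#' @return A tibble with columns `gene_id` and `band`.
#' @export
read_band_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("band annotation not found: ", path),
          class = "epichron_error_missing_file")
  }
  dat <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, trim_ws = TRUE,
                         col_types = readr::cols(.default = "c"))
  if (ncol(dat) != 2) {
    abort("band annotation must have exactly two columns (gene, band)",
          class = "epichron_error_bad_annotation")
  }
  names(dat) <- c("gene_id", "band")
  if (grepl("gene", tolower(dat$gene_id[1])) &&
      grepl("band|cyto", tolower(dat$band[1]))) {
    dat <- dat[-1, ]
  }
  dat <- unique(dat)
  if (anyDuplicated(dat$gene_id)) {
    abort(sprintf("gene '%s' is annotated to more than one band",
                  dat$gene_id[duplicated(dat$gene_id)][1]),
          class = "epichron_error_bad_annotation")
  }
  if (any(!nzchar(dat$band))) {
    abort("empty band label in annotation",
          class = "epichron_error_bad_annotation")
  }
  dat
}

#' Write a result table as TSV
#'
#' Writes any result tibble (per-gene statistics, over-representation
#' results, comparison tables) as tab-delimited text with a header, in input
#' row order, with numeric fields at full precision (at least 6 significant
#' digits round-trip).
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(records, path) {
  records <- as_tibble(records)
  tryCatch(
    readr::write_tsv(records, path, progress = FALSE),
    error = function(e) abort(paste0("cannot write result table: ",
                                     conditionMessage(e)),
                              class = "epichron_error_unwritable")
  )
  invisible(path)
}
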