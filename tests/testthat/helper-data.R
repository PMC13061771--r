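# fixture builders shared across test files

# expression tibble from a numeric matrix (rows = genes)
make_expr <- function(m, gene_ids = sprintf("g%d", seq_len(nrow(m))),
                      sample_ids = sprintf("s%d", seq_len(ncol(m)))) {
  out <- tibble::tibble(gene_id = gene_ids)
  out[sample_ids] <- as.data.frame(m)
  out
}

write_temp <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# the fixture clinical table as a GEO-style CSV on disk
write_fixture_clinical_csv <- function() {
  clin <- epichron::fixture_clinical_table()
  names(clin) <- c("Sample GEO accession",
                   "Baseline seizure frequency (Seizure/month)", "Gender",
                   "Age", "Epilepsy duration", "Onset age", "Etiology")
  path <- tempfile(fileext = ".csv")
  readr::write_csv(clin, path)
  path
}

# small deterministic band annotation over a synthetic universe, including
# a dense band mimicking a susceptibility locus on 6p21
make_band_fixture <- function(n_universe = 200, band_size = 10, seed = 7) {
  set.seed(seed)
  genes <- sprintf("u%03d", seq_len(n_universe))
  bands <- sample(sprintf("%dq%d", 1:8, rep(11:14, 2)), n_universe,
                  replace = TRUE)
  bands[seq_len(band_size)] <- "6p21"
  list(universe = genes,
       annotation = tibble::tibble(gene_id = genes, band = bands))
}
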