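test_that("GREIN-style CSV parses into a validated gene x sample matrix", {
  samples <- sprintf("GSM%07d", 6725524 + 0:15)
  lines <- c(paste(c("gene", samples), collapse = ","),
             paste(c("A", round(runif(16, 0, 50), 3)), collapse = ","),
             paste(c("B", rep(0, 16)), collapse = ","),
             paste(c("C", 1:16), collapse = ","))
  expr <- read_expression_matrix(write_temp(lines))
  expect_equal(dim(expr), c(3L, 17L))
  expect_equal(names(expr)[-1], samples)
  expect_equal(expr$gene_id, c("A", "B", "C"))
  expect_equal(unlist(expr[3, -1], use.names = FALSE), as.numeric(1:16))
})

test_that("invalid expression inputs raise distinct named failures", {
  expect_error(read_expression_matrix(tempfile()),
               class = "epichron_error_missing_file")
  neg <- write_temp(c("gene,s1,s2", "A,1,2", "B,3,-0.5"))
  err <- expect_error(read_expression_matrix(neg),
                      class = "epichron_error_negative_value")
  expect_match(conditionMessage(err), "B")
  expect_match(conditionMessage(err), "s2")
  txt <- write_temp(c("gene,s1,s2", "A,1,abc"))
  expect_error(read_expression_matrix(txt),
               class = "epichron_error_non_numeric")
  expect_error(read_expression_matrix(write_temp(c("gene", "A"))),
               class = "epichron_error_no_samples")
})

test_that("duplicate gene identifiers are suffixed with a warning", {
  path <- write_temp(c("gene,s1,s2", "A,1,2", "A,3,4", "B,5,6", "A,7,8"))
  expect_warning(expr <- read_expression_matrix(path), "duplicated")
  expect_equal(expr$gene_id, c("A", "A.1", "B", "A.2"))
})

test_that("delimiter auto-detection and CRLF line endings both work", {
  body <- c("gene\ts1\ts2", "A\t1.5\t2.5")
  tsv <- write_temp(body, ext = ".tsv")
  crlf <- tempfile(fileext = ".csv")
  con <- file(crlf, "wb")
  writeBin(charToRaw(paste0("gene,s1,s2\r\nA,1.5,2.5\r\n")), con)
  close(con)
  a <- read_expression_matrix(tsv)
  b <- read_expression_matrix(crlf)
  expect_equal(a[-1], b[-1])
})

test_that("clinical fixture CSV round-trips with GEO-style headers", {
  clin <- read_clinical_table(write_fixture_clinical_csv())
  expect_equal(nrow(clin), 16L)
  expect_equal(sum(clin$gender == "M"), 10L)
  expect_equal(sum(clin$gender == "F"), 6L)
  expect_true(all(abs(clin$onset_age + clin$duration - clin$age) <= 1))
  expect_equal(clin, fixture_clinical_table())
})

test_that("clinical validation flags bad records by sample", {
  base <- c("sample_id,seizure_frequency,gender,age,duration,onset_age,etiology")
  bad_gender <- write_temp(c(base, "P1,1,X,30,10,20,Unk"))
  err <- expect_error(read_clinical_table(bad_gender),
                      class = "epichron_error_bad_gender")
  expect_match(conditionMessage(err), "P1")
  onset_zero <- write_temp(c(base, "P1,1,F,30,30,0,Unk"))
  expect_equal(read_clinical_table(onset_zero)$onset_age, 0)
  no_col <- write_temp(c("sample_id,gender,age,duration,onset_age,etiology",
                         "P1,F,30,10,20,Unk"))
  expect_error(read_clinical_table(no_col),
               class = "epichron_error_missing_column")
  non_num <- write_temp(c(base, "P1,1,F,thirty,10,20,Unk"))
  expect_error(read_clinical_table(non_num),
               class = "epichron_error_non_numeric")
})

test_that("gene lists honor comments, blanks and duplicates", {
  path <- write_temp(c("# age-associated genes", "A", "", "B  ", "A",
                       "C # trailing note"), ext = ".txt")
  expect_equal(read_gene_list(path), c("A", "B", "C"))
})

test_that("band annotation enforces one band per gene", {
  ok <- write_temp(c("gene\tband", "A\t6p21", "B\t1q21"), ext = ".tsv")
  ann <- read_band_annotation(ok)
  expect_equal(ann$band, c("6p21", "1q21"))
  dup <- write_temp(c("A\t6p21", "A\t1q21"), ext = ".tsv")
  expect_error(read_band_annotation(dup),
               class = "epichron_error_bad_annotation")
})

test_that("result tables round-trip identifiers exactly and values to 6 sig digits", {
  rec <- tibble::tibble(gene_id = c("GABBR1", "KCNN4"),
                        log2_fc = c(0.6123457, -1.234568e-4),
                        p = c(0.04937512, 0.9000001))
  path <- tempfile(fileext = ".tsv")
  write_result_table(rec, path)
  expect_equal(length(readLines(path)), 3L)
  back <- readr::read_tsv(path, show_col_types = FALSE)
  expect_equal(back$gene_id, rec$gene_id)
  expect_equal(signif(back$log2_fc, 6), signif(rec$log2_fc, 6))
  expect_equal(signif(back$p, 6), signif(rec$p, 6))
  empty <- tibble::tibble(gene_id = character(), p = numeric())
  write_result_table(empty, path)
  expect_equal(length(readLines(path)), 1L)
})
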