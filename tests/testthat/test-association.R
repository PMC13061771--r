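clin <- fixture_clinical_table()

test_that("Spearman correlation matches closed forms and is rank-based", {
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$r, 1)
  expect_equal(spearman_cor(1:5, c(2, 4, 6, 8, 10))$p, 0)
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5))$r, 0.8)
  expect_equal(spearman_cor(1:5, c(2, 1, 4, 3, 5))$r,
               oracle_spearman_d2(1:5, c(2, 1, 4, 3, 5)))
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  for (cc in c(0.001, 1, 50)) {
    expect_equal(spearman_cor(x, log2(x + cc))$r, 1)
  }
  got <- spearman_cor(rep(2, 6), rnorm(6))
  expect_true(is.na(got$r))
  expect_equal(got$p, 1)
})

test_that("the t-approximation p stays close to a permutation p at n = 16", {
  set.seed(41)
  x <- rnorm(16)
  for (rho in c(0, 0.4, 0.7)) {
    y <- rho * x + sqrt(1 - rho^2) * rnorm(16)
    got <- spearman_cor(x, y)
    if (abs(got$r) > 0.9) next
    expect_lte(abs(got$p - oracle_perm_spearman_p(x, y, B = 2e4)), 0.012)
  }
})

test_that("screening flags exact monotone genes and skips constant ones", {
  m <- rbind(2^(0.1 * clin$duration),       # noiseless positive spike
             100 - clin$duration,           # noiseless negative
             rep(7, 16))                    # constant
  expr <- make_expr(m, sample_ids = clin$sample_id)
  got <- screen_genes(expr, clin, "duration")
  expect_equal(got$r[1:2], c(1, -1))
  expect_true(all(got$significant[1:2]))
  expect_equal(got$direction[1:2], c("positive", "negative"))
  expect_false(got$significant[3])
  expect_true(is.na(got$r[3]))
})

test_that("null genes are flagged near the joint rule's theoretical rate", {
  # at n = 16 the null Spearman r has sd 1/sqrt(15), so the |r| > 0.5 and
  # p < 0.05 rule fires for about 5% of independent genes
  set.seed(42)
  G <- 4000
  expr <- make_expr(matrix(rnorm(G * 16), G, 16), sample_ids = clin$sample_id)
  rate <- mean(screen_genes(expr, clin, "duration")$significant)
  expect_gt(rate, 0.05 - 3 * sqrt(0.05 * 0.95 / G))
  expect_lt(rate, 0.05 + 3 * sqrt(0.05 * 0.95 / G))
})

test_that("age-associated exclusion flags records without losing them", {
  rec <- tibble::tibble(gene_id = sprintf("g%d", 1:10), r = runif(10))
  out <- exclude_genes(rec, c("g2", "g5", "g9"))
  expect_equal(nrow(out), 10L)
  expect_equal(sum(out$age_associated), 3L)
  expect_equal(nrow(reported_genes(out)), 7L)
  expect_equal(exclude_genes(rec, character(0))$age_associated, rep(FALSE, 10))
})

test_that("residualization matches closed-form least squares", {
  # intercept only -> centering
  y <- c(4, 9, 1, 6)
  X0 <- matrix(1, 4, 1)
  expect_equal(residualize(y, X0), y - mean(y))
  # exact linear dependence -> zero residuals
  x <- c(1, 2, 3, 5)
  X <- cbind(1, x)
  expect_lt(max(abs(residualize(2 + 3 * x, X))), 1e-10)
  # toy simple regression against the hand formula
  expect_equal(residualize(c(1, 2, 3, 4), X), oracle_simple_ols_resid(x, 1:4))
})

test_that("residuals are orthogonal to every design column", {
  des <- build_design(clin)
  set.seed(43)
  for (i in 1:10) {
    y <- rnorm(16, sd = 5)
    res <- residualize(y, des)
    expect_lt(max(abs(crossprod(des, res))), 1e-8 * sqrt(sum(y^2)) + 1e-10)
  }
})

test_that("the design encodes categoricals against the modal level", {
  des <- build_design(clin)
  expect_equal(nrow(des), 16L)
  expect_true("(Intercept)" %in% colnames(des))
  # 'Unk' dominates etiology and must be the dropped reference level
  expect_false(any(grepl("Unk", colnames(des))))
  expect_true(any(grepl("gender", colnames(des))))
  cl2 <- clin
  cl2$etiology <- "Unk"
  expect_warning(des2 <- build_design(cl2), "constant")
  expect_false(any(grepl("etiology", colnames(des2))))
})

test_that("partial Spearman reduces to plain Spearman without covariates", {
  gen <- generate_expression(clin, spike_spec(n_genes = 60, n_duration_pos = 5, n_duration_neg = 5,
                                          n_onset_pos = 5, n_onset_neg = 5,
                                          n_age_confounded = 5, seed = 44))
  expr <- as_expression_matrix(gen$expression)
  plain <- screen_genes(expr, clin, "duration")
  part <- partial_spearman(expr, clin, "duration", covariates = character(0))
  expect_equal(part$r_partial, plain$r)
  expect_equal(part$p, plain$p)
})

test_that("covariate adjustment strips age-driven confounding", {
  gen <- generate_expression(clin, spike_spec())
  expr <- log_transform(as_expression_matrix(gen$expression), 0.001)
  truth <- gen$truth
  plain <- screen_genes(expr, clin, "duration")
  part <- partial_spearman(expr, clin, "duration")
  conf <- truth$class == "age_confounded"
  nul <- truth$class == "null"
  plain_conf_rate <- mean(plain$significant[conf])
  null_rate <- mean(plain$significant[nul])
  # confounded genes look strongly duration-associated before adjustment...
  expect_gte(plain_conf_rate, 5 * null_rate)
  # ...and adjustment removes at least 80% of those flags
  part_conf_rate <- mean(part$significant[conf])
  expect_lte(part_conf_rate, 0.2 * plain_conf_rate)
  # adjusted r of confounded genes collapses to null-like magnitudes
  expect_lt(mean(abs(part$r_partial[conf])),
            mean(abs(plain$r[conf])) - 0.3)
  # true duration effects keep their sign under adjustment (allowing the
  # sampling noise the strong age-duration collinearity leaves behind)
  pos <- truth$class == "duration_pos"
  neg <- truth$class == "duration_neg"
  expect_gte(mean(part$r_partial[pos] > 0), 0.9)
  expect_gte(mean(part$r_partial[neg] < 0), 0.9)
  expect_gt(mean(part$r_partial[pos]), 0.25)
  expect_lt(mean(part$r_partial[neg]), -0.25)
})

test_that("partial correlation is not invariant to the expression scale", {
  gen <- generate_expression(clin, spike_spec(n_genes = 80, n_duration_pos = 8, n_duration_neg = 8,
                                              n_onset_pos = 8, n_onset_neg = 8,
                                              n_age_confounded = 8, seed = 45))
  expr_raw <- as_expression_matrix(gen$expression)
  expr_log <- log_transform(expr_raw, 0.001)
  a <- partial_spearman(expr_raw, clin, "duration")
  b <- partial_spearman(expr_log, clin, "duration")
  expect_false(isTRUE(all.equal(a$r_partial, b$r_partial)))
})

test_that("the reduced-degrees-of-freedom option is more conservative", {
  gen <- generate_expression(clin, spike_spec(n_genes = 50, n_duration_pos = 5, n_duration_neg = 5,
                                          n_onset_pos = 5, n_onset_neg = 5,
                                          n_age_confounded = 5, seed = 46))
  expr <- as_expression_matrix(gen$expression)
  a <- partial_spearman(expr, clin, "duration")
  b <- partial_spearman(expr, clin, "duration", df_adjust = TRUE)
  expect_equal(a$r_partial, b$r_partial)
  expect_true(all(b$p >= a$p - 1e-12))
})

test_that("directional overlap is a sorted intersection", {
  expect_equal(overlap_sets(c("A", "B", "C"), c("C", "B", "D")), c("B", "C"))
  expect_equal(overlap_sets(c("A"), c("B")), character(0))
  expect_equal(overlap_sets(c("B", "A"), c("B", "A")), c("A", "B"))
})
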