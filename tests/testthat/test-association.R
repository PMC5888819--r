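covars <- function(n, seed = 1) {
  withr::with_seed(seed, list(age = rnorm(n, 65, 10),
                              sex = sample(c("M", "F"), n, replace = TRUE)))
}

test_that("an exactly linear relationship is fitted exactly", {
  n <- 30
  cv <- covars(n)
  mi <- withr::with_seed(2, rnorm(n))
  mr <- -0.3 * mi
  fit <- fit_association(mr, mi, cv$age, cv$sex)
  expect_equal(fit$beta, -0.3, tolerance = 1e-9)
  expect_gt(fit$f_observed, 1e10)
})

test_that("degenerate predictors and short inputs raise typed errors", {
  n <- 20
  cv <- covars(n)
  mr <- withr::with_seed(3, rnorm(n))
  expect_error(fit_association(mr, rep(0, n), cv$age, cv$sex),
               class = "mirlink_collinearity_error")
  expect_error(fit_association(mr[1:4], rnorm(4), cv$age[1:4], cv$sex[1:4]),
               class = "mirlink_size_error")
  expect_error(fit_association(mr, rnorm(n), cv$age, rep(NA, n)),
               class = "mirlink_size_error")
})

test_that("the slope matches a closed-form normal-equations solve", {
  # six subjects, hand-checkable design
  y <- c(2.0, 1.5, -0.5, 0.25, -1.0, 3.0)
  x <- c(1.0, 0.5, -1.0, 0.0, -2.0, 2.0)
  age <- c(60, 70, 55, 65, 62, 58)
  sexm <- c(1, 0, 1, 0, 1, 0)
  fit <- fit_association(y, x, age, ifelse(sexm == 1, "M", "F"))
  expect_equal(fit$beta, normal_eq_beta(y, x, age, sexm), tolerance = 1e-10)
})

test_that("the residual bootstrap is deterministic and bounded by extremity", {
  n <- 40
  cv <- covars(n, 5)
  mi <- withr::with_seed(6, rnorm(n))
  mr <- withr::with_seed(7, -0.8 * mi + rnorm(n, sd = 0.15))
  fit <- fit_association(mr, mi, cv$age, cv$sex)
  p1 <- bootstrap_pvalue(fit, n_resamples = 2000, seed = 99)
  p2 <- bootstrap_pvalue(fit, n_resamples = 2000, seed = 99)
  expect_identical(p1, p2)
  # a planted strong effect can never be beaten by a resample
  expect_lte(p1, 2 / 2001)
  expect_error(bootstrap_pvalue(fit, n_resamples = 0),
               class = "mirlink_spec_error")
})

test_that("the bootstrap p converges to the classical F-test p", {
  n <- 50
  cv <- covars(n, 8)
  mi <- withr::with_seed(9, rnorm(n))
  mr <- withr::with_seed(10, 0.2 * mi + rnorm(n))  # moderate, p not extreme
  fit <- fit_association(mr, mi, cv$age, cv$sex)
  p_boot <- bootstrap_pvalue(fit, n_resamples = 20000, seed = 123)
  p_f <- pf(fit$f_observed, 1, fit$df_resid, lower.tail = FALSE)
  expect_gt(p_f, 0.01)  # informative comparison, not a degenerate case
  expect_lt(abs(p_boot - p_f), 0.01)
})

test_that("the slope is invariant to affine rescaling of age", {
  n <- 35
  cv <- covars(n, 11)
  mi <- withr::with_seed(12, rnorm(n))
  mr <- withr::with_seed(13, 0.5 * mi + 0.02 * cv$age + rnorm(n, sd = 0.3))
  f1 <- fit_association(mr, mi, cv$age, cv$sex)
  f2 <- fit_association(mr, mi, (cv$age - 50) / 10, cv$sex)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
  expect_equal(f1$f_observed, f2$f_observed, tolerance = 1e-8)
})

test_that("gene-level FDR adjusts within each gene only", {
  res <- tibble::tibble(
    gene = c("g1", "g2", "g2"),
    mirna = c("m1", "m1", "m2"),
    p_raw = c(0.03, 0.0002, 0.0001))
  got <- gene_level_fdr(res)
  expect_equal(got$p_fdr[got$gene == "g1"], 0.03)           # m = 1
  expect_equal(got$p_fdr[got$gene == "g2"], c(2e-4, 2e-4))  # brute-force BH
  glob <- gene_level_fdr(res, scope = "global")
  expect_equal(glob$p_fdr, brute_bh(res$p_raw))
})

test_that("the screen recovers planted pairs and stays deterministic", {
  pa <- tibble::tibble(gene = c("gene001", "gene002"),
                       mirna = c("mir-001", "mir-002"),
                       beta = c(-0.4, 0.4))
  cfg <- synthetic_config(
    n_subjects = 80, n_genes = 4, n_mirnas = 40, nb_dispersion = 0.01,
    subject_sd = 0.35,
    planted_gene_log_fc = setNames(rep(log(2), 2), pa$gene),
    planted_mirna_log_fc = setNames(rep(log(4), 2), pa$mirna),
    planted_assoc = pa,
    gene_log_baseline = setNames(rep(log(50 / 1e6), 2), pa$gene),
    mirna_log_baseline = setNames(rep(log(60), 2), pa$mirna),
    seed = 37)
  st <- generate_study(cfg)$study
  norm <- scale_normalize(st$mirna)
  sm <- st$samples[c("sample_id", "subject", "tissue")]
  rpm <- 1e6 * wide_to_matrix_test(st$mrna, "gene") %*%
    diag(1 / st$samples$total_pc_count)
  colnames(rpm) <- st$samples$sample_id
  rpm_tbl <- dplyr::bind_cols(tibble::tibble(gene = st$mrna$gene),
                              tibble::as_tibble(rpm))
  mrna_d <- paired_diff(rpm_tbl, sm)
  mirna_d <- paired_diff(norm$signals, sm)
  cov <- st$samples[st$samples$tissue == "tumor",
                    c("subject", "age", "sex")]
  # with 40 miRNAs per gene the smallest attainable within-gene FDR p is
  # 40 / (B + 1), so B must comfortably exceed 40 / 0.05
  s1 <- association_screen(mrna_d, mirna_d, cov, n_resamples = 1500, seed = 4)
  s2 <- association_screen(mrna_d, mirna_d, cov, n_resamples = 1500, seed = 4)
  expect_identical(tidy(s1), tidy(s2))
  planted <- dplyr::semi_join(s1, pa, by = c("gene", "mirna"))
  expect_true(all(planted$significant))
  expect_equal(sign(planted$beta), sign(pa$beta))
  expect_true(all(s1$p_fdr >= s1$p_raw))
})
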