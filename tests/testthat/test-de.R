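test_that("rpmpcg is the per-million ratio and scale invariant", {
  expect_equal(rpmpcg(10, 1e6), 10)
  expect_equal(rpmpcg(0, 123456), 0)
  expect_equal(rpmpcg(7, 2e6), rpmpcg(14, 4e6))
  expect_error(rpmpcg(5, 0), class = "mirlink_degenerate_sample_error")
  expect_error(rpmpcg(-1, 10), class = "mirlink_domain_error")
})

test_that("identical tumor and normal counts give fold change 1 and p near 1", {
  n <- 12
  counts <- withr::with_seed(41, rep(rpois(n, 80), 2))
  fit <- fit_paired_nb(counts,
                       tissue = rep(c("tumor", "normal"), each = n),
                       subject = rep(paste0("S", 1:n), 2),
                       offset = rep(log(1e6), 2 * n))
  expect_equal(fit$fold_change, 1, tolerance = 1e-6)
  expect_gt(fit$p_raw, 0.9)
  expect_error(fit_paired_nb(rep(0, 2 * n),
                             rep(c("tumor", "normal"), each = n),
                             rep(paste0("S", 1:n), 2), rep(log(1e6), 2 * n)),
               class = "mirlink_degenerate_gene_error")
  expect_error(fit_paired_nb(c(1, 2), c("tumor", "normal"), c("S1", "S1"),
                             c(0, 0)),
               class = "mirlink_size_error")
})

test_that("a planted halving of expression is estimated within 10%", {
  cfg <- synthetic_config(
    n_subjects = 200, n_genes = 5, n_mirnas = 3,
    planted_gene_log_fc = c(gene002 = log(0.5)),
    gene_log_baseline = c(gene002 = log(50 / 1e6)), seed = 17)
  st <- generate_study(cfg)$study
  de <- de_test(st)
  fc <- de$fold_change[de$gene == "gene002"]
  expect_gt(fc, 0.45)
  expect_lt(fc, 0.55)
  # model fold change tracks the ratio of mean RPMPCG on balanced data
  expect_true(all(abs(de$fold_change / de$mean_ratio - 1) < 0.15))
})

test_that("bh_adjust agrees with a brute-force step-up on random vectors", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "mirlink_domain_error")
  withr::with_seed(33, {
    for (i in 1:200) {
      p <- runif(sample(1:30, 1))
      expect_equal(bh_adjust(p), brute_bh(p))
    }
  })
})

test_that("dysregulation calls follow the strict fold-change and FDR rules", {
  expect_identical(classify_dysregulation(0.18, 6.44e-29), "down")
  expect_identical(classify_dysregulation(3.70, 6.94e-53), "up")
  expect_identical(classify_dysregulation(1.50, 1e-10), "none")
  expect_identical(classify_dysregulation(0.67, 1e-10), "none")
  expect_identical(classify_dysregulation(2.0, 0.05), "none")
  expect_error(classify_dysregulation(-1, 0.01), class = "mirlink_domain_error")
})

test_that("lowering the adjusted p never demotes an up or down call", {
  withr::with_seed(14, {
    fc <- exp(runif(200, log(0.2), log(5)))
    p1 <- runif(200)
    p2 <- p1 * runif(200)   # p2 <= p1
    c1 <- classify_dysregulation(fc, p1)
    c2 <- classify_dysregulation(fc, p2)
    expect_false(any(c1 != "none" & c2 == "none"))
  })
})

test_that("subgroup restriction equals the overall fit when everyone is MSS", {
  cfg <- synthetic_config(n_subjects = 30, n_genes = 6, n_mirnas = 3,
                          frac_msi = 0, seed = 19)
  st <- generate_study(cfg)$study
  overall <- de_test(st)
  mss <- subgroup_de(st, "MSS")
  expect_equal(mss$fold_change, overall$fold_change)
  expect_equal(mss$p_raw, overall$p_raw)
  expect_identical(mss$subgroup[1], "MSS")
  expect_error(de_test(st, subgroup = "MSI"),
               class = "mirlink_subgroup_size_error")
})

test_that("an MSI-only effect is found in the MSI stratum but not in MSS", {
  cfg <- synthetic_config(
    n_subjects = 120, n_genes = 6, n_mirnas = 3, frac_msi = 0.5,
    subgroup_log_fc = tibble::tibble(gene = "gene003", subgroup = "MSI",
                                     log_fc = log(2.5)),
    gene_log_baseline = c(gene003 = log(60 / 1e6)), seed = 23)
  st <- generate_study(cfg)$study
  msi <- de_test(st, subgroup = "MSI")
  mss <- de_test(st, subgroup = "MSS")
  expect_identical(msi$direction[msi$gene == "gene003"], "up")
  expect_identical(mss$direction[mss$gene == "gene003"], "none")
})

test_that("the paired NB engines agree on balanced synthetic data", {
  skip_if_not_installed("glmmTMB")
  cfg <- synthetic_config(n_subjects = 40, n_genes = 3, n_mirnas = 3,
                          planted_gene_log_fc = c(gene001 = log(2)),
                          gene_log_baseline =
                            setNames(rep(log(80 / 1e6), 3),
                                     sprintf("gene%03d", 1:3)),
                          seed = 29)
  st <- generate_study(cfg)$study
  counts <- wide_to_matrix_test(st$mrna, "gene")
  off <- log(st$samples$total_pc_count)
  for (g in rownames(counts)) {
    a <- fit_paired_nb(counts[g, ], st$samples$tissue, st$samples$subject, off,
                       method = "edger")
    b <- fit_paired_nb(counts[g, ], st$samples$tissue, st$samples$subject, off,
                       method = "glmmTMB")
    expect_equal(a$log_fc, b$log_fc, tolerance = 0.05)
  }
})

test_that("genes below the expression cutoff are excluded before fitting", {
  out <- tiny_study(seed = 31, n_subjects = 10)
  st <- out$study
  st$mrna[st$mrna$gene == "gene002", -1] <- 0
  de <- de_test(st)
  expect_false("gene002" %in% de$gene)
  expect_identical(attr(de, "excluded"), "gene002")
})
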