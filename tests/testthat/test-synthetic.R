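test_that("generator is deterministic and a null config plants no effects", {
  cfg <- synthetic_config(n_subjects = 6, n_genes = 4, n_mirnas = 3, seed = 7)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a$study$mrna, b$study$mrna)
  expect_identical(a$study$mirna, b$study$mirna)
  expect_identical(a$study$samples, b$study$samples)
  expect_identical(a$study$utr, b$study$utr)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$truth$true_fc$fc == 1))
  expect_equal(nrow(a$truth$true_beta), 0)
})

test_that("planted fold change shows up in the RPMPCG mean ratio", {
  cfg <- synthetic_config(
    n_subjects = 200, n_genes = 4, n_mirnas = 3,
    planted_gene_log_fc = c(gene001 = log(2)),
    gene_log_baseline = c(gene001 = log(50 / 1e6)), seed = 5)
  st <- generate_study(cfg)$study
  rpm <- rpmpcg(wide_to_matrix_test(st$mrna, "gene"),
                rep(st$samples$total_pc_count, each = nrow(st$mrna)))
  tum <- rowMeans(rpm[, st$samples$tissue == "tumor"])
  nor <- rowMeans(rpm[, st$samples$tissue == "normal"])
  ratio <- tum[["gene001"]] / nor[["gene001"]]
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("with no planted effects per-gene mean ratios converge to 1", {
  cfg <- synthetic_config(n_subjects = 500, n_genes = 8, n_mirnas = 3,
                          gene_log_baseline =
                            setNames(rep(log(50 / 1e6), 8),
                                     sprintf("gene%03d", 1:8)),
                          seed = 21)
  st <- generate_study(cfg)$study
  rpm <- rpmpcg(wide_to_matrix_test(st$mrna, "gene"),
                rep(st$samples$total_pc_count, each = nrow(st$mrna)))
  ratio <- rowMeans(rpm[, st$samples$tissue == "tumor"]) /
    rowMeans(rpm[, st$samples$tissue == "normal"])
  expect_true(all(ratio > 0.9 & ratio < 1.1))
})

test_that("plant_seed_sites packs the exact number of sites and no more", {
  withr::with_seed(11, {
    for (case in list(list(seed = "ACGUAC", n = 2L, len = 1000),
                      list(seed = "ACGUACG", n = 3L, len = 600),
                      list(seed = "ACGUACGU", n = 1L, len = 200),
                      list(seed = "ACGUAC", n = 0L, len = 300))) {
      p <- plant_seed_sites(case$len, case$seed, case$n)
      site <- naive_rc(case$seed)
      hits <- naive_scan(p$sequence, site)
      expect_identical(length(hits), case$n)
      expect_setequal(hits, p$starts)
      expect_true(all(p$starts >= 0 &
                        p$starts <= case$len - nchar(case$seed)))
    }
  })
})

test_that("plant_seed_sites is deterministic under a fixed RNG state", {
  a <- withr::with_seed(4, plant_seed_sites(400, "CGUACGA", 2))
  b <- withr::with_seed(4, plant_seed_sites(400, "CGUACGA", 2))
  expect_identical(a, b)
})

test_that("impossible packings and bad configs raise named errors", {
  expect_error(plant_seed_sites(20, "ACGUAC", 5), class = "mirlink_capacity_error")
  expect_error(plant_seed_sites(100, "ACGT", 1), class = "mirlink_config_error")
  expect_error(synthetic_config(n_subjects = 1),
               regexp = "n_subjects", class = "mirlink_config_error")
  expect_error(synthetic_config(nb_dispersion = 0),
               regexp = "nb_dispersion", class = "mirlink_config_error")
  expect_error(synthetic_config(utr_length = 4),
               regexp = "utr_length", class = "mirlink_config_error")
  expect_error(synthetic_config(frac_msi = 1.2),
               regexp = "frac_msi", class = "mirlink_config_error")
  expect_error(
    synthetic_config(planted_assoc = tibble::tibble(gene = "nope",
                                                    mirna = "mir-001",
                                                    beta = 1)),
    class = "mirlink_config_error")
})

test_that("planted seed sites in a generated study are recoverable by a naive scan", {
  pa <- tibble::tibble(gene = c("gene001", "gene002"),
                       mirna = c("mir-001", "mir-002"),
                       beta = c(-0.5, -0.3))
  cfg <- synthetic_config(n_subjects = 4, n_genes = 3, n_mirnas = 2,
                          planted_assoc = pa,
                          planted_seed_sites =
                            tibble::tibble(gene = c("gene001", "gene002"),
                                           mirna = c("mir-001", "mir-002"),
                                           n_sites = c(2L, 1L)),
                          seed = 13)
  out <- generate_study(cfg)
  st <- out$study
  for (k in seq_len(nrow(pa))) {
    mat <- st$mirna_seq$sequence[st$mirna_seq$mirna == pa$mirna[k]]
    utr <- st$utr$sequence[st$utr$gene == pa$gene[k]]
    expected_n <- c(2L, 1L)[k]
    for (len in 6:8) {
      site <- naive_rc(substr(mat, 2, 1 + len))
      expect_identical(length(naive_scan(utr, site)), expected_n)
    }
    truth_starts <- out$truth$true_seed_sites |>
      dplyr::filter(gene == pa$gene[k], mirna == pa$mirna[k])
    expect_identical(sort(truth_starts$start),
                     sort(naive_scan(utr, naive_rc(substr(mat, 2, 9)))))
  }
})
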