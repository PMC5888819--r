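test_that("seeds are the windows starting at mature position 2", {
  s <- extract_seeds("ACGUACGUACGU")
  expect_equal(s$seed, c("CGUACG", "CGUACGU", "CGUACGUA"))
  expect_equal(s$seed_length, 6:8)
  expect_true(all(s$mirna_start == 2))
  # truncation: length-8 mature yields only the 6- and 7-mer
  expect_equal(extract_seeds("ACGUACGU")$seed_length, 6:7)
  # case normalization
  expect_equal(extract_seeds("acguacguacgu")$seed, s$seed)
  expect_error(extract_seeds("ACGTACGTACGT"), class = "mirlink_alphabet_error")
  expect_error(extract_seeds("ACGUAC"), class = "mirlink_alphabet_error")
})

test_that("scan_utr reports exact reverse-complement hits with 0-based spans", {
  seeds <- extract_seeds("ACGUACGUACGU", mirna = "m1")
  expect_identical(nrow(scan_utr("", seeds)), 0L)
  expect_error(scan_utr("ACGT", seeds[0, ]), class = "mirlink_spec_error")
  # place the 6-mer site at offset 10: RC("CGUACG") == "CGTACG"
  utr <- paste0(strrep("T", 10), "CGTACG", strrep("T", 10))
  hits <- scan_utr(utr, seeds[seeds$seed_length == 6, ])
  expect_equal(hits$start, 10L)
  expect_equal(hits$end, 16L)
  # N never matches
  utr_n <- sub("CGTACG", "CGTNCG", utr)
  expect_identical(nrow(scan_utr(utr_n, seeds[seeds$seed_length == 6, ])), 0L)
  # overlapping occurrences are all reported
  seeds_aa <- extract_seeds("AAAAAAAAAA", mirna = "m2")
  hits_aa <- scan_utr("TTTTTTTT", seeds_aa[seeds_aa$seed_length == 6, ])
  expect_equal(hits_aa$start, 0:2)
})

test_that("scan_utr equals the naive substring oracle on random cases", {
  withr::with_seed(55, {
    for (i in 1:200) {
      utr <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE),
                   collapse = "")
      mature <- paste(sample(c("A", "C", "G", "U"), 12, replace = TRUE),
                      collapse = "")
      seeds <- extract_seeds(mature, mirna = "m")
      got <- scan_utr(utr, seeds)
      for (len in 6:8) {
        site <- naive_rc(seeds$seed[seeds$seed_length == len])
        expect_identical(sort(got$start[got$seed_length == len]),
                         as.integer(sort(naive_scan(utr, site))))
      }
    }
  })
})

test_that("every 7-mer hit contains a 6-mer hit at the same offset", {
  withr::with_seed(56, {
    for (i in 1:50) {
      utr <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
                   collapse = "")
      seeds <- extract_seeds(paste(sample(c("A", "C", "G", "U"), 10,
                                          replace = TRUE), collapse = ""),
                             mirna = "m")
      got <- scan_utr(utr, seeds)
      s7 <- got$start[got$seed_length == 7]
      s6 <- got$start[got$seed_length == 6]
      # seeds share start position 2, so the 6-mer site is the suffix of the
      # 7-mer site: a 7-mer match at s implies a 6-mer match at s + 1
      expect_true(all((s7 + 1L) %in% s6))
    }
  })
})

test_that("direct calls need both a seed match and a negative slope", {
  assoc <- tibble::tibble(
    gene = c("PDGFRA", "MYC", "HSPA8"),
    mirna = c("hsa-miR-17-5p", "hsa-miR-17-5p", "hsa-miR-17-5p"),
    beta = c(-0.28, 0.35, 0.27))
  matches <- tibble::tibble(gene = c("PDGFRA", "HSPA8"),
                            mirna = "hsa-miR-17-5p", record = gene,
                            seed_length = 7L, start = 5L, end = 12L)
  calls <- classify_interaction(assoc, matches)
  expect_identical(calls$call, c("direct", "indirect", "indirect"))
  expect_identical(calls$has_seed_match, c(TRUE, FALSE, TRUE))
})

test_that("per-miRNA summaries partition genes by match status", {
  tb <- load_mapk_tables()
  calls <- classify_interaction(
    tb$mirna_assoc[c("gene", "mirna", "beta")],
    tb$mirna_assoc |> dplyr::filter(seed_match) |>
      dplyr::transmute(gene, mirna, record = gene, seed_length = NA_integer_,
                       start = NA_integer_, end = NA_integer_))
  sm <- summarize_by_mirna(calls)
  m150 <- sm[sm$mirna == "hsa-miR-150-5p", ]
  expect_identical(m150$n_with_match, 3L)
  expect_identical(m150$n_without_match, 4L)
  expect_identical(m150$genes_with_match, "PDGFRA,PRKCB,RASGRP3")
  one <- summarize_by_mirna(calls[1, ])
  expect_identical(nrow(one), 1L)
  expect_identical(nrow(summarize_by_mirna(calls[0, ])), 0L)
})

test_that("isoform records are scanned per record and matched at gene level", {
  utr <- tibble::tibble(
    gene = c("g1", "g1", "g2"),
    record = c("g1-201", "g1-202", "g2-201"),
    sequence = c(strrep("T", 40),
                 paste0(strrep("T", 8), "CGTACG", strrep("T", 8)),
                 strrep("A", 40)))
  seeds <- extract_seeds("ACGUACGUACGU", mirna = "m1")
  got <- scan_seed_matches(utr, seeds[seeds$seed_length == 6, ])
  expect_identical(unique(got$gene), "g1")
  expect_identical(unique(got$record), "g1-202")
})
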