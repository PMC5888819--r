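#' Configuration for a full pipeline run
#'
#' Collects every analysis setting in one declarative object. Defaults are
#' the study's stated settings: FDR 0.05, fold-change thresholds 1.50 /
#' 0.67, the >20%-of-normals miRNA expression filter, and 10,000 bootstrap
#' resamples.
#'
#' @param fdr FDR threshold used both for gene dysregulation and for the
#'   association screen.
#' @param fc_up,fc_down Fold-change thresholds (require
#'   `fc_down < 1 < fc_up`).
#' @param min_normal_fraction miRNA detection filter threshold.
#' @param n_resamples Bootstrap resamples per association test.
#' @param subgroups Tumor-phenotype subgroups to analyse separately
#'   (subset of `c("MSI", "MSS")`; `character()` to skip).
#' @param gene_list Optional pathway gene set to restrict the mRNA screen.
#' @param mirna_scope `"dysregulated"` crosses dysregulated genes with
#'   dysregulated miRNAs (both past the fold-change thresholds);
#'   `"filtered"` uses every filter-retained miRNA instead.
#' @param max_zero_frac Unexpressed-gene exclusion threshold for
#'   [de_test()].
#' @param seed Integer seed for the bootstrap stream.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(fdr = 0.05, fc_up = 1.50, fc_down = 0.67,
                            min_normal_fraction = 0.20, n_resamples = 10000,
                            subgroups = c("MSI", "MSS"), gene_list = NULL,
                            mirna_scope = c("dysregulated", "filtered"),
                            max_zero_frac = 0.9, seed = 1L) {
  mirna_scope <- match.arg(mirna_scope)
  cfg <- list(fdr = fdr, fc_up = fc_up, fc_down = fc_down,
              min_normal_fraction = min_normal_fraction,
              n_resamples = n_resamples, subgroups = subgroups,
              gene_list = gene_list, mirna_scope = mirna_scope,
              max_zero_frac = max_zero_frac, seed = as.integer(seed))
  if (any(c(cfg$fdr, cfg$fc_up, cfg$fc_down) <= 0))
    stop_mirlink("Thresholds must be positive.", "config_error")
  if (!(cfg$fc_down < 1 && 1 < cfg$fc_up))
    stop_mirlink("Need fc_down < 1 < fc_up.", "config_error")
  if (!is.null(cfg$gene_list) && length(cfg$gene_list) == 0)
    stop_mirlink("`gene_list` is empty.", "config_error")
  if (cfg$n_resamples < 1)
    stop_mirlink("`n_resamples` must be >= 1.", "config_error")
  structure(cfg, class = "pipeline_config")
}

#' Run the full paired miRNA-mRNA integration pipeline
#'
#' Executes the stages in order: 75th-percentile normalization of the
#' miRNA signals; the >20%-of-normals expression filter; paired
#' negative-binomial differential expression of the genes (overall and per
#' MSI/MSS subgroup) with BH adjustment and fold-change classification;
#' fold-change classification of the filtered miRNAs; the
#' covariate-adjusted residual-bootstrap association screen of
#' dysregulated genes against dysregulated miRNAs; seed-region scanning of
#' the genes' 3'UTRs; and direct/indirect interaction calls for the
#' significant associations. Subjects with unknown MSI status contribute
#' to the overall analysis only.
#'
#' @param study A [paired_study()] with `utr` and `mirna_seq` components.
#' @param config A [pipeline_config()].
#' @return A list of class `mirlink_run`: `de` (overall + subgroup
#'   [de_test()] tables), `mirna_fc` (per-miRNA means, fold change and
#'   dysregulation flag), `mirna_filter`, `associations`, `seed_matches`,
#'   `calls`, `mirna_summary`, `run_log` (one structured row per stage,
#'   recording the settings and seed).
#' @export
run_pipeline <- function(study, config = pipeline_config()) {
  if (!inherits(study, "paired_study"))
    stop_mirlink("`study` must be a paired_study.", "config_error")
  if (!inherits(config, "pipeline_config"))
    stop_mirlink("`config` must come from pipeline_config().", "config_error")
  log_rows <- list()
  log_stage <- function(stage, detail, n_in, n_out, t0) {
    log_rows[[length(log_rows) + 1]] <<- tibble(
      stage = stage, detail = detail, n_in = n_in, n_out = n_out,
      elapsed_s = round(as.numeric(proc.time()[3] - t0), 3))
  }

  t0 <- proc.time()[3]
  norm <- scale_normalize(study$mirna)
  log_stage("normalize", "75th-percentile scaling", nrow(study$mirna),
            nrow(norm$signals), t0)

  t0 <- proc.time()[3]
  normal_ids <- study$samples$sample_id[study$samples$tissue == "normal"]
  filt <- expression_filter(norm$signals, normal_ids,
                            config$min_normal_fraction)
  kept <- filt$mirna[filt$retained]
  log_stage("mirna_filter",
            sprintf("detected in > %g%% of normals", 100 * config$min_normal_fraction),
            nrow(filt), length(kept), t0)

  t0 <- proc.time()[3]
  de_overall <- de_test(study, genes = config$gene_list, subgroup = "overall",
                        fdr = config$fdr, fc_up = config$fc_up,
                        fc_down = config$fc_down,
                        max_zero_frac = config$max_zero_frac)
  de_tables <- list(overall = de_overall)
  for (sg in config$subgroups) {
    de_tables[[sg]] <- de_test(study, genes = config$gene_list, subgroup = sg,
                               fdr = config$fdr, fc_up = config$fc_up,
                               fc_down = config$fc_down,
                               max_zero_frac = config$max_zero_frac)
  }
  de <- list_rbind(map(de_tables, tidy))
  log_stage("mrna_de", paste("paired NB model;", "subgroups:",
                             paste(c("overall", config$subgroups),
                                   collapse = ",")),
            nrow(study$mrna), nrow(de), t0)

  t0 <- proc.time()[3]
  sample_map <- study$samples[c("sample_id", "subject", "tissue")]
  mirna_d <- paired_diff(norm$signals |> filter(.data$mirna %in% kept),
                         sample_map)
  mirna_fc <- mirna_d |>
    group_by(.data$mirna) |>
    summarize(tumor_mean = mean(.data$tumor), normal_mean = mean(.data$normal),
              fold_change = .data$tumor_mean / .data$normal_mean,
              .groups = "drop") |>
    mutate(dysregulated = .data$fold_change > config$fc_up |
             .data$fold_change < config$fc_down)
  log_stage("mirna_fc", "fold change of normalized signals",
            length(kept), sum(mirna_fc$dysregulated), t0)

  dys_genes <- union(de_overall$gene[de_overall$direction != "none"],
                     unlist(map(de_tables[config$subgroups],
                                function(x) x$gene[x$direction != "none"])))
  dys_genes <- sort(dys_genes)
  dys_mirnas <- if (config$mirna_scope == "dysregulated")
    mirna_fc$mirna[mirna_fc$dysregulated] else mirna_fc$mirna

  t0 <- proc.time()[3]
  rpm <- matrix_to_wide(rpmpcg_matrix(study), "gene")
  mrna_d <- paired_diff(rpm |> filter(.data$gene %in% dys_genes), sample_map)
  covariates <- study$samples |>
    filter(.data$tissue == "tumor") |>
    select("subject", "age", "sex")
  assoc <- if (length(dys_genes) && length(dys_mirnas)) {
    association_screen(mrna_d, mirna_d, covariates,
                       genes = dys_genes, mirnas = dys_mirnas,
                       n_resamples = config$n_resamples, seed = config$seed,
                       fdr = config$fdr)
  } else {
    tibble(gene = character(), mirna = character(), beta = double(),
           f_observed = double(), p_raw = double(), p_fdr = double(),
           n_subjects = integer(), significant = logical())
  }
  log_stage("association_screen",
            sprintf("bootstrap B=%d, seed=%d", config$n_resamples, config$seed),
            length(dys_genes) * length(dys_mirnas), sum(assoc$significant), t0)

  t0 <- proc.time()[3]
  sig <- assoc |> filter(.data$significant)
  matches <- if (nrow(sig) && !is.null(study$utr) &&
                 !is.null(study$mirna_seq)) {
    seeds <- seed_table(study$mirna_seq |>
                          filter(.data$mirna %in% unique(sig$mirna)))
    scan_seed_matches(study$utr |> filter(.data$gene %in% unique(sig$gene)),
                      seeds, pairs = sig[c("gene", "mirna")])
  } else {
    tibble(gene = character(), record = character(), mirna = character(),
           seed_length = integer(), start = integer(), end = integer())
  }
  calls <- classify_interaction(sig[c("gene", "mirna", "beta", "p_fdr")],
                                matches)
  summary <- summarize_by_mirna(calls)
  log_stage("seed_match", "6/7/8-mer reverse-complement scan",
            nrow(sig), nrow(matches), t0)

  structure(list(
    de = de, mirna_fc = mirna_fc, mirna_filter = filt,
    scale_factors = norm$scale_factors,
    associations = assoc, seed_matches = matches, calls = calls,
    mirna_summary = summary,
    run_log = bind_rows(log_rows),
    config = config
  ), class = "mirlink_run")
}

#' @export
print.mirlink_run <- function(x, ...) {
  g <- x$de |> filter(.data$subgroup == "overall")
  cat("<mirlink_run>\n")
  cat(sprintf("  genes: %d tested, %d dysregulated overall (%d up, %d down)\n",
              nrow(g), sum(g$direction != "none"), sum(g$direction == "up"),
              sum(g$direction == "down")))
  cat(sprintf("  miRNAs: %d past filter, %d dysregulated\n",
              nrow(x$mirna_fc), sum(x$mirna_fc$dysregulated)))
  cat(sprintf("  associations: %d tested, %d significant, %d direct\n",
              nrow(x$associations), nrow(x$calls),
              sum(x$calls$call == "direct")))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.mirlink_run <- function(x, ...) {
  g <- x$de |> filter(.data$subgroup == "overall")
  tibble(n_genes_tested = nrow(g),
         n_dysregulated = sum(g$direction != "none"),
         n_mirnas_filtered = nrow(x$mirna_fc),
         n_mirnas_dysregulated = sum(x$mirna_fc$dysregulated),
         n_assoc_tested = nrow(x$associations),
         n_assoc_significant = nrow(x$calls),
         n_direct = sum(x$calls$call == "direct"))
}

#' Write a run's report tables to a directory
#'
#' @param run A [run_pipeline()] result.
#' @param path Output directory (created if missing).
#' @return `path`, invisibly.
#' @export
write_run <- function(run, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$de, file.path(path, "de_genes.tsv"))
  readr::write_tsv(run$mirna_fc, file.path(path, "mirna_fc.tsv"))
  readr::write_tsv(tidy(run$associations), file.path(path, "associations.tsv"))
  readr::write_tsv(run$seed_matches, file.path(path, "seed_matches.tsv"))
  readr::write_tsv(tibble(run$calls), file.path(path, "interaction_calls.tsv"))
  readr::write_tsv(run$mirna_summary, file.path(path, "mirna_summary.tsv"))
  readr::write_tsv(run$run_log, file.path(path, "run_log.tsv"))
  jsonlite::write_json(glance(run), file.path(path, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Replay the packaged study tables through the classification rules
#'
#' Recomputes, from the packaged printed tables alone, the headline counts
#' and arithmetic checks of the original analysis: dysregulated-gene
#' counts by direction, the union of overall and subgroup-specific
#' dysregulated genes, association row/gene counts, the number of direct
#' interactions (seed match with negative slope), the cohort colon-site
#' percentage, and fold-change-as-mean-ratio checks for genes/miRNAs whose
#' printed means reproduce the printed fold change at two decimals.
#'
#' @param tables Output of [load_mapk_tables()] (loaded fresh by default).
#' @param fdr,fc_up,fc_down Thresholds for [classify_dysregulation()].
#' @return Tibble `metric`, `value`, `expected`, `matches` - `expected`
#'   being the count or value printed in the original report.
#' @export
replay_study_tables <- function(tables = load_mapk_tables(), fdr = 0.05,
                                fc_up = 1.50, fc_down = 0.67) {
  de <- tables$de_genes
  cls <- classify_dysregulation(de$fold_change, de$p_adjusted, fdr,
                                fc_up, fc_down)
  assoc <- tables$mirna_assoc
  calls <- classify_interaction(
    assoc |> select("gene", "mirna", "beta"),
    assoc |> filter(.data$seed_match) |> select("gene", "mirna") |>
      mutate(record = .data$gene, seed_length = NA_integer_,
             start = NA_integer_, end = NA_integer_))
  per_mirna <- summarize_by_mirna(calls)
  t4 <- tables$seed_summary
  union_n <- length(union(de$gene, tables$subgroup_genes$gene))
  cohort_colon <- tables$cohort |>
    filter(.data$section == "Site", .data$label == "Colon")
  fgf9 <- de |> filter(.data$gene == "FGF9")
  myc <- de |> filter(.data$gene == "MYC")
  m203 <- assoc |> filter(.data$mirna == "hsa-miR-203a") |> slice(1)
  n_listed <- function(x) {
    ifelse(is.na(x) | x == "", 0L, stringr::str_count(x, ",") + 1L)
  }
  counts_match <- per_mirna |>
    left_join(t4 |>
                transmute(.data$mirna,
                          n_with_match_printed = n_listed(.data$genes_with_match),
                          n_without_match_printed =
                            n_listed(.data$genes_without_match)),
              by = "mirna")
  metric <- function(name, value, expected)
    tibble(metric = name, value = as.numeric(value),
           expected = as.numeric(expected))
  out <- bind_rows(
    metric("de_genes_total", nrow(de), 83),
    metric("de_genes_down", sum(cls == "down"), 60),
    metric("de_genes_up", sum(cls == "up"), 23),
    metric("dysregulated_any_subgroup", union_n, 99),
    metric("assoc_rows", nrow(assoc), 68),
    metric("assoc_genes", length(unique(assoc$gene)), 13),
    metric("direct_interactions", sum(calls$call == "direct"), 13),
    metric("seed_summary_mirnas", nrow(t4), nrow(per_mirna)),
    metric("seed_count_agreement",
           sum(counts_match$n_with_match == counts_match$n_with_match_printed &
                 counts_match$n_without_match ==
                   counts_match$n_without_match_printed, na.rm = TRUE),
           nrow(per_mirna)),
    metric("cohort_colon_count", cohort_colon$count, 169),
    metric("cohort_colon_percent", cohort_colon$percent, 77.9),
    metric("fgf9_mean_ratio", round(fgf9$tumor_mean / fgf9$normal_mean, 2),
           fgf9$fold_change),
    metric("myc_mean_ratio", round(myc$tumor_mean / myc$normal_mean, 2),
           myc$fold_change),
    metric("mir203a_mean_ratio",
           round(m203$mirna_tumor_mean / m203$mirna_normal_mean, 2),
           m203$mirna_fc),
    metric("mir203a_paired_mean_diff",
           m203$mirna_tumor_mean - m203$mirna_normal_mean, 8.82)
  )
  mutate(out, matches = .data$value == .data$expected)
}
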