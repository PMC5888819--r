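#' Reads per million protein-coding genes (RPMPCG)
#'
#' Normalizes a gene's count by the sample's total protein-coding
#' expression, per million: `1e6 * gene_count / total_pc_count`.
#'
#' @param gene_count Non-negative counts (vector or matrix).
#' @param total_pc_count Positive per-sample protein-coding totals,
#'   recycled against `gene_count`.
#' @return Numeric of the same shape as `gene_count`.
#' @export
rpmpcg <- function(gene_count, total_pc_count) {
  if (any(total_pc_count <= 0))
    stop_mirlink("`total_pc_count` must be positive.", "degenerate_sample_error")
  if (any(gene_count < 0))
    stop_mirlink("`gene_count` must be non-negative.", "domain_error")
  1e6 * gene_count / total_pc_count
}

# gene x sample RPMPCG matrix for a paired_study
rpmpcg_matrix <- function(study) {
  counts <- wide_to_matrix(study$mrna, "gene")
  totals <- setNames(study$samples$total_pc_count, study$samples$sample_id)
  sweep(counts, 2, totals[colnames(counts)], function(y, t) 1e6 * y / t)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (a validated front end to
#' [stats::p.adjust()] with `method = "BH"`): order-preserving, capped at 1.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  assert_prob(p, "p")
  p.adjust(p, method = "BH")
}

#' Classify dysregulation from fold change and adjusted p-value
#'
#' A gene (or miRNA) is called `up` when significant
#' (`p_adjusted < fdr_cut`) with fold change strictly above `up_cut`,
#' `down` when significant with fold change strictly below `down_cut`, and
#' `none` otherwise. All comparisons are strict, so a fold change of
#' exactly 1.50 is not a call.
#'
#' @param fold_change Positive fold changes (tumor vs normal).
#' @param p_adjusted Adjusted p-values.
#' @param fdr_cut Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param up_cut,down_cut Fold-change thresholds (defaults 1.50 and 0.67).
#' @return Character vector over `c("up", "down", "none")`.
#' @export
classify_dysregulation <- function(fold_change, p_adjusted, fdr_cut = 0.05,
                                   up_cut = 1.50, down_cut = 0.67) {
  if (any(fold_change <= 0))
    stop_mirlink("`fold_change` must be positive.", "domain_error")
  assert_prob(p_adjusted, "p_adjusted")
  dplyr::case_when(
    p_adjusted < fdr_cut & fold_change > up_cut ~ "up",
    p_adjusted < fdr_cut & fold_change < down_cut ~ "down",
    .default = "none"
  )
}

#' Paired negative-binomial differential-expression test for one gene
#'
#' Fits the paired tumor-vs-normal model for a single gene's counts: mean
#' counts are linked to `exp(subject effect + tissue * beta + offset)`,
#' with the log protein-coding total as offset. The default engine
#' eliminates the subject effect with per-subject intercepts and uses a
#' Cox-Reid adjusted-profile-likelihood dispersion estimate with a
#' likelihood-ratio test of the tissue term (via edgeR); `method =
#' "glmmTMB"` fits the subject effect as a Gaussian random intercept in a
#' negative-binomial mixed model (Laplace approximation) instead, as an
#' independent cross-check.
#'
#' @param counts Integer counts, one per sample.
#' @param tissue Character (`"tumor"`/`"normal"`) per sample.
#' @param subject Subject id per sample; each subject must appear once per
#'   tissue.
#' @param offset Log protein-coding total per sample.
#' @param method `"edger"` (default) or `"glmmTMB"`.
#' @return One-row tibble: `fold_change` (`exp` of the tissue
#'   coefficient), `log_fc` (natural log), `p_raw` (likelihood-ratio test
#'   of the tissue term), `n_pairs`, `method`.
#' @export
fit_paired_nb <- function(counts, tissue, subject,
                          offset, method = c("edger", "glmmTMB")) {
  method <- match.arg(method)
  tissue <- normalize_code(tissue, TISSUE_CODES, "tissue")
  n_pairs <- length(unique(subject))
  if (n_pairs < 2 || length(counts) != 2 * n_pairs)
    stop_mirlink("Need >= 2 complete tumor/normal pairs.", "size_error")
  if (all(counts == 0))
    stop_mirlink("Gene has zero counts in every sample.", "degenerate_gene_error")
  if (method == "edger") {
    m <- matrix(as.numeric(counts), nrow = 1)
    res <- edger_paired_fit(m, tissue, subject, offset)
    return(tibble(fold_change = res$fold_change, log_fc = res$log_fc,
                  p_raw = res$p_raw, n_pairs = n_pairs, method = method))
  }
  if (!requireNamespace("glmmTMB", quietly = TRUE))
    stop_mirlink("method = 'glmmTMB' requires the glmmTMB package.",
                 "config_error")
  d <- data.frame(y = counts, tumor = as.numeric(tissue == "tumor"),
                  subject = factor(subject), off = offset)
  f1 <- tryCatch(
    glmmTMB::glmmTMB(y ~ tumor + (1 | subject) + offset(off),
                     family = glmmTMB::nbinom2, data = d),
    error = function(e) stop_mirlink(paste("NB fit failed:", conditionMessage(e)),
                                     "fit_error"))
  f0 <- glmmTMB::glmmTMB(y ~ 1 + (1 | subject) + offset(off),
                         family = glmmTMB::nbinom2, data = d)
  lrt <- max(0, 2 * (as.numeric(stats::logLik(f1)) -
                       as.numeric(stats::logLik(f0))))
  beta <- glmmTMB::fixef(f1)$cond[["tumor"]]
  tibble(fold_change = exp(beta), log_fc = beta,
         p_raw = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
         n_pairs = n_pairs, method = method)
}

# matrix-level paired NB fit via edgeR; rows = genes
edger_paired_fit <- function(counts, tissue, subject, offset) {
  design <- model.matrix(~ factor(subject) + (tissue == "tumor"))
  colnames(design)[ncol(design)] <- "tumor"
  dge <- edgeR::DGEList(counts)
  dge$offset <- matrix(offset, nrow(counts), ncol(counts), byrow = TRUE)
  dge <- edgeR::estimateDisp(dge, design)
  fit <- edgeR::glmFit(dge, design)
  lrt <- edgeR::glmLRT(fit, coef = "tumor")
  log_fc <- fit$coefficients[, "tumor"]   # natural log scale
  list(fold_change = exp(log_fc), log_fc = log_fc,
       p_raw = lrt$table$PValue)
}

#' Paired differential-expression screen for a study
#'
#' Runs the paired negative-binomial model of [fit_paired_nb()] over all
#' (or selected) genes of a study, adjusts p-values across genes with
#' Benjamini-Hochberg, and classifies dysregulation by fold-change and FDR
#' thresholds. Genes with zero counts in more than `max_zero_frac` of
#' samples are excluded before fitting (recorded in the `excluded`
#' attribute), mirroring the exclusion of unexpressed genes.
#'
#' @param study A [paired_study()].
#' @param genes Optional character vector restricting the screen (e.g. a
#'   pathway gene set).
#' @param subgroup `"overall"` (default), `"MSI"` or `"MSS"`; subgroups
#'   restrict to subjects with that tumor phenotype.
#' @param fdr,fc_up,fc_down Thresholds for [classify_dysregulation()].
#' @param max_zero_frac Exclusion threshold for unexpressed genes
#'   (default 0.9).
#' @return A tibble of class `mirlink_de`: `gene`, `tumor_mean`,
#'   `normal_mean` (arithmetic means of per-sample RPMPCG), `mean_ratio`,
#'   `fold_change` (model estimate, used for classification), `p_raw`,
#'   `p_adjusted`, `direction`, `subgroup`, `n_pairs`.
#' @export
de_test <- function(study, genes = NULL,
                    subgroup = c("overall", "MSI", "MSS"),
                    fdr = 0.05, fc_up = 1.50, fc_down = 0.67,
                    max_zero_frac = 0.9) {
  subgroup <- match.arg(subgroup)
  samples <- study$samples
  if (subgroup != "overall") {
    keep_subj <- unique(samples$subject[samples$msi_status == subgroup])
    if (length(keep_subj) < 2)
      stop_mirlink(sprintf("Subgroup %s has fewer than 2 pairs.", subgroup),
                   "subgroup_size_error")
    samples <- samples[samples$subject %in% keep_subj, ]
  }
  counts <- wide_to_matrix(study$mrna, "gene")[, samples$sample_id,
                                               drop = FALSE]
  if (!is.null(genes)) {
    unknown <- setdiff(genes, rownames(counts))
    if (length(unknown))
      stop_mirlink(paste("Unknown gene(s):", paste(unknown, collapse = ", ")),
                   "key_error")
    counts <- counts[genes, , drop = FALSE]
  }
  zero_frac <- rowMeans(counts == 0)
  excluded <- rownames(counts)[zero_frac > max_zero_frac]
  counts <- counts[zero_frac <= max_zero_frac, , drop = FALSE]
  if (nrow(counts) == 0)
    stop_mirlink("No gene passes the expression filter.", "degenerate_gene_error")

  offset <- log(samples$total_pc_count)
  fitres <- edger_paired_fit(counts, samples$tissue, samples$subject, offset)
  rpm <- sweep(counts, 2, samples$total_pc_count, function(y, t) 1e6 * y / t)
  tum <- rowMeans(rpm[, samples$tissue == "tumor", drop = FALSE])
  nor <- rowMeans(rpm[, samples$tissue == "normal", drop = FALSE])
  out <- tibble(
    gene = rownames(counts),
    tumor_mean = unname(tum),
    normal_mean = unname(nor),
    mean_ratio = unname(tum / nor),
    fold_change = unname(fitres$fold_change),
    p_raw = fitres$p_raw
  ) |>
    mutate(p_adjusted = bh_adjust(.data$p_raw),
           direction = classify_dysregulation(.data$fold_change,
                                              .data$p_adjusted, fdr,
                                              fc_up, fc_down),
           subgroup = subgroup,
           n_pairs = length(unique(samples$subject)))
  attr(out, "excluded") <- excluded
  class(out) <- c("mirlink_de", class(out))
  out
}

#' @rdname de_test
#' @export
subgroup_de <- function(study, subgroup, ...) {
  de_test(study, subgroup = subgroup, ...)
}

#' @exportS3Method generics::tidy
tidy.mirlink_de <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mirlink_de")
  out
}

#' @exportS3Method generics::glance
glance.mirlink_de <- function(x, ...) {
  tibble(subgroup = x$subgroup[1], n_genes = nrow(x),
         n_up = sum(x$direction == "up"),
         n_down = sum(x$direction == "down"),
         n_excluded = length(attr(x, "excluded")),
         n_pairs = x$n_pairs[1])
}
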