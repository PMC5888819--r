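#' Covariate-adjusted association of paired mRNA and miRNA differences
#'
#' Ordinary least squares of the per-subject (tumor - normal) mRNA
#' expression on the per-subject (tumor - normal) miRNA signal, adjusted
#' for age (years, untransformed) and sex (single male indicator). The
#' association statistic is the F statistic comparing this model with the
#' null model that drops the miRNA term.
#'
#' @param mrna_diff,mirna_diff Numeric vectors, one value per subject.
#' @param age Numeric ages in years.
#' @param sex Character `"M"`/`"F"` (or codings recognized by the readers).
#' @return An object of class `assoc_fit`: `beta` (miRNA slope),
#'   `f_observed`, `n`, plus the pieces the residual bootstrap needs
#'   (null-model fitted values and residuals, QR decompositions).
#' @examples
#' set.seed(1)
#' mi <- rnorm(30); mr <- -0.3 * mi + rnorm(30, sd = 0.1)
#' fit <- fit_association(mr, mi, age = rnorm(30, 65, 10),
#'                        sex = sample(c("M", "F"), 30, TRUE))
#' glance(fit)
#' @export
fit_association <- function(mrna_diff, mirna_diff, age, sex) {
  n <- length(mrna_diff)
  if (length(mirna_diff) != n || length(age) != n || length(sex) != n)
    stop_mirlink("All inputs must have one value per subject.", "size_error")
  keep <- complete.cases(mrna_diff, mirna_diff, age, sex)
  if (!all(keep))
    stop_mirlink("Missing values in inputs; drop incomplete subjects first.",
                 "size_error")
  sex <- normalize_code(sex, SEX_CODES, "sex")
  X_full <- cbind(`(Intercept)` = 1, mirna_diff = mirna_diff, age = age,
                  sexM = as.numeric(sex == "M"))
  X_null <- X_full[, -2, drop = FALSE]
  if (n < ncol(X_full) + 1)
    stop_mirlink("Too few subjects for the association model.", "size_error")
  qr_full <- qr(X_full)
  if (qr_full$rank < ncol(X_full))
    stop_mirlink("Rank-deficient design (e.g. constant miRNA differences).",
                 "collinearity_error")
  qr_null <- qr(X_null)
  coefs <- qr.coef(qr_full, mrna_diff)
  rss_full <- sum(qr.resid(qr_full, mrna_diff)^2)
  fitted_null <- qr.fitted(qr_null, mrna_diff)
  resid_null <- mrna_diff - fitted_null
  rss_null <- sum(resid_null^2)
  df2 <- n - ncol(X_full)
  f_obs <- ((rss_null - rss_full) / 1) / (rss_full / df2)
  structure(list(
    beta = unname(coefs["mirna_diff"]), f_observed = f_obs, n = n,
    coefficients = coefs, df_resid = df2,
    qr_full = qr_full, qr_null = qr_null,
    y = mrna_diff, fitted_null = fitted_null, resid_null = resid_null,
    sigma = sqrt(rss_full / df2)
  ), class = "assoc_fit")
}

#' @export
print.assoc_fit <- function(x, ...) {
  cat(sprintf("<assoc_fit> n = %d, beta = %.4g, F = %.4g\n",
              x$n, x$beta, x$f_observed))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.assoc_fit <- function(x, ...) {
  se <- sqrt(diag(chol2inv(qr.R(x$qr_full))) * x$sigma^2)
  tibble(term = names(x$coefficients),
         estimate = unname(x$coefficients),
         std.error = unname(se),
         statistic = unname(x$coefficients / se))
}

#' @exportS3Method generics::glance
glance.assoc_fit <- function(x, ...) {
  tibble(beta = x$beta, f_observed = x$f_observed, n = x$n,
         df_resid = x$df_resid)
}

#' Residual-bootstrap p-value for the miRNA association F statistic
#'
#' Builds the null distribution of the association F statistic by
#' resampling the residuals of the no-association model: in each of `B`
#' rounds, residuals of the null fit (mRNA difference on intercept, age,
#' sex) are resampled with replacement, added back to the null fitted
#' values, and the full-vs-null F statistic is recomputed. The p-value is
#' `(1 + #\{F_b >= F_observed\}) / (B + 1)`, so it is never exactly zero.
#' The observed F is taken from `fit` and never recomputed.
#'
#' @param fit An [fit_association()] object.
#' @param n_resamples Number of bootstrap rounds `B` (default 10000).
#' @param seed Optional integer; when given, the bootstrap runs under a
#'   local RNG state so the p-value is reproducible and the caller's RNG
#'   stream is untouched.
#' @return A single p-value in `(0, 1]`.
#' @export
bootstrap_pvalue <- function(fit, n_resamples = 10000, seed = NULL) {
  if (!inherits(fit, "assoc_fit"))
    stop_mirlink("`fit` must come from fit_association().", "config_error")
  if (n_resamples < 1)
    stop_mirlink("`n_resamples` must be >= 1.", "spec_error")
  with_local_seed(seed, {
    f_boot <- bootstrap_f_stats(fit, n_resamples)
    (1 + sum(f_boot >= fit$f_observed)) / (n_resamples + 1)
  })
}

# vectorized: B bootstrap F statistics from the stored null fit
bootstrap_f_stats <- function(fit, B) {
  n <- fit$n
  idx <- sample.int(n, n * B, replace = TRUE)
  Ystar <- matrix(fit$fitted_null + 0, n, B) +
    matrix(fit$resid_null[idx], n, B)
  Qf <- qr.Q(fit$qr_full)
  Qn <- qr.Q(fit$qr_null)
  tot <- colSums(Ystar^2)
  rss_full <- tot - colSums(crossprod(Qf, Ystar)^2)
  rss_null <- tot - colSums(crossprod(Qn, Ystar)^2)
  pmax(rss_null - rss_full, 0) / (rss_full / fit$df_resid)
}

#' Gene-level Benjamini-Hochberg adjustment of association p-values
#'
#' Applies the BH step-up adjustment separately within each gene, across
#' that gene's miRNA tests only (multiplicity control "at the gene
#' level"). `scope = "global"` adjusts across all rows instead.
#'
#' @param results Tibble with at least `gene` and `p_raw` columns.
#' @param scope `"gene"` (default) or `"global"`.
#' @return `results` with a `p_fdr` column filled in.
#' @export
gene_level_fdr <- function(results, scope = c("gene", "global")) {
  scope <- match.arg(scope)
  if (scope == "gene") {
    results |>
      group_by(.data$gene) |>
      mutate(p_fdr = bh_adjust(.data$p_raw)) |>
      ungroup()
  } else {
    mutate(results, p_fdr = bh_adjust(.data$p_raw))
  }
}

#' Screen all gene x miRNA pairs for paired-difference associations
#'
#' Crosses every candidate gene with every candidate miRNA and, for each
#' pair, fits the covariate-adjusted association of
#' [fit_association()] and computes the residual-bootstrap p-value of
#' [bootstrap_pvalue()]; p-values are then FDR-adjusted at the gene level.
#' Subjects with missing age or sex are dropped (and counted in the
#' `n_dropped` attribute).
#'
#' @param mrna_diff Long tibble from [paired_diff()] for mRNA (RPMPCG
#'   scale): columns `gene`, `subject`, `diff`.
#' @param mirna_diff Long tibble from [paired_diff()] for normalized miRNA
#'   signals: columns `mirna`, `subject`, `diff`.
#' @param covariates Tibble `subject`, `age`, `sex`.
#' @param genes,mirnas Optional restrictions (character vectors); defaults
#'   to everything present.
#' @param n_resamples Bootstrap rounds per pair (default 10000).
#' @param seed Integer seed for the bootstrap stream (default 1); results
#'   are deterministic given `(inputs, seed)`.
#' @param fdr Significance threshold on `p_fdr` (default 0.05).
#' @param fdr_scope Passed to [gene_level_fdr()].
#' @return A tibble of class `mirlink_assoc`: `gene`, `mirna`, `beta`,
#'   `f_observed`, `p_raw`, `p_fdr`, `n_subjects`, `significant`.
#' @export
association_screen <- function(mrna_diff, mirna_diff, covariates,
                               genes = NULL, mirnas = NULL,
                               n_resamples = 10000, seed = 1,
                               fdr = 0.05, fdr_scope = c("gene", "global")) {
  fdr_scope <- match.arg(fdr_scope)
  genes <- genes %||% unique(mrna_diff$gene)
  mirnas <- mirnas %||% unique(mirna_diff$mirna)
  if (length(genes) == 0 || length(mirnas) == 0)
    stop_mirlink("Need at least one gene and one miRNA.", "config_error")
  cov <- covariates |> mutate(sex = normalize_code(.data$sex, SEX_CODES, "sex"))
  complete <- cov[complete.cases(cov$age, cov$sex), ]
  n_dropped <- nrow(cov) - nrow(complete)
  mr <- mrna_diff |> filter(.data$gene %in% genes) |>
    select("gene", "subject", "diff")
  mi <- mirna_diff |> filter(.data$mirna %in% mirnas) |>
    select("mirna", "subject", "diff")
  subj <- Reduce(intersect, list(unique(mr$subject), unique(mi$subject),
                                 complete$subject))
  subj <- sort(subj)
  cov_s <- complete[match(subj, complete$subject), ]
  mr_w <- tidyr::pivot_wider(mr, names_from = "subject", values_from = "diff")
  mi_w <- tidyr::pivot_wider(mi, names_from = "subject", values_from = "diff")
  mr_m <- wide_to_matrix(mr_w[c("gene", subj)], "gene")
  mi_m <- wide_to_matrix(mi_w[c("mirna", subj)], "mirna")
  grid <- tidyr::expand_grid(gene = sort(genes), mirna = sort(mirnas))
  with_local_seed(seed, {
    rows <- pmap(grid, function(gene, mirna) {
      fit <- fit_association(mr_m[gene, ], mi_m[mirna, ],
                             cov_s$age, cov_s$sex)
      p <- bootstrap_pvalue(fit, n_resamples = n_resamples, seed = NULL)
      tibble(gene = gene, mirna = mirna, beta = fit$beta,
             f_observed = fit$f_observed, p_raw = p, n_subjects = fit$n)
    })
    out <- list_rbind(rows)
    out <- gene_level_fdr(out, scope = fdr_scope) |>
      mutate(significant = .data$p_fdr < fdr) |>
      select("gene", "mirna", "beta", "f_observed", "p_raw", "p_fdr",
             "n_subjects", "significant")
    attr(out, "n_dropped") <- n_dropped
    class(out) <- c("mirlink_assoc", class(out))
    out
  })
}

#' @exportS3Method generics::tidy
tidy.mirlink_assoc <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "mirlink_assoc")
  out
}

#' @exportS3Method generics::glance
glance.mirlink_assoc <- function(x, ...) {
  tibble(n_tests = nrow(x), n_genes = length(unique(x$gene)),
         n_mirnas = length(unique(x$mirna)),
         n_significant = sum(x$significant),
         n_subjects = x$n_subjects[1])
}
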