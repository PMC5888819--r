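#' 75th-percentile scaling normalization of miRNA array signals
#'
#' Rescales every sample so that its 75th percentile equals the median of
#' all samples' 75th percentiles: each sample is multiplied by
#' `median(q75 of all samples) / q75(sample)`. This removes multiplicative
#' per-array artifacts (scanner gain, input amount) while preserving
#' relative signal within a sample. Percentiles use the usual linear
#' interpolation between order statistics (quantile type 7).
#'
#' @param signals Wide tibble: column `mirna` plus one numeric column per
#'   sample.
#' @return An object of class `normalized_signals`: list with `signals`
#'   (rescaled wide tibble), `scale_factors` (tibble `sample`, `q75`,
#'   `scale_factor`) and `reference_quantile` (the median 75th percentile).
#' @examples
#' x <- tibble::tibble(mirna = c("a", "b", "c", "d"),
#'                     s1 = c(1, 2, 2, 2), s2 = c(2, 4, 4, 4))
#' scale_normalize(x)$scale_factors
#' @export
scale_normalize <- function(signals) {
  m <- wide_to_matrix(signals, "mirna")
  q75 <- unname(apply(m, 2, quantile, probs = 0.75, names = FALSE, type = 7))
  if (any(q75 <= 0))
    stop_mirlink(paste("Sample(s) with non-positive 75th percentile:",
                       paste(colnames(m)[q75 <= 0], collapse = ", ")),
                 "degenerate_sample_error")
  ref <- stats::median(q75)
  sf <- ref / q75
  scaled <- sweep(m, 2, sf, `*`)
  structure(list(
    signals = matrix_to_wide(scaled, "mirna"),
    scale_factors = tibble(sample = colnames(m), q75 = q75, scale_factor = sf),
    reference_quantile = ref
  ), class = "normalized_signals")
}

#' @export
print.normalized_signals <- function(x, ...) {
  cat(sprintf("<normalized_signals> %d miRNAs x %d samples, reference 75th percentile %.4g\n",
              nrow(x$signals), nrow(x$scale_factors), x$reference_quantile))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.normalized_signals <- function(x, ...) x$scale_factors

#' @exportS3Method generics::glance
glance.normalized_signals <- function(x, ...) {
  tibble(n_mirnas = nrow(x$signals), n_samples = nrow(x$scale_factors),
         reference_quantile = x$reference_quantile)
}

#' Filter miRNAs by detection in normal-mucosa samples
#'
#' Keeps miRNAs whose signal is detected (strictly positive) in strictly
#' more than `min_fraction` of the normal samples. The strict inequality
#' reads "expressed in greater than 20% of normal samples" literally: a
#' miRNA detected in exactly 20% of normals is dropped at
#' `min_fraction = 0.20`.
#'
#' @param signals Wide tibble (`mirna` + sample columns), usually the
#'   `signals` component of [scale_normalize()].
#' @param normal_samples Character vector of normal-sample ids.
#' @param min_fraction Detection-fraction threshold in (0, 1); default 0.20.
#' @return Tibble `mirna`, `n_detected`, `frac_detected`, `retained`.
#' @export
expression_filter <- function(signals, normal_samples, min_fraction = 0.20) {
  if (length(normal_samples) == 0)
    stop_mirlink("`normal_samples` must be nonempty.", "config_error")
  if (min_fraction <= 0 || min_fraction >= 1)
    stop_mirlink("`min_fraction` must lie in (0, 1).", "config_error")
  missing <- setdiff(normal_samples, names(signals))
  if (length(missing))
    stop_mirlink(paste("Unknown sample id(s):", paste(missing, collapse = ", ")),
                 "key_error")
  m <- wide_to_matrix(signals[c("mirna", normal_samples)], "mirna")
  n_det <- unname(rowSums(m > 0))
  frac <- n_det / length(normal_samples)
  tibble(mirna = rownames(m), n_detected = as.integer(n_det),
         frac_detected = frac, retained = frac > min_fraction)
}

#' Per-subject paired (tumor minus normal) differential expression
#'
#' Converts a feature-by-sample table into subject-level differential
#' expression: for each feature and subject, the value in the carcinoma
#' sample minus the value in the matched normal-mucosa sample.
#'
#' @param values Wide tibble: an id column (first column, e.g. `gene` or
#'   `mirna`) plus one numeric column per sample.
#' @param sample_map Tibble with columns `sample_id`, `subject`, `tissue`.
#' @return Long tibble: id column, `subject`, `tumor`, `normal`,
#'   `diff = tumor - normal`.
#' @examples
#' v <- tibble::tibble(mirna = "miR-203a", S1_T = 12.52, S1_N = 3.70)
#' sm <- tibble::tibble(sample_id = c("S1_T", "S1_N"), subject = "S1",
#'                      tissue = c("tumor", "normal"))
#' paired_diff(v, sm)
#' @export
paired_diff <- function(values, sample_map) {
  id_col <- names(values)[1]
  if (nrow(values) == 0) {
    return(tibble(!!id_col := character(), subject = character(),
                  tumor = double(), normal = double(), diff = double()))
  }
  sm <- sample_map
  sm$tissue <- normalize_code(sm$tissue, TISSUE_CODES, "tissue")
  counts <- sm |> count(.data$subject, .data$tissue)
  wide <- tidyr::pivot_wider(counts, names_from = "tissue",
                             values_from = "n", values_fill = 0L)
  if (!all(c("tumor", "normal") %in% names(wide)))
    wide[setdiff(c("tumor", "normal"), names(wide))] <- 0L
  unpaired <- wide$subject[wide$tumor != 1L | wide$normal != 1L]
  if (length(unpaired))
    stop_mirlink(paste("Subjects missing a tissue:",
                       paste(unpaired, collapse = ", ")), "pairing_error")
  missing_cols <- setdiff(sm$sample_id, names(values))
  if (length(missing_cols))
    stop_mirlink(paste("Samples absent from `values`:",
                       paste(missing_cols, collapse = ", ")), "key_error")
  long <- values |>
    tidyr::pivot_longer(-all_of(id_col), names_to = "sample_id",
                        values_to = "value") |>
    inner_join(sm, by = "sample_id")
  long |>
    select(all_of(id_col), "subject", "tissue", "value") |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "value") |>
    mutate(diff = .data$tumor - .data$normal)
}
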