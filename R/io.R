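#' Construct a paired tumor-normal expression study
#'
#' Bundles everything one analysis run needs: per-sample metadata, the mRNA
#' count matrix, the miRNA signal matrix and (optionally) 3'UTR and mature
#' miRNA sequences. Validation enforces the paired design: every subject has
#' exactly one tumor and one normal sample, counts are non-negative
#' integers, and identifiers are unique.
#'
#' @param samples Tibble with one row per sample: `sample_id`, `subject`,
#'   `tissue` (`"tumor"`/`"normal"`), `age` (years), `sex` (`"M"`/`"F"`),
#'   `site`, `msi_status` (`"MSI"`, `"MSS"` or `"unknown"`),
#'   `total_pc_count` (positive integer protein-coding total used as the
#'   model offset).
#' @param mrna Wide tibble: column `gene` plus one non-negative integer
#'   column per `sample_id`.
#' @param mirna Wide tibble: column `mirna` plus one non-negative numeric
#'   column per `sample_id`.
#' @param utr Optional tibble of 3'UTR sequences: `gene`, `record`
#'   (isoform/transcript identifier; a gene may have several), `sequence`
#'   (DNA, `ACGTN`).
#' @param mirna_seq Optional tibble of mature miRNA sequences: `mirna`,
#'   `sequence` (RNA, `ACGU`).
#' @return An object of class `paired_study`.
#' @export
paired_study <- function(samples, mrna, mirna, utr = NULL, mirna_seq = NULL) {
  study <- structure(
    list(samples = as_tibble(samples), mrna = as_tibble(mrna),
         mirna = as_tibble(mirna),
         utr = if (!is.null(utr)) as_tibble(utr),
         mirna_seq = if (!is.null(mirna_seq)) as_tibble(mirna_seq)),
    class = "paired_study")
  validate_paired_study(study)
}

# canonical recodings accepted for free-text metadata
SEX_CODES <- c(M = "M", MALE = "M", F = "F", FEMALE = "F")
TISSUE_CODES <- c(TUMOR = "tumor", TUMOUR = "tumor", CARCINOMA = "tumor",
                  T = "tumor", NORMAL = "normal", MUCOSA = "normal",
                  N = "normal")
MSI_CODES <- c(MSI = "MSI", MSS = "MSS", UNSTABLE = "MSI", STABLE = "MSS",
               UNKNOWN = "unknown", NA_ = "unknown")

normalize_code <- function(x, codes, what) {
  key <- toupper(trimws(as.character(x)))
  key[is.na(key) | key == ""] <- "NA_"
  out <- unname(codes[key])
  if (anyNA(out))
    stop_mirlink(sprintf("Unrecognized %s value(s): %s", what,
                         paste(unique(x[is.na(out)]), collapse = ", ")),
                 "format_error")
  out
}

validate_paired_study <- function(study) {
  s <- study$samples
  need <- c("sample_id", "subject", "tissue", "age", "sex", "site",
            "msi_status", "total_pc_count")
  if (!all(need %in% names(s)))
    stop_mirlink(paste("samples is missing column(s):",
                       paste(setdiff(need, names(s)), collapse = ", ")),
                 "format_error")
  s$tissue <- normalize_code(s$tissue, TISSUE_CODES, "tissue")
  s$sex <- normalize_code(s$sex, SEX_CODES, "sex")
  s$msi_status <- normalize_code(s$msi_status, MSI_CODES, "msi_status")
  if (anyDuplicated(s$sample_id))
    stop_mirlink("Duplicate sample ids.", "format_error")
  pair_tab <- s |> count(.data$subject, .data$tissue)
  bad <- pair_tab |>
    tidyr::pivot_wider(names_from = "tissue", values_from = "n",
                       values_fill = 0L) |>
    filter(.data$tumor != 1L | .data$normal != 1L)
  if (nrow(bad) > 0)
    stop_mirlink(paste("Subjects without exactly one tumor and one normal sample:",
                       paste(bad$subject, collapse = ", ")),
                 "pairing_error")
  if (any(s$total_pc_count <= 0))
    stop_mirlink("total_pc_count must be positive for every sample.",
                 "format_error")
  for (part in c("mrna", "mirna")) {
    tbl <- study[[part]]
    id <- if (part == "mrna") "gene" else "mirna"
    if (names(tbl)[1] != id)
      stop_mirlink(sprintf("First column of `%s` must be `%s`.", part, id),
                   "format_error")
    if (anyDuplicated(tbl[[id]]))
      stop_mirlink(sprintf("Duplicate %s identifiers.", id), "format_error")
    if (!setequal(names(tbl)[-1], s$sample_id))
      stop_mirlink(sprintf("`%s` sample columns do not match sample metadata.",
                           part), "format_error")
    vals <- as.matrix(tbl[-1])
    if (anyNA(vals) || any(vals < 0))
      stop_mirlink(sprintf("`%s` contains negative or missing values.", part),
                   "format_error")
  }
  study$samples <- s
  # fixed column order: tumor/normal pairs follow metadata order
  study$mrna <- study$mrna[c("gene", s$sample_id)]
  study$mirna <- study$mirna[c("mirna", s$sample_id)]
  study
}

#' @export
print.paired_study <- function(x, ...) {
  n_sub <- length(unique(x$samples$subject))
  cat(sprintf(paste0("<paired_study> %d subjects (%d samples), %d genes, ",
                     "%d miRNAs\n"),
              n_sub, nrow(x$samples), nrow(x$mrna), nrow(x$mirna)))
  msi <- table(x$samples$msi_status[x$samples$tissue == "tumor"])
  cat("  tumor phenotype:", paste(names(msi), msi, sep = "=", collapse = ", "),
      "\n")
  if (!is.null(x$utr)) cat(sprintf("  3'UTR records: %d\n", nrow(x$utr)))
  invisible(x)
}

#' Write / read a study bundle on disk
#'
#' The bundle is a directory of plain-text files: `mrna_counts.tsv`
#' (gene x sample), `mirna_signals.tsv` (miRNA x sample), `metadata.tsv`
#' (one row per sample, incl. covariates and protein-coding totals),
#' `utr.fasta` (DNA 3'UTRs, headers `gene|record`), `mirna.fasta`
#' (mature miRNA RNA sequences), and, when a ground truth is supplied,
#' `ground_truth.json`.
#'
#' @param study A [paired_study()].
#' @param path Directory to write into (created if missing).
#' @param truth Optional `ground_truth` object from [generate_study()].
#' @return `write_study()` returns `path` invisibly; `read_study()` returns
#'   a validated [paired_study()].
#' @export
write_study <- function(study, path, truth = NULL) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(study$mrna, file.path(path, "mrna_counts.tsv"))
  readr::write_tsv(study$mirna, file.path(path, "mirna_signals.tsv"))
  readr::write_tsv(study$samples, file.path(path, "metadata.tsv"))
  if (!is.null(study$utr)) {
    seqs <- Biostrings::DNAStringSet(study$utr$sequence)
    names(seqs) <- paste(study$utr$gene, study$utr$record, sep = "|")
    Biostrings::writeXStringSet(seqs, file.path(path, "utr.fasta"))
  }
  if (!is.null(study$mirna_seq)) {
    seqs <- Biostrings::RNAStringSet(study$mirna_seq$sequence)
    names(seqs) <- study$mirna_seq$mirna
    Biostrings::writeXStringSet(seqs, file.path(path, "mirna.fasta"))
  }
  if (!is.null(truth)) {
    jsonlite::write_json(unclass(truth), file.path(path, "ground_truth.json"),
                         digits = NA)
  }
  invisible(path)
}

#' @rdname write_study
#' @export
read_study <- function(path) {
  need <- c("mrna_counts.tsv", "mirna_signals.tsv", "metadata.tsv")
  missing <- need[!file.exists(file.path(path, need))]
  if (length(missing))
    stop_mirlink(paste("Bundle is missing:", paste(missing, collapse = ", ")),
                 "format_error")
  samples <- readr::read_tsv(file.path(path, "metadata.tsv"),
                             show_col_types = FALSE)
  mrna <- readr::read_tsv(file.path(path, "mrna_counts.tsv"),
                          show_col_types = FALSE)
  mirna <- readr::read_tsv(file.path(path, "mirna_signals.tsv"),
                           show_col_types = FALSE)
  utr <- NULL
  if (file.exists(file.path(path, "utr.fasta"))) {
    seqs <- Biostrings::readDNAStringSet(file.path(path, "utr.fasta"))
    ids <- strsplit(names(seqs), "|", fixed = TRUE)
    utr <- tibble(gene = map_chr(ids, 1),
                  record = map_chr(ids, function(x) x[min(2, length(x))]),
                  sequence = unname(toupper(as.character(seqs))))
  }
  mirna_seq <- NULL
  if (file.exists(file.path(path, "mirna.fasta"))) {
    # mature sequences in public sources mix RNA/DNA alphabets and case
    seqs <- Biostrings::readBStringSet(file.path(path, "mirna.fasta"))
    mirna_seq <- tibble(mirna = names(seqs),
                        sequence = unname(chartr("Tt", "Uu",
                                                 toupper(as.character(seqs)))))
  }
  paired_study(samples, mrna, mirna, utr = utr, mirna_seq = mirna_seq)
}

#' Load the packaged colorectal-cancer MAPK study tables
#'
#' Machine-readable copies of the printed summary tables of a published
#' paired tumor-normal colorectal-cancer study of the KEGG MAPK-signaling
#' pathway, used for replay checks of the classification and summary rules:
#' the cohort description, the dysregulated-gene table (83 genes), the
#' miRNA:mRNA association table (68 rows across 13 genes, with seed-match
#' flags), the per-miRNA seed-match summary, and the genes reported as
#' dysregulated only in the MSI or MSS subgroup.
#'
#' Printed values are kept both as printed strings (p-values such as
#' `"<.0001"`) and as parsed numerics (`"<.0001"` is parsed as its bound,
#' 0.0001). File integrity is checked against a packaged MD5 manifest.
#'
#' @return A list of tibbles: `cohort`, `de_genes`, `mirna_assoc`,
#'   `seed_summary`, `subgroup_genes`.
#' @export
load_mapk_tables <- function() {
  dir <- system.file("extdata", package = "mirlink")
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE)
  for (k in seq_len(nrow(manifest))) {
    f <- file.path(dir, manifest$file[k])
    if (!file.exists(f))
      stop_mirlink(paste("Missing packaged fixture:", manifest$file[k]),
                   "integrity_error")
    if (unname(tools::md5sum(f)) != manifest$md5[k])
      stop_mirlink(paste("Checksum mismatch for packaged fixture:",
                         manifest$file[k]), "integrity_error")
  }
  parse_p <- function(x) as.numeric(sub("^<", "", x))
  cohort <- readr::read_tsv(file.path(dir, "crc_mapk_cohort.tsv"),
                            col_types = "cciddd")
  de <- readr::read_tsv(file.path(dir, "crc_mapk_de_genes.tsv"),
                        col_types = "ccdddcc") |>
    mutate(p_value = parse_p(.data$p_value_printed),
           p_adjusted = parse_p(.data$p_adjusted_printed))
  assoc <- readr::read_tsv(file.path(dir, "crc_mapk_mirna_assoc.tsv"),
                           col_types = "cdddcdddcccl") |>
    mutate(beta = as.numeric(.data$beta_printed),
           p_raw = parse_p(.data$p_raw_printed),
           p_fdr = parse_p(.data$p_fdr_printed))
  seed_summary <- readr::read_tsv(file.path(dir, "crc_mapk_seed_summary.tsv"),
                                  col_types = "cicc")
  subgroup <- readr::read_tsv(file.path(dir, "crc_mapk_subgroup_genes.tsv"),
                              show_col_types = FALSE)
  nrows <- c(de = 83L, assoc = 68L)
  if (nrow(de) != nrows["de"] || nrow(assoc) != nrows["assoc"])
    stop_mirlink("Packaged table row counts changed.", "integrity_error")
  list(cohort = cohort, de_genes = de, mirna_assoc = assoc,
       seed_summary = seed_summary, subgroup_genes = subgroup)
}
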