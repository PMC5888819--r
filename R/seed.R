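#' Extract 6/7/8-mer seed regions from a mature miRNA sequence
#'
#' Seeds are contiguous windows starting at position 2 (1-based) of the
#' mature sequence: positions 2-7 (6-mer), 2-8 (7-mer) and 2-9 (8-mer).
#' Shorter matures yield only the windows they can contain (a length-8
#' mature gives the 6- and 7-mers only); a full set needs length >= 9.
#'
#' @param mature_rna Mature miRNA sequence (RNA alphabet `ACGU`; case is
#'   normalized).
#' @param mirna Optional identifier carried into the output.
#' @return Tibble `mirna`, `seed_length`, `seed`, `mirna_start` (always 2).
#' @examples
#' extract_seeds("ACGUACGUACGU")
#' @export
extract_seeds <- function(mature_rna, mirna = NA_character_) {
  seq <- toupper(mature_rna)
  if (grepl("[^ACGU]", seq))
    stop_mirlink("Mature sequence contains non-RNA characters.",
                 "alphabet_error")
  lens <- c(6L, 7L, 8L)
  lens <- lens[nchar(seq) >= lens + 1L]
  if (length(lens) == 0)
    stop_mirlink("Mature sequence too short for any seed (need >= 7 nt).",
                 "alphabet_error")
  tibble(mirna = mirna, seed_length = lens,
         seed = substr(rep(seq, length(lens)), 2L, 1L + lens),
         mirna_start = 2L)
}

#' Seed table for a set of mature miRNAs
#'
#' @param mirna_seq Tibble `mirna`, `sequence` (e.g. the `mirna_seq`
#'   component of a [paired_study()]).
#' @return Row-bound [extract_seeds()] output for every miRNA.
#' @export
seed_table <- function(mirna_seq) {
  list_rbind(map2(mirna_seq$sequence, mirna_seq$mirna, extract_seeds))
}

#' Scan a 3'UTR for seed-complement sites
#'
#' Reports every occurrence of the DNA reverse complement of each seed in
#' the UTR, including overlapping occurrences. `N` bases never match.
#' Coordinates are 0-based, half-open.
#'
#' @param utr_dna UTR sequence (DNA alphabet `ACGTN`).
#' @param seeds Seed tibble from [extract_seeds()] / [seed_table()]
#'   (columns `mirna`, `seed_length`, `seed`).
#' @return Tibble `mirna`, `seed_length`, `start`, `end`
#'   (`end - start == seed_length`).
#' @export
scan_utr <- function(utr_dna, seeds) {
  if (nrow(seeds) == 0)
    stop_mirlink("Empty seed set.", "spec_error")
  utr <- toupper(utr_dna)
  if (grepl("[^ACGTN]", utr))
    stop_mirlink("UTR contains characters outside {A,C,G,T,N}.",
                 "alphabet_error")
  if (nchar(utr) == 0) {
    return(tibble(mirna = character(), seed_length = integer(),
                  start = integer(), end = integer()))
  }
  subject <- Biostrings::DNAString(utr)
  rows <- pmap(seeds[c("mirna", "seed_length", "seed")],
               function(mirna, seed_length, seed) {
    if (nchar(utr) < seed_length) {
      return(tibble(mirna = character(), seed_length = integer(),
                    start = integer(), end = integer()))
    }
    hits <- Biostrings::matchPattern(seed_rc_dna(seed), subject, fixed = TRUE)
    st <- Biostrings::start(hits) - 1L
    tibble(mirna = rep(mirna, length(st)),
           seed_length = rep(as.integer(seed_length), length(st)),
           start = st, end = st + as.integer(seed_length))
  })
  list_rbind(rows)
}

#' Scan many UTR records against many miRNAs
#'
#' A gene may have several UTR records (transcript isoforms); matches are
#' reported per record, and a gene-level match exists when any record
#' matches.
#'
#' @param utr Tibble `gene`, `record`, `sequence` (DNA).
#' @param seeds Seed tibble from [seed_table()].
#' @param pairs Optional tibble `gene`, `mirna` restricting the scan to
#'   those pairs (e.g. significant associations).
#' @return Tibble `gene`, `record`, `mirna`, `seed_length`, `start`, `end`.
#' @export
scan_seed_matches <- function(utr, seeds, pairs = NULL) {
  out <- pmap(utr[c("gene", "record", "sequence")],
              function(gene, record, sequence) {
    sd <- seeds
    if (!is.null(pairs))
      sd <- semi_join(sd, pairs[pairs$gene == gene, , drop = FALSE],
                      by = "mirna")
    if (nrow(sd) == 0) {
      return(tibble(gene = character(), record = character(),
                    mirna = character(), seed_length = integer(),
                    start = integer(), end = integer()))
    }
    scan_utr(sequence, sd) |>
      mutate(gene = gene, record = record, .before = 1)
  })
  list_rbind(out)
}

#' Classify significant associations as direct or indirect
#'
#' A miRNA:mRNA association is called `direct` when the miRNA has at least
#' one seed-complement site in the gene's 3'UTR *and* the association
#' slope is negative (miRNA up, mRNA down - the signature of repression by
#' binding); otherwise it is `indirect` (attributed to feedback /
#' feed-forward regulation).
#'
#' @param assoc Tibble with columns `gene`, `mirna`, `beta` (typically the
#'   significant rows of an [association_screen()] result).
#' @param matches Seed-match tibble from [scan_seed_matches()].
#' @return `assoc` with `has_seed_match` (logical) and `call`
#'   (`"direct"`/`"indirect"`) added; class `mirlink_calls`.
#' @export
classify_interaction <- function(assoc, matches) {
  matched <- matches |> distinct(.data$gene, .data$mirna) |>
    mutate(has_seed_match = TRUE)
  out <- assoc |>
    left_join(matched, by = c("gene", "mirna")) |>
    mutate(has_seed_match = !is.na(.data$has_seed_match),
           call = if_else(.data$has_seed_match & .data$beta < 0,
                          "direct", "indirect"))
  class(out) <- c("mirlink_calls", class(out))
  out
}

#' Summarize interaction calls per miRNA
#'
#' Partitions each miRNA's associated genes by seed-match status, the
#' layout of a per-miRNA seed-match summary table.
#'
#' @param calls Output of [classify_interaction()].
#' @return Tibble `mirna`, `n_assoc`, `n_with_match`, `n_without_match`,
#'   `genes_with_match`, `genes_without_match` (comma-separated, sorted).
#' @export
summarize_by_mirna <- function(calls) {
  if (nrow(calls) == 0) {
    return(tibble(mirna = character(), n_assoc = integer(),
                  n_with_match = integer(), n_without_match = integer(),
                  genes_with_match = character(),
                  genes_without_match = character()))
  }
  calls |>
    group_by(.data$mirna) |>
    summarize(
      n_assoc = dplyr::n(),
      n_with_match = sum(.data$has_seed_match),
      n_without_match = sum(!.data$has_seed_match),
      genes_with_match = paste(sort(.data$gene[.data$has_seed_match]),
                               collapse = ","),
      genes_without_match = paste(sort(.data$gene[!.data$has_seed_match]),
                                  collapse = ","),
      .groups = "drop"
    ) |>
    arrange(.data$mirna)
}
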