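#' Configuration for the synthetic paired-study generator
#'
#' Describes a paired carcinoma / normal-mucosa expression study to be
#' simulated: negative-binomial mRNA counts with a shared subject intercept
#' and per-sample protein-coding totals, log-normal miRNA array signals with
#' per-array scale artifacts, planted tumor-vs-normal fold changes, planted
#' linear miRNA-to-mRNA effects on the subject-level differential expression,
#' and 3'UTR sequences with planted seed-complement sites.
#'
#' The demographic defaults (217 subjects, mean age 64.8 years, SD 10.1,
#' 54.4% male, 77.9% colon site, 13.4% microsatellite-unstable tumors) mirror
#' the colorectal-cancer cohort whose summary tables ship with the package;
#' the variance components are free parameters of the simulator.
#'
#' @param n_subjects Number of subjects; each contributes one tumor and one
#'   normal sample per assay.
#' @param n_genes,n_mirnas Number of mRNA genes / miRNAs to simulate.
#' @param frac_msi Proportion of subjects with microsatellite-unstable (MSI)
#'   tumors; the rest are MSS.
#' @param nb_dispersion Negative-binomial dispersion of the mRNA counts
#'   (`variance = mu + dispersion * mu^2`).
#' @param baseline_log_mean_range Interval (length-2 numeric) for the
#'   per-gene baseline log relative abundance; the default spans roughly
#'   0.2-600 reads per million protein-coding reads.
#' @param planted_gene_log_fc Named numeric vector of tumor-vs-normal log
#'   fold changes (natural log) keyed by gene id; genes not named get 0.
#' @param planted_assoc Tibble with columns `gene`, `mirna`, `beta`: linear
#'   effect of the per-subject (tumor - normal) miRNA signal on the gene's
#'   (tumor - normal) expression in RPMPCG units.
#' @param planted_mirna_log_fc Named numeric vector of tumor-vs-normal log
#'   fold changes for miRNAs.
#' @param subgroup_log_fc Tibble with columns `gene`, `subgroup`
#'   (`"MSI"`/`"MSS"`), `log_fc`: additional tumor effect applied only to
#'   subjects of that tumor phenotype.
#' @param planted_seed_sites Tibble with columns `gene`, `mirna`, `n_sites`:
#'   exact number of seed-complement sites to plant in the gene's 3'UTR.
#'   `NULL` plants one site for every `planted_assoc` pair with negative
#'   `beta`, so planted repressive associations are also direct by sequence.
#' @param age_mean,age_sd Mean and SD of subject age in years.
#' @param frac_male,frac_colon Proportions of male subjects and colon (vs
#'   rectal) tumor sites.
#' @param subject_sd SD of the per-gene log-normal subject intercept shared
#'   by a subject's tumor and normal sample.
#' @param total_count_meanlog,total_count_sdlog Log-normal parameters of the
#'   per-sample protein-coding total used as the model offset.
#' @param mirna_baseline_log_range Interval for per-miRNA baseline log
#'   signal.
#' @param mirna_subject_sd,mirna_noise_sd SDs (log scale) of the per-miRNA
#'   subject intercept and the per-observation signal noise.
#' @param array_scale_sd SD (log scale) of the per-array multiplicative
#'   scale artifact that 75th-percentile normalization is meant to remove.
#' @param assoc_noise_sd SD (RPMPCG units) of the additive Gaussian noise on
#'   the planted miRNA-to-mRNA differential-expression effect.
#' @param age_effect,sex_effect Covariate effects (RPMPCG units per year of
#'   centred age, and for male sex) added to the tumor-minus-normal
#'   expression of genes carrying planted associations, so that the
#'   age/sex-adjusted association fit has something real to adjust for.
#' @param gene_log_baseline,mirna_log_baseline Optional named numeric
#'   overrides of the per-feature baseline log mean (same scale as the
#'   corresponding range argument), pinning the expression level - and
#'   hence the signal-to-noise - of features that carry planted effects.
#' @param utr_length Length (bases) of each simulated 3'UTR.
#' @param mature_length Length (bases) of each simulated mature miRNA.
#' @param seed Integer seed; identical `(config, seed)` gives bit-identical
#'   output.
#'
#' @return An object of class `synthetic_config` (a validated list).
#' @seealso [generate_study()]
#' @export
synthetic_config <- function(n_subjects = 217,
                             n_genes = 241,
                             n_mirnas = 100,
                             frac_msi = 0.134,
                             nb_dispersion = 0.1,
                             baseline_log_mean_range = log(c(0.2, 600) / 1e6),
                             planted_gene_log_fc = NULL,
                             planted_assoc = NULL,
                             planted_mirna_log_fc = NULL,
                             subgroup_log_fc = NULL,
                             planted_seed_sites = NULL,
                             age_mean = 64.8,
                             age_sd = 10.1,
                             frac_male = 0.544,
                             frac_colon = 0.779,
                             subject_sd = 0.5,
                             total_count_meanlog = log(2e6),
                             total_count_sdlog = 0.2,
                             mirna_baseline_log_range = log(c(1, 300)),
                             mirna_subject_sd = 0.4,
                             mirna_noise_sd = 0.15,
                             array_scale_sd = 0.2,
                             assoc_noise_sd = 1,
                             age_effect = 0.05,
                             sex_effect = 1,
                             gene_log_baseline = NULL,
                             mirna_log_baseline = NULL,
                             utr_length = 1000,
                             mature_length = 22,
                             seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  bad <- function(field, why) {
    stop_mirlink(sprintf("Invalid synthetic_config field `%s`: %s", field, why),
                 "config_error")
  }
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 2) bad("n_subjects", "must be >= 2")
  if (cfg$n_genes < 1) bad("n_genes", "must be >= 1")
  if (cfg$n_mirnas < 1) bad("n_mirnas", "must be >= 1")
  if (!is.numeric(cfg$frac_msi) || cfg$frac_msi < 0 || cfg$frac_msi > 1)
    bad("frac_msi", "must lie in [0, 1]")
  if (!is.numeric(cfg$nb_dispersion) || cfg$nb_dispersion <= 0)
    bad("nb_dispersion", "must be > 0")
  if (cfg$utr_length < 8) bad("utr_length", "must be >= 8 bases")
  if (length(cfg$baseline_log_mean_range) != 2 ||
      diff(cfg$baseline_log_mean_range) < 0)
    bad("baseline_log_mean_range", "must be an increasing length-2 interval")
  if (cfg$mature_length < 9) bad("mature_length", "must be >= 9 for the full seed set")
  gene_ids <- synthetic_gene_ids(cfg$n_genes)
  mirna_ids <- synthetic_mirna_ids(cfg$n_mirnas)
  if (!is.null(cfg$planted_gene_log_fc)) {
    if (is.null(names(cfg$planted_gene_log_fc)) ||
        !all(names(cfg$planted_gene_log_fc) %in% gene_ids))
      bad("planted_gene_log_fc", "names must be generated gene ids")
  }
  if (!is.null(cfg$planted_mirna_log_fc)) {
    if (is.null(names(cfg$planted_mirna_log_fc)) ||
        !all(names(cfg$planted_mirna_log_fc) %in% mirna_ids))
      bad("planted_mirna_log_fc", "names must be generated miRNA ids")
  }
  if (!is.null(cfg$planted_assoc)) {
    pa <- cfg$planted_assoc
    if (!all(c("gene", "mirna", "beta") %in% names(pa)))
      bad("planted_assoc", "needs columns gene, mirna, beta")
    if (!all(pa$gene %in% gene_ids)) bad("planted_assoc", "unknown gene id")
    if (!all(pa$mirna %in% mirna_ids)) bad("planted_assoc", "unknown miRNA id")
  }
  if (!is.null(cfg$subgroup_log_fc)) {
    sg <- cfg$subgroup_log_fc
    if (!all(c("gene", "subgroup", "log_fc") %in% names(sg)))
      bad("subgroup_log_fc", "needs columns gene, subgroup, log_fc")
    if (!all(sg$subgroup %in% c("MSI", "MSS")))
      bad("subgroup_log_fc", "subgroup must be MSI or MSS")
    if (!all(sg$gene %in% gene_ids)) bad("subgroup_log_fc", "unknown gene id")
  }
  if (!is.null(cfg$gene_log_baseline) &&
      (is.null(names(cfg$gene_log_baseline)) ||
       !all(names(cfg$gene_log_baseline) %in% gene_ids)))
    bad("gene_log_baseline", "names must be generated gene ids")
  if (!is.null(cfg$mirna_log_baseline) &&
      (is.null(names(cfg$mirna_log_baseline)) ||
       !all(names(cfg$mirna_log_baseline) %in% mirna_ids)))
    bad("mirna_log_baseline", "names must be generated miRNA ids")
  if (!is.null(cfg$planted_seed_sites)) {
    ps <- cfg$planted_seed_sites
    if (!all(c("gene", "mirna", "n_sites") %in% names(ps)))
      bad("planted_seed_sites", "needs columns gene, mirna, n_sites")
    if (!all(ps$gene %in% gene_ids)) bad("planted_seed_sites", "unknown gene id")
    if (!all(ps$mirna %in% mirna_ids)) bad("planted_seed_sites", "unknown miRNA id")
    if (sum(ps$n_sites) * 8 > cfg$utr_length)
      bad("planted_seed_sites", "sites do not fit in utr_length")
  }
  cfg
}

synthetic_gene_ids <- function(n) sprintf("gene%03d", seq_len(n))
synthetic_mirna_ids <- function(n) sprintf("mir-%03d", seq_len(n))

#' Generate a synthetic paired tumor-normal study with ground truth
#'
#' Simulates the full input bundle the analysis pipeline consumes - paired
#' mRNA counts, miRNA array signals, sample metadata, mature miRNA and 3'UTR
#' sequences - together with the planted effects, so that fold-change,
#' association and seed-site recovery can be tested against a known truth.
#'
#' Generation model, per subject \eqn{i}:
#' \itemize{
#'   \item mRNA gene \eqn{g}: normal-tissue expectation (RPMPCG scale)
#'     \eqn{q^N_{gi} = 10^6 \exp(b_g + u_{gi})} with subject intercept
#'     \eqn{u_{gi} \sim N(0, \sigma_u^2)} shared by both tissues; tumor
#'     expectation \eqn{q^T_{gi} = q^N_{gi} e^{\phi_{gi}} + \sum_m
#'     \beta_{gm} d_{mi} + \gamma_a (a_i - \bar a) + \gamma_s I(male_i) +
#'     \epsilon_{gi}} where \eqn{\phi_{gi}} is the planted (sub)group log
#'     fold change and \eqn{d_{mi}} the latent miRNA tumor-minus-normal
#'     signal. Counts are negative binomial with mean
#'     \eqn{q/10^6 \times L_s} for sample total \eqn{L_s}.
#'   \item miRNA \eqn{m}: latent log-normal signals with subject intercept
#'     and tumor log fold change; the observed value is the latent signal
#'     times a per-array scale artifact, which 75th-percentile
#'     normalization is designed to remove.
#'   \item 3'UTRs: uniform random DNA with the requested number of
#'     seed-complement sites planted exactly (accidental extra occurrences
#'     of the planted miRNA's seeds are rejection-sampled away).
#' }
#'
#' @param config A [synthetic_config()].
#' @return A list with components `study` (a [paired_study()]) and `truth`
#'   (class `ground_truth`: tibbles `true_fc`, `true_beta`,
#'   `true_seed_sites`, `subgroup_effects`, `mirna_fc`).
#' @examples
#' cfg <- synthetic_config(n_subjects = 10, n_genes = 5, n_mirnas = 4,
#'                         seed = 7)
#' out <- generate_study(cfg)
#' out$study
#' @export
generate_study <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_mirlink("`config` must be created by synthetic_config().", "config_error")
  validate_synthetic_config(config)
  set.seed(config$seed)
  n <- config$n_subjects
  genes <- synthetic_gene_ids(config$n_genes)
  mirnas <- synthetic_mirna_ids(config$n_mirnas)
  subjects <- sprintf("S%03d", seq_len(n))

  meta <- tibble(
    subject = subjects,
    age = rnorm(n, config$age_mean, config$age_sd),
    sex = ifelse(runif(n) < config$frac_male, "M", "F"),
    site = ifelse(runif(n) < config$frac_colon, "colon", "rectal"),
    msi_status = ifelse(runif(n) < config$frac_msi, "MSI", "MSS")
  )
  samples <- tibble(
    sample_id = c(paste0(subjects, "_T"), paste0(subjects, "_N")),
    subject = rep(subjects, 2),
    tissue = rep(c("tumor", "normal"), each = n)
  ) |>
    left_join(meta, by = "subject") |>
    mutate(total_pc_count = round(rlnorm(2 * n, config$total_count_meanlog,
                                         config$total_count_sdlog)))

  # ---- miRNA signals -------------------------------------------------------
  mirna_lfc <- setNames(numeric(config$n_mirnas), mirnas)
  if (!is.null(config$planted_mirna_log_fc))
    mirna_lfc[names(config$planted_mirna_log_fc)] <- config$planted_mirna_log_fc
  c_m <- runif(config$n_mirnas, config$mirna_baseline_log_range[1],
               config$mirna_baseline_log_range[2])
  names(c_m) <- mirnas
  if (!is.null(config$mirna_log_baseline))
    c_m[names(config$mirna_log_baseline)] <- config$mirna_log_baseline
  c_m <- unname(c_m)
  v <- matrix(rnorm(config$n_mirnas * n, 0, config$mirna_subject_sd),
              config$n_mirnas, n)
  eps_t <- matrix(rnorm(config$n_mirnas * n, 0, config$mirna_noise_sd),
                  config$n_mirnas, n)
  eps_n <- matrix(rnorm(config$n_mirnas * n, 0, config$mirna_noise_sd),
                  config$n_mirnas, n)
  latent_tumor <- exp(c_m + v + mirna_lfc + eps_t)
  latent_normal <- exp(c_m + v + eps_n)
  array_scale <- exp(rnorm(2 * n, 0, config$array_scale_sd))
  observed <- cbind(latent_tumor, latent_normal) *
    rep(array_scale, each = config$n_mirnas)
  dimnames(observed) <- list(mirnas, samples$sample_id)
  mirna_diff <- latent_tumor - latent_normal   # miRNA x subject, latent scale
  dimnames(mirna_diff) <- list(mirnas, subjects)

  # ---- mRNA counts ---------------------------------------------------------
  gene_lfc <- setNames(numeric(config$n_genes), genes)
  if (!is.null(config$planted_gene_log_fc))
    gene_lfc[names(config$planted_gene_log_fc)] <- config$planted_gene_log_fc
  b_g <- runif(config$n_genes, config$baseline_log_mean_range[1],
               config$baseline_log_mean_range[2])
  names(b_g) <- genes
  if (!is.null(config$gene_log_baseline))
    b_g[names(config$gene_log_baseline)] <- config$gene_log_baseline
  b_g <- unname(b_g)
  u <- matrix(rnorm(config$n_genes * n, 0, config$subject_sd),
              config$n_genes, n)
  lfc_mat <- matrix(gene_lfc, config$n_genes, n)
  if (!is.null(config$subgroup_log_fc)) {
    for (k in seq_len(nrow(config$subgroup_log_fc))) {
      row <- config$subgroup_log_fc[k, ]
      in_grp <- meta$msi_status == row$subgroup
      gi <- match(row$gene, genes)
      lfc_mat[gi, in_grp] <- lfc_mat[gi, in_grp] + row$log_fc
    }
  }
  q_normal <- 1e6 * exp(b_g + u)               # gene x subject, RPMPCG scale
  q_tumor <- q_normal * exp(lfc_mat)
  if (!is.null(config$planted_assoc) && nrow(config$planted_assoc) > 0) {
    age_c <- meta$age - mean(meta$age)
    male <- as.numeric(meta$sex == "M")
    assoc_genes <- unique(config$planted_assoc$gene)
    for (g in assoc_genes) {
      gi <- match(g, genes)
      rows <- config$planted_assoc[config$planted_assoc$gene == g, ]
      # subject-centred miRNA differences: the slope is beta while the
      # gene's planted fold change stays identifiable (no mean shift)
      d_c <- mirna_diff[rows$mirna, , drop = FALSE]
      d_c <- d_c - rowMeans(d_c)
      effect <- as.numeric(rows$beta %*% d_c)
      q_tumor[gi, ] <- q_tumor[gi, ] + effect +
        config$age_effect * age_c + config$sex_effect * male +
        rnorm(n, 0, config$assoc_noise_sd)
    }
    q_tumor <- pmax(q_tumor, 1e-3)
  }
  L <- setNames(samples$total_pc_count, samples$sample_id)
  mu_t <- q_tumor / 1e6 * rep(L[paste0(subjects, "_T")], each = config$n_genes)
  mu_n <- q_normal / 1e6 * rep(L[paste0(subjects, "_N")], each = config$n_genes)
  size <- 1 / config$nb_dispersion
  counts <- cbind(
    matrix(rnbinom(length(mu_t), mu = mu_t, size = size), config$n_genes, n),
    matrix(rnbinom(length(mu_n), mu = mu_n, size = size), config$n_genes, n)
  )
  dimnames(counts) <- list(genes, samples$sample_id)

  # ---- sequences -----------------------------------------------------------
  mirna_seq <- tibble(
    mirna = mirnas,
    sequence = replicate(config$n_mirnas,
                         paste(sample(c("A", "C", "G", "U"),
                                      config$mature_length, replace = TRUE),
                               collapse = ""))
  )
  planted_sites <- config$planted_seed_sites
  if (is.null(planted_sites)) {
    planted_sites <- if (is.null(config$planted_assoc)) {
      tibble(gene = character(), mirna = character(), n_sites = integer())
    } else {
      config$planted_assoc |>
        filter(.data$beta < 0) |>
        transmute(.data$gene, .data$mirna, n_sites = 1L)
    }
  }
  utr_rows <- vector("list", config$n_genes)
  site_rows <- list()
  for (gi in seq_len(config$n_genes)) {
    g <- genes[gi]
    plant <- planted_sites[planted_sites$gene == g & planted_sites$n_sites > 0, ]
    if (nrow(plant) == 0) {
      seq <- paste(sample(c("A", "C", "G", "T"), config$utr_length,
                          replace = TRUE), collapse = "")
    } else {
      sites8 <- map_chr(plant$mirna, function(m) {
        mat <- mirna_seq$sequence[mirna_seq$mirna == m]
        seed_rc_dna(substr(mat, 2, 9))
      })
      planted <- plant_multi_sites(config$utr_length, sites8, plant$n_sites,
                                   guard_seeds = unlist(map(plant$mirna, function(m) {
                                     mat <- mirna_seq$sequence[mirna_seq$mirna == m]
                                     c(seed_rc_dna(substr(mat, 2, 7)),
                                       seed_rc_dna(substr(mat, 2, 8)),
                                       seed_rc_dna(substr(mat, 2, 9)))
                                   })))
      seq <- planted$sequence
      for (k in seq_len(nrow(plant))) {
        st <- planted$starts[[k]]
        site_rows[[length(site_rows) + 1]] <- tibble(
          gene = g, mirna = plant$mirna[k],
          start = st, end = st + 8L
        )
      }
    }
    utr_rows[[gi]] <- tibble(gene = g, record = g, sequence = seq)
  }
  utr <- list_rbind(utr_rows)
  true_sites <- if (length(site_rows)) list_rbind(site_rows) else
    tibble(gene = character(), mirna = character(),
           start = integer(), end = integer())

  study <- paired_study(
    samples = samples,
    mrna = matrix_to_wide(counts, "gene"),
    mirna = matrix_to_wide(observed, "mirna"),
    utr = utr,
    mirna_seq = mirna_seq
  )
  truth <- structure(list(
    true_fc = tibble(gene = genes, fc = exp(unname(gene_lfc))),
    true_beta = config$planted_assoc %||%
      tibble(gene = character(), mirna = character(), beta = double()),
    true_seed_sites = true_sites,
    subgroup_effects = config$subgroup_log_fc %||%
      tibble(gene = character(), subgroup = character(), log_fc = double()),
    mirna_fc = tibble(mirna = mirnas, fc = exp(unname(mirna_lfc)))
  ), class = "ground_truth")
  list(study = study, truth = truth)
}

# DNA reverse complement of an RNA (or DNA) seed string
seed_rc_dna <- function(seed) {
  dna <- chartr("Uu", "Tt", toupper(seed))
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

count_occurrences <- function(seq, pattern) {
  length(Biostrings::matchPattern(pattern, Biostrings::DNAString(seq),
                                  fixed = TRUE))
}

# place non-overlapping copies of each site sequence in a random background,
# then verify that every guard pattern occurs exactly its expected number of
# times; redraw the whole sequence otherwise (rejection sampling). The
# expected count of a guard is its occurrence count inside the planted site
# strings (a periodic seed can occur more than once per site), so only
# background or boundary-spanning extras trigger a redraw.
plant_multi_sites <- function(utr_length, sites, n_sites, guard_seeds,
                              max_tries = 1000) {
  guard_counts <- map_int(guard_seeds, function(g) {
    sum(map_int(seq_along(sites), function(k) {
      n_sites[k] * count_occurrences(sites[k], g)
    }))
  })
  total <- sum(nchar(sites) * n_sites)
  if (total > utr_length)
    stop_mirlink("Requested seed sites do not fit in the UTR.", "capacity_error")
  lens <- rep(nchar(sites), n_sites)
  site_seq <- rep(sites, n_sites)
  site_of <- rep(seq_along(sites), n_sites)
  for (try in seq_len(max_tries)) {
    starts <- place_nonoverlapping(utr_length, lens)
    if (is.null(starts)) next
    chars <- sample(c("A", "C", "G", "T"), utr_length, replace = TRUE)
    for (k in seq_along(starts)) {
      idx <- starts[k] + seq_len(lens[k])   # starts are 0-based
      chars[idx] <- strsplit(site_seq[k], "")[[1]]
    }
    seq <- paste(chars, collapse = "")
    ok <- all(map_int(seq_along(guard_seeds), function(j) {
      count_occurrences(seq, guard_seeds[j])
    }) == guard_counts)
    if (ok) {
      starts_by_site <- split(starts, site_of)
      return(list(sequence = seq,
                  starts = lapply(seq_along(sites), function(j) {
                    sort(starts_by_site[[as.character(j)]] %||% integer())
                  })))
    }
  }
  stop_mirlink("Could not plant the requested seed sites without accidental matches.",
               "capacity_error")
}

# sample 0-based, non-overlapping start positions for segments of given lengths
place_nonoverlapping <- function(utr_length, lens, max_tries = 200) {
  if (length(lens) == 0) return(integer())
  for (try in seq_len(max_tries)) {
    starts <- map_int(lens, function(l) sample.int(utr_length - l + 1, 1) - 1L)
    o <- order(starts)
    s <- starts[o]; l <- lens[o]
    if (all(diff(s) >= l[-length(l)])) return(starts)
  }
  NULL
}

#' Plant exact seed-complement sites into a random UTR background
#'
#' Builds a uniform-random DNA sequence of length `utr_length` containing
#' exactly `n_sites` non-overlapping occurrences of the DNA reverse
#' complement of `seed_rna`, and no accidental extra occurrences (the
#' background is rejection-sampled until the count is exact). Uses the
#' current RNG stream; wrap in [set.seed()] for reproducibility.
#'
#' @param utr_length UTR length in bases (>= 8).
#' @param seed_rna RNA seed sequence of length 6, 7 or 8.
#' @param n_sites Number of sites to plant (may be 0).
#' @return A list with `sequence` (character scalar) and `starts` (0-based
#'   integer start offsets of the planted sites).
#' @examples
#' set.seed(1)
#' p <- plant_seed_sites(200, "ACGUAC", 2)
#' p$starts
#' @export
plant_seed_sites <- function(utr_length, seed_rna, n_sites) {
  seed_rna <- toupper(seed_rna)
  if (!nchar(seed_rna) %in% 6:8 || grepl("[^ACGU]", seed_rna))
    stop_mirlink("`seed_rna` must be an RNA string of length 6, 7 or 8.",
                 "config_error")
  if (n_sites < 0 || n_sites * nchar(seed_rna) > utr_length)
    stop_mirlink("Cannot pack the requested number of sites into the UTR.",
                 "capacity_error")
  site <- seed_rc_dna(seed_rna)
  out <- plant_multi_sites(utr_length, site, as.integer(n_sites),
                           guard_seeds = site)
  list(sequence = out$sequence, starts = out$starts[[1]])
}

#' Benchmark configuration for parameter-recovery checks
#'
#' A frozen synthetic-study design used to check that the pipeline
#' recovers what was planted: 200 subject pairs and a study-sized panel of
#' 814 miRNAs; eight genes carry planted fold changes spanning 0.4-3 at a
#' moderate baseline (50 RPMPCG); ten further genes (fold change 2, so
#' they pass the dysregulation screen) each carry one planted linear
#' miRNA association with slopes of magnitude 0.35-0.5, against six
#' upregulated (baseline 60, fold change 4) and four downregulated
#' (baseline 300, fold change 0.4) miRNAs. Negative-slope pairs get one
#' planted seed site each, so they are the ground-truth direct
#' interactions. Dispersion and subject variability are set so the planted
#' linear effects are the dominant signal at this sample size.
#'
#' @param seed Integer seed passed to [synthetic_config()].
#' @return A [synthetic_config()] whose ground truth contains 8
#'   fold-change genes, 10 associations and 5 direct interactions.
#' @export
recovery_benchmark_config <- function(seed = 1L) {
  genes_fc <- synthetic_gene_ids(18)[1:8]
  genes_as <- synthetic_gene_ids(18)[9:18]
  mirnas_pl <- synthetic_mirna_ids(10)
  betas <- c(-0.35, -0.4, -0.35, -0.5, -0.35, 0.35, 0.35, 0.4, 0.35, 0.5)
  mirna_fc <- c(4, 0.4, 4, 0.4, 4, 4, 0.4, 4, 4, 0.4)
  mirna_base <- ifelse(mirna_fc > 1, 60, 300)
  fc_pl <- c(2, 0.5, 3, 0.4, 1.8, 0.55, 2.5, 0.45)
  synthetic_config(
    n_subjects = 200, n_genes = 40, n_mirnas = 814, nb_dispersion = 0.01,
    subject_sd = 0.35,
    planted_gene_log_fc = setNames(log(c(fc_pl, rep(2, 10))),
                                   c(genes_fc, genes_as)),
    planted_mirna_log_fc = setNames(log(mirna_fc), mirnas_pl),
    planted_assoc = tibble(gene = genes_as, mirna = mirnas_pl, beta = betas),
    gene_log_baseline = setNames(rep(log(50 / 1e6), 18),
                                 c(genes_fc, genes_as)),
    mirna_log_baseline = setNames(log(mirna_base), mirnas_pl),
    seed = seed)
}

#' @rdname recovery_benchmark_config
#' @format NULL
#' @details `recovery_fc_genes()` and `recovery_assoc_pairs()` return the
#'   identifiers of the planted fold-change genes and association pairs of
#'   the benchmark design.
#' @export
recovery_fc_genes <- function() synthetic_gene_ids(18)[1:8]

#' @rdname recovery_benchmark_config
#' @export
recovery_assoc_pairs <- function() {
  tibble(gene = synthetic_gene_ids(18)[9:18],
         mirna = synthetic_mirna_ids(10),
         beta = c(-0.35, -0.4, -0.35, -0.5, -0.35, 0.35, 0.35, 0.4, 0.35,
                  0.5))
}
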