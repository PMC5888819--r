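# independent oracles kept deliberately naive

# all start offsets (0-based) of `site` in `seq`, overlapping included
naive_scan <- function(seq, site) {
  n <- nchar(seq); m <- nchar(site)
  if (m == 0 || n < m) return(integer())
  hits <- integer()
  for (i in seq_len(n - m + 1)) {
    if (substr(seq, i, i + m - 1) == site) hits <- c(hits, i - 1L)
  }
  hits
}

# DNA reverse complement of an RNA seed, character by character
naive_rc <- function(seed) {
  comp <- c(A = "T", C = "G", G = "C", U = "A", T = "A")
  paste(rev(comp[strsplit(toupper(seed), "")[[1]]]), collapse = "")
}

# brute-force BH step-up with explicit monotonicity enforcement
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# closed-form OLS via normal equations
normal_eq_beta <- function(y, x, age, sex_m) {
  X <- cbind(1, x, age, sex_m)
  solve(t(X) %*% X, t(X) %*% y)[2]
}

# small paired study for I/O and pipeline tests
tiny_study <- function(seed = 3, n_subjects = 8, n_genes = 5, n_mirnas = 4) {
  generate_study(synthetic_config(n_subjects = n_subjects, n_genes = n_genes,
                                  n_mirnas = n_mirnas, seed = seed))
}

wide_to_matrix_test <- function(tbl, id_col) {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  m
}
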