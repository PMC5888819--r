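# internal error helpers: every user-facing failure carries a subclass so
# callers (and tests) can distinguish configuration, pairing, format, ...
stop_mirlink <- function(msg, class, ...) {
  rlang::abort(msg, class = c(paste0("mirlink_", class), "mirlink_error"), ...)
}

assert_prob <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1)) {
    stop_mirlink(sprintf("`%s` must be numeric in [0, 1].", what), "domain_error")
  }
  invisible(x)
}

# run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards (NULL seed = use the current stream)
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# wide feature-by-sample tibble (first column = feature id) -> numeric matrix
wide_to_matrix <- function(tbl, id_col) {
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  rownames(m) <- tbl[[id_col]]
  storage.mode(m) <- "double"
  m
}

matrix_to_wide <- function(m, id_col) {
  bind_cols(tibble::tibble(!!id_col := rownames(m)), tibble::as_tibble(m))
}
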