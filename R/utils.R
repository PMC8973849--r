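# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards so library code never disturbs the
# user's stream. A NULL seed uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    abort("`seed` must be a single finite number or NULL.")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

check_prob <- function(x, name, lo = 0, hi = 1, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) & is.finite(x) &
    (if (open_lo) x > lo else x >= lo) &
    (if (open_hi) x < hi else x <= hi)
  if (!all(ok)) {
    abort(sprintf("`%s` must be in %s%g, %g%s.", name,
                  if (open_lo) "(" else "[", lo, hi,
                  if (open_hi) ")" else "]"))
  }
  invisible(x)
}

check_count <- function(x, name, min = 0) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x < min || x != round(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  invisible(as.integer(x))
}

# Counts tibble (gene_id + sample columns) -> integer/double matrix.
counts_to_matrix <- function(counts, id_col = 1L) {
  counts <- as_tibble(counts)
  ids <- counts[[id_col]]
  if (anyDuplicated(ids)) abort("feature ids must be unique.")
  m <- as.matrix(counts[, -id_col, drop = FALSE])
  if (!is.numeric(m)) abort("all sample columns must be numeric.")
  rownames(m) <- ids
  m
}

matrix_to_tibble <- function(m, id_name) {
  out <- as_tibble(m, .name_repair = "minimal")
  out <- tibble::add_column(out, !!id_name := rownames(m), .before = 1)
  out
}
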