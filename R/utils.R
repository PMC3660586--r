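# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. `seed = NULL` uses the session stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) {
    return(force(code))
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    rlang::abort("`seed` must be a single finite number or NULL.")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

# Numerically stable log(sum(exp(x))) over matrix rows.  Row maxima via
# columnwise pmax (few columns, many rows).
row_log_sum_exp <- function(mat) {
  nc <- ncol(mat)
  mx <- mat[, 1L]
  if (nc > 1L) for (j in 2:nc) mx <- pmax(mx, mat[, j])
  mx + log(rowSums(exp(mat - mx)))
}

# Round only for display; keeps full precision in returned objects.
round2 <- function(x) round(x, 2L)

`%||%` <- function(a, b) if (is.null(a)) b else a
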