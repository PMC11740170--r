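#' @keywords internal
"_PACKAGE"

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv())
    else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Pearson correlation that tolerates zero-variance vectors: defined as 0
# (with one warning at the call site that opts in via `warn`).
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) return(0)
  stats::cor(x, y)
}

# Row-wise correlation matrix over the rows of `m`, with zero-variance rows
# mapped to r = 0 against everything (and r = 1 with themselves).
row_cor_matrix <- function(m, warn = TRUE) {
  n <- nrow(m)
  v <- apply(m, 1L, stats::sd)
  degenerate <- v == 0
  if (any(degenerate) && warn)
    warning(sum(degenerate), " zero-variance spectrum(s); correlations set to 0")
  r <- matrix(0, n, n)
  ok <- which(!degenerate)
  if (length(ok) >= 2L)
    r[ok, ok] <- suppressWarnings(stats::cor(t(m[ok, , drop = FALSE])))
  diag(r) <- 1
  r
}

# Squared distance from points (x, y) to a centre.
dist2 <- function(x, y, cx, cy) (x - cx)^2 + (y - cy)^2

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
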