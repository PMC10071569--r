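# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("`%s` must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("`%s` must be >= 0 (got %g)", name, x)
  invisible(x)
}

# Trailing least-squares slope (units of y per unit of x) for each index i,
# over the window of the `window` most recent points ending at i. Indices
# with fewer than `window` points get NA. Causal by construction.
trailing_slope <- function(x, y, window) {
  n <- length(x)
  out <- rep(NA_real_, n)
  if (n < window) return(out)
  for (i in window:n) {
    idx <- (i - window + 1L):i
    xs <- x[idx] - mean(x[idx])
    ys <- y[idx]
    sxx <- sum(xs^2)
    out[i] <- if (sxx > 0) sum(xs * (ys - mean(ys))) / sxx else 0
  }
  out
}
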