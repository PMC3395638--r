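## Internal numeric helpers.

## Running minimum/maximum over a centred window of 2*halfwidth+1 points,
## truncated at the edges.  Implemented as an accumulation of shifted
## copies (vectorized pmin/pmax), O(n * halfwidth) but allocation-light.
runningMin <- function(x, halfwidth) {
  n <- length(x)
  if (halfwidth <= 0 || n == 0L) return(x)
  res <- x
  for (k in seq_len(min(halfwidth, n - 1L))) {
    res <- pmin(res,
                c(x[-seq_len(k)], rep(Inf, k)),      # window reaches right
                c(rep(Inf, k), x[seq_len(n - k)]))   # window reaches left
  }
  res
}

runningMax <- function(x, halfwidth) {
  n <- length(x)
  if (halfwidth <= 0 || n == 0L) return(x)
  res <- x
  for (k in seq_len(min(halfwidth, n - 1L))) {
    res <- pmax(res,
                c(x[-seq_len(k)], rep(-Inf, k)),
                c(rep(-Inf, k), x[seq_len(n - k)]))
  }
  res
}

## Evaluate `expr` under a locally seeded RNG, restoring the caller's RNG
## state afterwards.  seed = NULL leaves the global stream untouched.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Uniform-grid check: relative spread of spacings below `tol`.
isUniformGrid <- function(mz, tol = 1e-6) {
  if (length(mz) < 3L) return(TRUE)
  d <- diff(mz)
  (max(d) - min(d)) <= tol * stats::median(d)
}
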