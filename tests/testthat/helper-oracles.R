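## Independent brute-force oracles used to pin down the numerical
## behaviour of the main implementations.  These deliberately take the
## slow, explicit path.

## Savitzky-Golay by sliding least-squares polynomial fit: interior points
## use the centred window evaluated at its middle; the first/last half
## windows reuse the edge window's fit evaluated at the off-centre offsets.
sgOracle <- function(y, window, polyorder) {
  n <- length(y)
  k <- (window - 1L) %/% 2L
  fitAt <- function(idx, at) {
    t <- seq_along(idx)
    X <- outer(t, 0:polyorder, `^`)
    beta <- qr.solve(X, y[idx])
    sum(beta * at^(0:polyorder))
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i <= k) out[i] <- fitAt(1:window, i)
    else if (i > n - k) out[i] <- fitAt((n - window + 1L):n, i - (n - window))
    else out[i] <- fitAt((i - k):(i + k), k + 1L)
  }
  out
}

## Morphological opening by explicit double loops.
tophatOracle <- function(y, halfwidth) {
  n <- length(y)
  ero <- vapply(seq_len(n), function(i)
    min(y[max(1, i - halfwidth):min(n, i + halfwidth)]), numeric(1))
  dil <- vapply(seq_len(n), function(i)
    max(ero[max(1, i - halfwidth):min(n, i + halfwidth)]), numeric(1))
  pmax(y - dil, 0)
}

## Pearson correlation from the raw definition (no stats::cor).
pearsonOracle <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - n * mean(x) * mean(y)
  sxx <- sum(x^2) - n * mean(x)^2
  syy <- sum(y^2) - n * mean(y)^2
  sxy / sqrt(sxx * syy)
}

## UPGMA by O(n^3) re-averaging from the ORIGINAL distance matrix: at
## every step the inter-cluster distance is recomputed as the mean over
## all member pairs, never via the incremental update.  Returns the
## cophenetic distance matrix (merge distance d between every leaf pair).
upgmaCopheneticOracle <- function(D) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- NULL; bestd <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < bestd) { bestd <- d; best <- c(i, j) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- bestd; coph[b, a] <- bestd
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  coph
}

copheneticFromTree <- function(tree) {
  hc <- asHclust(tree)
  as.matrix(stats::cophenetic(hc))[hc$labels, hc$labels]
}

## All permutations of 1..n (small n), one per row.
allPerms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- allPerms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

## Exact one-sided Mantel p by exhaustive enumeration of relabelings
## (identity included in the numerator and denominator).
mantelExactOracle <- function(A, B) {
  n <- nrow(A)
  ut <- upper.tri(A)
  va <- A[ut]
  robs <- pearsonOracle(va, B[ut])
  P <- allPerms(n)
  rs <- apply(P, 1, function(p) pearsonOracle(va, B[p, p][ut]))
  list(r = robs, p = sum(rs >= robs - 1e-12) / nrow(P))
}

## Fixed-radius grouping of the pooled peak multiset, label-blind: a new
## centre opens when a peak is farther than maxShift from the running
## mean of the current group.
pooledGroupingOracle <- function(mzValues, maxShift) {
  mzValues <- sort(mzValues)
  centres <- numeric(0)
  cur <- numeric(0)
  for (m in mzValues) {
    if (length(cur) && abs(m - mean(cur)) > maxShift) {
      centres <- c(centres, mean(cur))
      cur <- numeric(0)
    }
    cur <- c(cur, m)
  }
  c(centres, mean(cur))
}
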