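#' Pearson correlation of two binary peak vectors
#'
#' The ordinary Pearson correlation evaluated on 0/1 presence vectors
#' (equivalently, the phi coefficient).  Undefined when either vector is
#' constant.
#'
#' @param x,y equal-length numeric 0/1 vectors (length >= 2).
#' @return the correlation coefficient in `[-1, 1]`.
#' @export
#' @examples
#' binaryPearson(c(1, 1, 0, 0, 1), c(1, 0, 0, 0, 1))  # 2/3
binaryPearson <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and y must have equal length >= 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: constant peak vector")
  stats::cor(x, y)
}

#' Binary-Pearson proximity matrix
#'
#' All-pairs [binaryPearson()] over the spectrum columns of a binarized
#' peak matrix.  Spectra with constant (typically all-zero) bit vectors
#' make the coefficient undefined and are reported by name.
#'
#' @param x a [BinaryPeakMatrix], or a plain 0/1 matrix with positions in
#'   rows and labelled spectrum columns.
#' @return a [SimilarityMatrix].
#' @export
proximityMatrix <- function(x) {
  bits <- if (is(x, "BinaryPeakMatrix")) peakPresence(x) else as.matrix(x)
  if (ncol(bits) < 2L) stop("need at least two spectra")
  if (nrow(bits) < 2L) stop("need at least two peak positions")
  sds <- apply(bits, 2, stats::sd)
  if (any(sds == 0))
    stop("undefined correlation: constant peak vector for spectrum ",
         paste(colnames(bits)[sds == 0], collapse = ", "))
  r <- stats::cor(bits)
  r <- pmin(pmax(r, -1), 1)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  SimilarityMatrix(r)
}

#' UPGMA (group-average) dendrogram
#'
#' Agglomerative clustering on the distance `d = 1 - r` derived from a
#' binary-Pearson similarity matrix (or on a distance matrix supplied
#' directly).  At every step the closest pair of clusters is merged --
#' ties broken in favour of the lowest-index pair, so trees are
#' bit-reproducible -- and the distance from the new cluster to any other
#' is the unweighted mean of all member pairwise distances.  Merge
#' heights are `d/2` (ultrametric convention), so a two-leaf tree with
#' `r = 0.8` merges at height 0.1.
#'
#' @param x a [SimilarityMatrix] (distances taken as `1 - r`) or a
#'   symmetric numeric distance matrix with labelled dimnames.
#' @return a [SpectralDendrogram].
#' @export
upgmaTree <- function(x) {
  D <- if (is(x, "SimilarityMatrix")) 1 - as.matrix(x) else as.matrix(x)
  labels <- rownames(D)
  n <- nrow(D)
  if (is.null(labels) || n < 2L)
    stop("need a labelled matrix with at least two entries")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")

  id <- -seq_len(n)          # hclust convention: negative = leaf
  size <- rep(1L, n)
  active <- seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- c(NA_integer_, NA_integer_); bestd <- Inf
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        dij <- D[active[i], active[j]]
        if (dij < bestd) { bestd <- dij; best <- c(i, j) }
      }
    }
    a <- active[best[1]]; b <- active[best[2]]
    merge[step, ] <- sort(c(id[a], id[b]))
    height[step] <- bestd / 2
    ## group-average update: unweighted mean over all member pairs
    for (k in active) {
      if (k == a || k == b) next
      D[a, k] <- D[k, a] <-
        (size[a] * D[a, k] + size[b] * D[b, k]) / (size[a] + size[b])
    }
    size[a] <- size[a] + size[b]
    id[a] <- step
    active <- active[active != b]
  }
  SpectralDendrogram(merge, height, labels)
}

#' Convert a dendrogram to an hclust object
#'
#' Heights are doubled on conversion (`hclust` stores the full merge
#' distance `d`, while [SpectralDendrogram] stores `d/2`), so that
#' `ape::as.phylo()` -- which halves hclust heights -- reproduces the
#' original ultrametric branch lengths.
#'
#' @param tree a [SpectralDendrogram].
#' @return an object of class `hclust`.
#' @export
asHclust <- function(tree) {
  stopifnot(is(tree, "SpectralDendrogram"))
  n <- length(tree@labels)
  ## leaf order by recursive traversal
  expand <- function(node) {
    if (node < 0) return(-node)
    c(expand(tree@merge[node, 1]), expand(tree@merge[node, 2]))
  }
  structure(list(merge = tree@merge, height = 2 * tree@height,
                 order = expand(n - 1L), labels = tree@labels,
                 method = "average",
                 call = match.call(), dist.method = "1 - binary Pearson"),
            class = "hclust")
}

#' Cut a dendrogram into k clusters
#'
#' @param tree a [SpectralDendrogram].
#' @param k number of clusters.
#' @return named integer vector of cluster memberships.
#' @export
cutDendrogram <- function(tree, k) stats::cutree(asHclust(tree), k = k)

#' Known/novel call against a reference library
#'
#' Compares query spectra to a reference (type-strain) library on a
#' jointly binarized peak matrix: the best similarity is the maximum
#' binary-Pearson coefficient over the references, and a query whose best
#' similarity falls below the threshold (default 0.5) is flagged a
#' candidate novel species.  Queries and references must come from one
#' joint [alignPeaks()]/[binarizePeaks()] run so that their bit vectors
#' share positions.
#'
#' @param x a [BinaryPeakMatrix] containing query and reference columns,
#'   or a plain 0/1 matrix with labelled columns.
#' @param queryLabels column labels treated as queries.
#' @param referenceLabels column labels of the library; defaults to all
#'   remaining columns.
#' @param threshold similarity below which a query is called
#'   `candidate_novel` (strict `<`).
#' @return a `data.frame` with one row per query: `query`, `best_match`,
#'   `best_similarity`, `verdict` (`"assigned"`/`"candidate_novel"`),
#'   `threshold`.
#' @export
callNovelty <- function(x, queryLabels, referenceLabels = NULL,
                        threshold = 0.5) {
  bits <- if (is(x, "BinaryPeakMatrix")) peakPresence(x) else as.matrix(x)
  if (is.null(referenceLabels))
    referenceLabels <- setdiff(colnames(bits), queryLabels)
  if (!length(referenceLabels)) stop("empty reference library")
  missing <- setdiff(c(queryLabels, referenceLabels), colnames(bits))
  if (length(missing))
    stop("labels not in matrix: ", paste(missing, collapse = ", "))
  res <- lapply(queryLabels, function(q) {
    sims <- vapply(referenceLabels, function(r)
      binaryPearson(bits[, q], bits[, r]), numeric(1))
    best <- which.max(sims)
    data.frame(query = q, best_match = referenceLabels[best],
               best_similarity = sims[best],
               verdict = if (sims[best] < threshold) "candidate_novel"
                         else "assigned",
               threshold = threshold, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Mantel matrix-correlation test
#'
#' Correlates two similarity (or distance) matrices over the same strains:
#' the statistic is the Pearson correlation of the `n(n-1)/2` off-diagonal
#' upper-triangle entries, and significance comes from jointly permuting
#' rows and columns of the second matrix.  One-sided for positive
#' association: `p = (1 + #{permuted r >= observed r}) / (nPermutations + 1)`.
#'
#' @param a,b symmetric matrices (or [SimilarityMatrix] objects) with
#'   matching labels, `n >= 4`.
#' @param nPermutations number of permutations (default 9,999).
#' @param seed optional integer for a reproducible permutation stream; the
#'   caller's RNG state is untouched.
#' @return a [MantelResult].
#' @export
mantelTest <- function(a, b, nPermutations = 9999, seed = NULL) {
  A <- if (is(a, "SimilarityMatrix")) as.matrix(a) else as.matrix(a)
  B <- if (is(b, "SimilarityMatrix")) as.matrix(b) else as.matrix(b)
  n <- nrow(A)
  if (n != ncol(A) || !identical(dim(A), dim(B)))
    stop("matrices must be square with identical dimensions")
  if (n < 4L) stop("need at least 4 strains")
  if (!is.null(rownames(A)) && !is.null(rownames(B)) &&
      !identical(rownames(A), rownames(B)))
    stop("label mismatch between matrices")
  if (max(abs(A - t(A))) > 1e-8 || max(abs(B - t(B))) > 1e-8)
    stop("matrices must be symmetric")
  ut <- upper.tri(A)
  va <- A[ut]; vb <- B[ut]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("constant off-diagonal entries; correlation undefined")
  robs <- stats::cor(va, vb)
  count <- withLocalSeed(seed, {
    cnt <- 0L
    for (i in seq_len(nPermutations)) {
      p <- sample.int(n)
      rp <- stats::cor(va, B[p, p][ut])
      if (rp >= robs - 1e-12) cnt <- cnt + 1L
    }
    cnt
  })
  new("MantelResult", statistic = robs,
      pValue = (1 + count) / (nPermutations + 1),
      nPermutations = as.integer(nPermutations),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}
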