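#' Gap-excluded pairwise identity of aligned sequences
#'
#' Percent identity over the columns of a pairwise alignment, skipping
#' every column in which either sequence carries a gap.  Ambiguity codes
#' (anything other than A, C, G, T/U) are likewise excluded from both
#' numerator and denominator.  Case-insensitive; U is treated as T.
#'
#' @param a,b equal-length aligned sequences (character strings).
#' @return a list with `compared_columns`, `matches` and `similarity`
#'   (percent).
#' @export
#' @examples
#' pairwiseIdentity("AC-GT", "ACAGT")$similarity  # 100
pairwiseIdentity <- function(a, b) {
  ca <- .splitBases(a); cb <- .splitBases(b)
  if (length(ca) != length(cb)) stop("aligned sequences differ in length")
  valid <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  compared <- sum(valid)
  if (compared == 0L) stop("no comparable (non-gap, unambiguous) columns")
  matches <- sum(ca[valid] == cb[valid])
  list(compared_columns = compared, matches = matches,
       similarity = 100 * matches / compared)
}

.splitBases <- function(s) {
  x <- strsplit(toupper(as.character(s)), "")[[1]]
  x[x == "U"] <- "T"
  x
}

#' Kimura two-parameter distance
#'
#' The K2P nucleotide distance
#' `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`, with the transition
#' proportion `P` (A<->G, C<->T) and transversion proportion `Q` computed
#' over the gap- and ambiguity-excluded columns of a pairwise alignment.
#'
#' @param a,b equal-length aligned sequences.
#' @return a list with `P`, `Q` and `distance` (substitutions per site).
#' @export
k2pDistance <- function(a, b) {
  ca <- .splitBases(a); cb <- .splitBases(b)
  if (length(ca) != length(cb)) stop("aligned sequences differ in length")
  valid <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  n <- sum(valid)
  if (n == 0L) stop("no comparable columns")
  ca <- ca[valid]; cb <- cb[valid]
  diff <- ca != cb
  purine <- c("A", "G")
  transition <- diff & ((ca %in% purine) == (cb %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0)
    stop("sequences too divergent: K2P distance undefined (saturation)")
  list(P = P, Q = Q,
       distance = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q))
}

#' All-pairs 16S identity matrix
#'
#' Gap-excluded [pairwiseIdentity()] over every pair of an aligned
#' sequence set, returned as the symmetric percent-identity matrix (label
#' order preserved) that [mantelTest()] and [writeMatrixCsv()] consume.
#'
#' @param sequences an aligned `DNAStringSet` (e.g. from
#'   [readFastaSequences()]) or named character vector; all sequences
#'   must have equal aligned length.
#' @return numeric matrix of percent identities, diagonal 100.
#' @export
similarityMatrix16S <- function(sequences) {
  seqs <- as.character(sequences)
  if (is.null(names(seqs)) && !is.null(names(sequences)))
    names(seqs) <- names(sequences)
  if (length(seqs) < 2L) stop("need at least two aligned sequences")
  if (length(unique(nchar(seqs))) != 1L)
    stop("sequences differ in aligned length")
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      m[i, j] <- m[j, i] <- pairwiseIdentity(seqs[i], seqs[j])$similarity
    }
  }
  m
}
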