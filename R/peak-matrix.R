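#' Pick peaks from a relative-intensity spectrum
#'
#' Detects local maxima (plateaus are reduced to their central point)
#' whose relative intensity is at least `minRelIntensity` percent and
#' whose topographic prominence -- apex height minus the higher of the two
#' bounding valleys, where a valley is the minimum between the apex and
#' the nearest higher point (or the spectrum edge) -- is at least
#' `minProminence`.
#'
#' @param spectrum a [Spectrum] at stage `"relative"`.
#' @param minRelIntensity minimum apex height, percent of base peak.
#' @param minProminence minimum prominence, percent of base peak.
#' @return a [PeakList] (possibly empty).
#' @export
pickPeaks <- function(spectrum, minRelIntensity = 1, minProminence = 1) {
  stopifnot(is(spectrum, "Spectrum"))
  if (processingStage(spectrum) != "relative")
    stop("peak picking expects a relative-intensity spectrum")
  y <- intensity(spectrum)
  n <- length(y)
  if (n < 3L || max(y) == 0)
    return(PeakList(spectrumLabels(spectrum), numeric(0), numeric(0)))

  ## collapse equal-value runs so flat-topped peaks yield one apex
  r <- rle(y)
  rv <- r$values
  rend <- cumsum(r$lengths)
  rstart <- rend - r$lengths + 1L
  k <- length(rv)
  if (k < 3L) return(PeakList(spectrumLabels(spectrum), numeric(0), numeric(0)))
  isMax <- c(FALSE, rv[2:(k - 1)] > rv[1:(k - 2)] & rv[2:(k - 1)] > rv[3:k],
             FALSE)
  apexRun <- which(isMax)
  if (!length(apexRun))
    return(PeakList(spectrumLabels(spectrum), numeric(0), numeric(0)))
  apex <- (rstart[apexRun] + rend[apexRun]) %/% 2L
  h <- y[apex]

  keep <- h >= minRelIntensity
  apex <- apex[keep]; h <- h[keep]
  if (!length(apex))
    return(PeakList(spectrumLabels(spectrum), numeric(0), numeric(0)))

  prominence <- vapply(seq_along(apex), function(i) {
    a <- apex[i]; ha <- h[i]
    left <- if (a > 1L) y[1:(a - 1L)] else numeric(0)
    higher <- which(left > ha)
    leftBase <- if (length(higher)) min(left[(max(higher) + 1L):(a - 1L)])
                else if (length(left)) min(left) else ha
    right <- if (a < n) y[(a + 1L):n] else numeric(0)
    higher <- which(right > ha)
    rightBase <- if (length(higher)) min(right[1:(min(higher) - 1L)])
                 else if (length(right)) min(right) else ha
    ha - max(leftBase, rightBase)
  }, numeric(1))

  keep <- prominence >= minProminence
  PeakList(spectrumLabels(spectrum), mz(spectrum)[apex][keep], h[keep])
}

#' Match peaks across spectra within a maximum shift
#'
#' Greedy single-linkage grouping of the pooled peaks: all (m/z, spectrum)
#' pairs are sorted by m/z and scanned once.  A peak joins the currently
#' open consensus position when its m/z lies within `maxShift` Da of the
#' running mean of the members; otherwise it founds a new position.  A
#' spectrum never contributes two peaks to one position: on a collision
#' the peak nearer the consensus wins and the other becomes its own
#' position.  Because peaks are pooled and sorted first, the result does
#' not depend on the order of the input peak lists (columns keep input
#' order).
#'
#' @param peakLists list of [PeakList] objects (>= 1).
#' @param maxShift maximum distance to the consensus position, Da.  At the
#'   default 1 Da working grid the conventional "maximum shift 20" equals
#'   a 20 Da matching radius.
#' @return an [AlignedPeakMatrix]: consensus positions x spectra, relative
#'   intensities (0 where a spectrum has no member).
#' @export
alignPeaks <- function(peakLists, maxShift = 20) {
  if (!length(peakLists)) stop("need at least one peak list")
  if (maxShift <= 0) stop("maxShift must be positive")
  labels <- vapply(peakLists, spectrumLabels, character(1))
  if (anyDuplicated(labels)) stop("duplicate spectrum labels")
  pool <- data.frame(
    mz = unlist(lapply(peakLists, mz)),
    intensity = unlist(lapply(peakLists, intensity)),
    label = rep(labels, vapply(peakLists, function(p) length(mz(p)),
                               integer(1))),
    stringsAsFactors = FALSE)
  if (!nrow(pool))
    return(AlignedPeakMatrix(numeric(0), labels,
                             matrix(0, 0, length(labels))))
  pool <- pool[order(pool$mz, match(pool$label, labels)), , drop = FALSE]

  groups <- list()             # closed groups, each a data.frame
  cur <- pool[0, ]             # open group
  close_cur <- function() {
    if (nrow(cur)) groups[[length(groups) + 1L]] <<- cur
  }
  for (i in seq_len(nrow(pool))) {
    p <- pool[i, ]
    if (!nrow(cur)) { cur <- p; next }
    cons <- mean(cur$mz)
    if (abs(p$mz - cons) <= maxShift) {
      j <- which(cur$label == p$label)
      if (length(j)) {
        ## collision: the peak nearer the consensus keeps the position
        if (abs(p$mz - cons) < abs(cur$mz[j] - cons)) {
          groups[[length(groups) + 1L]] <- cur[j, , drop = FALSE]
          cur <- rbind(cur[-j, , drop = FALSE], p)
        } else {
          close_cur()
          cur <- p
        }
      } else {
        cur <- rbind(cur, p)
      }
    } else {
      close_cur()
      cur <- p
    }
  }
  close_cur()

  positions <- vapply(groups, function(g) mean(g$mz), numeric(1))
  o <- order(positions)
  groups <- groups[o]
  positions <- positions[o]
  ## guard against exactly coincident consensus positions
  eq <- which(diff(positions) <= 0)
  if (length(eq))
    positions[eq + 1L] <- positions[eq] + 1e-9

  values <- matrix(0, nrow = length(groups), ncol = length(labels),
                   dimnames = list(NULL, labels))
  for (g in seq_along(groups))
    values[g, groups[[g]]$label] <- groups[[g]]$intensity
  AlignedPeakMatrix(positions, labels, values)
}

#' Binarize an aligned peak matrix
#'
#' Presence/absence coding of the aligned relative intensities: bit = 1
#' iff the value is strictly greater than `threshold` percent.  Consensus
#' positions outside the m/z `window` are dropped.  The defaults (strict
#' >5%, m/z 3,500-20,000) are the fingerprinting convention used
#' throughout the package.  Spectra whose bits are all zero are recorded
#' in `metadata(x)$emptyColumns`.
#'
#' @param aligned an [AlignedPeakMatrix].
#' @param threshold relative-intensity threshold, percent (strict).
#' @param window numeric(2), m/z window kept (inclusive).
#' @return a [BinaryPeakMatrix].
#' @export
binarizePeaks <- function(aligned, threshold = 5, window = c(3500, 20000)) {
  stopifnot(is(aligned, "AlignedPeakMatrix"))
  pos <- peakPositions(aligned)
  keep <- pos >= window[1] & pos <= window[2]
  v <- peakIntensities(aligned)[keep, , drop = FALSE]
  bits <- (v > threshold) * 1
  out <- BinaryPeakMatrix(pos[keep], spectrumLabels(aligned), bits,
                          window = window, threshold = threshold)
  empty <- colnames(bits)[colSums(bits) == 0]
  if (length(empty)) metadata(out)$emptyColumns <- empty
  out
}
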