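#' Preprocessing configuration
#'
#' Bundles the parameters of the profile-spectrum preprocessing chain:
#' repeated Savitzky-Golay smoothing, morphological (top-hat) baseline
#' subtraction, and relative-intensity scaling.  Three smoothing cycles
#' follow the published workflow; window and polynomial order are not
#' reported there, so the defaults here are a deliberately gentle 7-point
#' quadratic filter.
#'
#' @param sgWindow odd Savitzky-Golay window length in points (> `sgPolyorder`).
#' @param sgPolyorder polynomial order of the filter.
#' @param sgCycles how many times the filter is applied (>= 0).
#' @param baselineMethod `"tophat"` (rolling minimum then maximum) or
#'   `"none"` for pre-centroided data.
#' @param baselineHalfwidth half-width of the structuring element in Da.
#' @return a validated list of class `PreprocessConfig`.
#' @export
#' @examples
#' preprocessConfig(sgWindow = 9, baselineHalfwidth = 100)
preprocessConfig <- function(sgWindow = 7, sgPolyorder = 2, sgCycles = 3,
                             baselineMethod = c("tophat", "none"),
                             baselineHalfwidth = 50) {
  baselineMethod <- match.arg(baselineMethod)
  if (sgWindow %% 2 != 1 || sgWindow <= sgPolyorder)
    stop("sgWindow must be odd and greater than sgPolyorder")
  if (sgCycles < 0) stop("sgCycles must be >= 0")
  if (baselineHalfwidth <= 0) stop("baselineHalfwidth must be positive")
  structure(list(sgWindow = as.integer(sgWindow),
                 sgPolyorder = as.integer(sgPolyorder),
                 sgCycles = as.integer(sgCycles),
                 baselineMethod = baselineMethod,
                 baselineHalfwidth = baselineHalfwidth),
            class = "PreprocessConfig")
}

#' Savitzky-Golay smoothing
#'
#' Applies the Savitzky-Golay filter `cycles` times to a raw (or already
#' smoothed) profile spectrum.  Each pass replaces every point by the
#' value of the local least-squares polynomial fit of order `polyorder`
#' over the centred `window`; spectrum edges use the asymmetric fits of
#' the first/last full window.  Constant and (for `polyorder >= 1`)
#' linear spectra pass through unchanged.  Any small negative excursions
#' are clipped to zero after the final cycle.
#'
#' @param spectrum a [Spectrum] at stage `"raw"` or `"smoothed"`, on a
#'   (near-)uniform m/z grid.
#' @param config a [preprocessConfig()]; `sgWindow`, `sgPolyorder` and
#'   `sgCycles` are used.
#' @return the smoothed [Spectrum], stage `"smoothed"`.
#' @export
smoothSpectrum <- function(spectrum, config = preprocessConfig()) {
  stopifnot(is(spectrum, "Spectrum"))
  if (!processingStage(spectrum) %in% c("raw", "smoothed"))
    stop("smoothing expects a raw or smoothed spectrum, got stage '",
         processingStage(spectrum), "'")
  n <- length(spectrum@intensity)
  if (config$sgWindow > n)
    stop("Savitzky-Golay window (", config$sgWindow,
         ") larger than spectrum (", n, " points)")
  if (!isUniformGrid(spectrum@mz, tol = 0.05))
    warning("m/z grid of '", spectrum@label,
            "' is not uniform; consider resampling before smoothing")
  y <- spectrum@intensity
  for (i in seq_len(config$sgCycles))
    y <- signal::sgolayfilt(y, p = config$sgPolyorder, n = config$sgWindow)
  Spectrum(spectrum@label, spectrum@mz, pmax(y, 0), stage = "smoothed",
           metadata = spectrum@metadata)
}

#' Top-hat baseline subtraction
#'
#' Estimates the baseline as a morphological opening -- a rolling minimum
#' followed by a rolling maximum over a window of `2 * halfwidth + 1`
#' points (halfwidth given in Da and converted via the grid spacing) --
#' and subtracts it, clipping at zero.  Peaks narrower than the
#' structuring element are preserved; smooth drifts wider than it are
#' removed.
#'
#' @param spectrum a [Spectrum] at stage `"smoothed"` (or `"raw"` when
#'   smoothing is disabled).
#' @param config a [preprocessConfig()]; `baselineMethod` and
#'   `baselineHalfwidth` are used.  With method `"none"` the intensities
#'   pass through unchanged.
#' @return the corrected [Spectrum], stage `"baselined"`.
#' @export
subtractBaseline <- function(spectrum, config = preprocessConfig()) {
  stopifnot(is(spectrum, "Spectrum"))
  if (!processingStage(spectrum) %in% c("raw", "smoothed"))
    stop("baseline subtraction expects a raw or smoothed spectrum, got stage '",
         processingStage(spectrum), "'")
  y <- spectrum@intensity
  if (config$baselineMethod == "tophat" && length(y) > 1L) {
    step <- stats::median(diff(spectrum@mz))
    h <- max(1L, as.integer(round(config$baselineHalfwidth / step)))
    baseline <- runningMax(runningMin(y, h), h)
    y <- pmax(y - baseline, 0)
  }
  Spectrum(spectrum@label, spectrum@mz, y, stage = "baselined",
           metadata = spectrum@metadata)
}

#' Relative-intensity scaling
#'
#' Rescales a baseline-corrected spectrum so its base peak is 100
#' (percent of base peak).  An all-zero spectrum is returned unchanged
#' with `metadata(x)$empty = TRUE` so downstream stages can reject it.
#' Idempotent.
#'
#' @param spectrum a [Spectrum] at stage `"baselined"` or `"relative"`.
#' @return the scaled [Spectrum], stage `"relative"`.
#' @export
toRelative <- function(spectrum) {
  stopifnot(is(spectrum, "Spectrum"))
  if (!processingStage(spectrum) %in% c("baselined", "relative"))
    stop("relative scaling expects a baselined spectrum, got stage '",
         processingStage(spectrum), "'")
  y <- spectrum@intensity
  md <- spectrum@metadata
  m <- if (length(y)) max(y) else 0
  if (m == 0) {
    md$empty <- TRUE
  } else {
    y <- pmin(100 * y / m, 100)  # guard the base peak against fp overshoot
  }
  Spectrum(spectrum@label, spectrum@mz, y, stage = "relative", metadata = md)
}

#' Resample a spectrum onto a new m/z grid
#'
#' Linear interpolation; points outside the original range take the
#' nearest edge value.
#'
#' @param spectrum a [Spectrum].
#' @param newMz strictly increasing target grid.
#' @return the resampled [Spectrum], same stage.
#' @export
resampleSpectrum <- function(spectrum, newMz) {
  stopifnot(is(spectrum, "Spectrum"))
  y <- stats::approx(spectrum@mz, spectrum@intensity, xout = newMz,
                     rule = 2)$y
  ## re-normalize a relative spectrum: interpolation can shave the apex
  if (processingStage(spectrum) == "relative" && max(y) > 0)
    y <- 100 * y / max(y)
  Spectrum(spectrum@label, newMz, y, stage = spectrum@stage,
           metadata = spectrum@metadata)
}

#' Average replicate spectra
#'
#' Pointwise arithmetic mean of replicate spectra at stage `"relative"`.
#' If the m/z grids differ and `resample = TRUE`, all spectra are first
#' linearly resampled onto the coarsest common uniform grid (step = the
#' largest median spacing, restricted to the shared m/z range).  The mean
#' of relative spectra generally has a base peak below 100, so the result
#' is returned at stage `"baselined"`; apply [toRelative()] before peak
#' picking.  `metadata(x)$members` records the member labels.
#'
#' @param spectra list of [Spectrum] objects at stage `"relative"`.
#' @param resample resample mixed grids (default) or raise an error.
#' @param label label of the average spectrum.
#' @return the average [Spectrum].
#' @export
averageSpectra <- function(spectra, resample = TRUE, label = NULL) {
  if (!length(spectra)) stop("cannot average an empty spectrum list")
  ok <- vapply(spectra, function(s) is(s, "Spectrum") &&
                 processingStage(s) == "relative", logical(1))
  if (!all(ok)) stop("all inputs must be Spectrum objects at stage 'relative'")
  grids <- lapply(spectra, mz)
  same <- all(vapply(grids[-1], function(g)
    length(g) == length(grids[[1]]) && isTRUE(all.equal(g, grids[[1]])),
    logical(1)))
  if (!same) {
    if (!resample) stop("mixed m/z grids; set resample = TRUE")
    step <- max(vapply(grids, function(g) stats::median(diff(g)), numeric(1)))
    lo <- max(vapply(grids, min, numeric(1)))
    hi <- min(vapply(grids, max, numeric(1)))
    if (hi <= lo) stop("spectra share no m/z range")
    common <- seq(lo, hi, by = step)
    spectra <- lapply(spectra, resampleSpectrum, newMz = common)
  }
  mat <- vapply(spectra, intensity, numeric(length(mz(spectra[[1]]))))
  avg <- rowMeans(as.matrix(mat))
  if (is.null(label))
    label <- sprintf("average_of_%d", length(spectra))
  Spectrum(label, mz(spectra[[1]]), avg, stage = "baselined",
           metadata = list(members = vapply(spectra, spectrumLabels,
                                            character(1)),
                           n = length(spectra)))
}

#' Run the full preprocessing chain on one spectrum
#'
#' Smoothing (unless `sgCycles = 0`), baseline subtraction, and relative
#' scaling, in that order.
#'
#' @param spectrum a raw [Spectrum].
#' @param config a [preprocessConfig()].
#' @return a [Spectrum] at stage `"relative"`.
#' @export
preprocessSpectrum <- function(spectrum, config = preprocessConfig()) {
  s <- if (config$sgCycles > 0) smoothSpectrum(spectrum, config) else spectrum
  toRelative(subtractBaseline(s, config))
}
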