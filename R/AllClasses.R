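#' @include AllGenerics.R
NULL

## Central S4 containers.  Spectra and peak lists are lightweight value
## classes; the aligned/binary peak matrices extend SummarizedExperiment so
## the usual Bioconductor subsetting and metadata machinery applies.

.STAGES <- c("raw", "smoothed", "baselined", "relative")

## Acquisition range of the instrument method emulated throughout (Da).
.ACQUISITION_RANGE <- c(2000, 20000)

#' Single-replicate mass spectrum
#'
#' A profile spectrum for one strain replicate: paired `mz` and
#' `intensity` vectors plus a `stage` flag tracking preprocessing state
#' (`"raw"` -> `"smoothed"` -> `"baselined"` -> `"relative"`).  All m/z
#' values are treated as singly protonated species.
#'
#' @slot label character(1), strain/replicate identifier.
#' @slot mz strictly increasing numeric vector of m/z values (Da).
#' @slot intensity non-negative numeric vector, same length as `mz`.
#' @slot stage one of `"raw"`, `"smoothed"`, `"baselined"`, `"relative"`.
#'   At stage `"relative"` the maximum intensity is 100 (base peak) unless
#'   the spectrum is all zero.
#' @slot metadata list of free-form annotations (e.g. `empty`, `members`).
#'
#' @param label,mz,intensity,stage,metadata see slot descriptions.
#' @return `Spectrum()` returns a validated `Spectrum` object.
#' @export
#' @examples
#' Spectrum("ec1", mz = c(2000, 2001, 2002), intensity = c(0, 5, 0))
setClass("Spectrum",
  representation(label = "character", mz = "numeric", intensity = "numeric",
                 stage = "character", metadata = "list"))

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@label) != 1L) msg <- c(msg, "label must be a single string")
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msg <- c(msg, "mz must be strictly increasing")
  if (length(object@intensity) && any(object@intensity < 0))
    msg <- c(msg, "intensity must be non-negative")
  if (!(object@stage %in% .STAGES))
    msg <- c(msg, sprintf("stage must be one of %s", paste(.STAGES, collapse = ", ")))
  if (object@stage == "relative" && length(object@intensity)) {
    m <- max(object@intensity)
    if (m > 0 && abs(m - 100) > 1e-6)
      msg <- c(msg, "relative-stage spectrum must have max intensity 100")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Spectrum-class
#' @export
Spectrum <- function(label, mz, intensity, stage = "raw", metadata = list()) {
  new("Spectrum", label = as.character(label), mz = as.numeric(mz),
      intensity = as.numeric(intensity), stage = stage, metadata = metadata)
}

#' @rdname accessors
#' @export
setMethod("mz", "Spectrum", function(x) x@mz)
#' @rdname accessors
#' @export
setMethod("intensity", "Spectrum", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("spectrumLabels", "Spectrum", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("processingStage", "Spectrum", function(x) x@stage)

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum '%s': %d points, m/z %.1f-%.1f, stage '%s'\n",
              object@label, length(object@mz),
              if (length(object@mz)) min(object@mz) else NA_real_,
              if (length(object@mz)) max(object@mz) else NA_real_,
              object@stage))
})

#' Picked peak list
#'
#' Centroided peaks of one spectrum: apex m/z plus relative intensity in
#' percent of the base peak.
#'
#' @slot label character(1) spectrum identifier.
#' @slot mz strictly increasing apex m/z (Da).
#' @slot intensity relative intensities in `[0, 100]`.
#'
#' @param label,mz,intensity see slots.
#' @return `PeakList()` returns a validated `PeakList`.
#' @export
setClass("PeakList",
  representation(label = "character", mz = "numeric", intensity = "numeric"))

setValidity("PeakList", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msg <- c(msg, "peaks must be sorted by strictly increasing mz")
  if (length(object@intensity) &&
      (any(object@intensity < 0) || any(object@intensity > 100)))
    msg <- c(msg, "relative intensity must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' @rdname PeakList-class
#' @export
PeakList <- function(label, mz, intensity) {
  o <- order(mz)
  new("PeakList", label = as.character(label), mz = as.numeric(mz)[o],
      intensity = as.numeric(intensity)[o])
}

#' @rdname accessors
#' @export
setMethod("mz", "PeakList", function(x) x@mz)
#' @rdname accessors
#' @export
setMethod("intensity", "PeakList", function(x) x@intensity)
#' @rdname accessors
#' @export
setMethod("spectrumLabels", "PeakList", function(x) x@label)

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList '%s': %d peaks\n", object@label, length(object@mz)))
})

#' Aligned peak matrix
#'
#' Consensus peak positions x spectra matrix of relative intensities
#' (percent of each spectrum's base peak; 0 where a spectrum has no peak at
#' that position).  Extends [SummarizedExperiment::SummarizedExperiment];
#' consensus m/z positions live in `rowData(x)$mz`, the intensities in
#' assay `"relint"`.
#'
#' @param positions strictly increasing consensus m/z (Da).
#' @param labels spectrum identifiers (columns).
#' @param values numeric matrix `length(positions)` x `length(labels)` of
#'   relative intensities in `[0, 100]`.
#' @return an `AlignedPeakMatrix`.
#' @export
setClass("AlignedPeakMatrix", contains = "SummarizedExperiment")

setValidity("AlignedPeakMatrix", function(object) {
  msg <- character()
  if (!"relint" %in% assayNames(object)) return("assay 'relint' missing")
  p <- rowData(object)$mz
  if (is.null(p)) msg <- c(msg, "rowData(x)$mz missing")
  else if (length(p) > 1L && any(diff(p) <= 0))
    msg <- c(msg, "consensus positions must be strictly increasing")
  v <- assay(object, "relint")
  if (any(v < -1e-9) || any(v > 100 + 1e-9))
    msg <- c(msg, "relative intensities must lie in [0, 100]")
  if (length(msg)) msg else TRUE
})

#' @rdname AlignedPeakMatrix-class
#' @export
AlignedPeakMatrix <- function(positions, labels, values) {
  values <- as.matrix(values)
  dimnames(values) <- list(NULL, labels)
  new("AlignedPeakMatrix", SummarizedExperiment(
    assays = list(relint = values),
    rowData = DataFrame(mz = as.numeric(positions))))
}

#' Binary peak matrix
#'
#' Presence/absence form of an [AlignedPeakMatrix]: bit = 1 iff the aligned
#' relative intensity is strictly greater than the binarization threshold,
#' restricted to an m/z window.  Extends SummarizedExperiment (assay
#' `"presence"`); the window and threshold are kept in `metadata()`.
#'
#' @param positions consensus m/z (Da), all inside `window`.
#' @param labels spectrum identifiers.
#' @param bits 0/1 matrix, positions x labels.
#' @param window numeric(2) m/z window (Da).
#' @param threshold relative-intensity threshold (percent) used.
#' @return a `BinaryPeakMatrix`.
#' @export
setClass("BinaryPeakMatrix", contains = "SummarizedExperiment")

setValidity("BinaryPeakMatrix", function(object) {
  msg <- character()
  if (!"presence" %in% assayNames(object)) return("assay 'presence' missing")
  b <- assay(object, "presence")
  if (!all(b %in% c(0, 1))) msg <- c(msg, "bits must be 0 or 1")
  p <- rowData(object)$mz
  w <- metadata(object)$mzWindow
  if (is.null(p) || (length(p) > 1L && any(diff(p) <= 0)))
    msg <- c(msg, "positions must be strictly increasing")
  if (!is.null(w) && length(p) && (any(p < w[1]) || any(p > w[2])))
    msg <- c(msg, "positions outside the m/z window")
  if (length(msg)) msg else TRUE
})

#' @rdname BinaryPeakMatrix-class
#' @export
BinaryPeakMatrix <- function(positions, labels, bits, window, threshold) {
  bits <- as.matrix(bits)
  dimnames(bits) <- list(NULL, labels)
  se <- SummarizedExperiment(assays = list(presence = bits),
                             rowData = DataFrame(mz = as.numeric(positions)))
  out <- new("BinaryPeakMatrix", se)
  metadata(out)$mzWindow <- as.numeric(window)
  metadata(out)$threshold <- as.numeric(threshold)
  out
}

#' @rdname accessors
#' @export
setMethod("peakPositions", "AlignedPeakMatrix", function(x) rowData(x)$mz)
#' @rdname accessors
#' @export
setMethod("peakPositions", "BinaryPeakMatrix", function(x) rowData(x)$mz)
#' @rdname accessors
#' @export
setMethod("spectrumLabels", "AlignedPeakMatrix", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("spectrumLabels", "BinaryPeakMatrix", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("peakIntensities", "AlignedPeakMatrix", function(x) assay(x, "relint"))
#' @rdname accessors
#' @export
setMethod("peakPresence", "BinaryPeakMatrix", function(x) assay(x, "presence"))
#' @rdname accessors
#' @export
setMethod("mzWindow", "BinaryPeakMatrix", function(x) metadata(x)$mzWindow)

setMethod("show", "AlignedPeakMatrix", function(object) {
  cat(sprintf("AlignedPeakMatrix: %d consensus positions x %d spectra\n",
              nrow(object), ncol(object)))
})
setMethod("show", "BinaryPeakMatrix", function(object) {
  w <- metadata(object)$mzWindow
  cat(sprintf("BinaryPeakMatrix: %d positions x %d spectra, window %.0f-%.0f, threshold >%g%%\n",
              nrow(object), ncol(object), w[1], w[2], metadata(object)$threshold))
})

#' Binary-Pearson similarity matrix
#'
#' Symmetric strain x strain matrix of Pearson correlation coefficients
#' computed on binarized peak vectors (the phi coefficient).
#'
#' @slot values symmetric numeric matrix with unit diagonal, entries in
#'   `[-1, 1]`, dimnames = spectrum labels.
#'
#' @param values see slot.
#' @return `SimilarityMatrix()` returns a validated object.
#' @export
setClass("SimilarityMatrix", representation(values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (is.null(rownames(v)) || !identical(rownames(v), colnames(v)))
    msg <- c(msg, "dimnames must be present and identical")
  if (max(abs(v - t(v))) > 1e-12) msg <- c(msg, "matrix must be symmetric (1e-12)")
  if (max(abs(diag(v) - 1)) > 1e-12) msg <- c(msg, "diagonal must be 1")
  if (any(v < -1 - 1e-12) || any(v > 1 + 1e-12))
    msg <- c(msg, "values must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' @rdname SimilarityMatrix-class
#' @export
SimilarityMatrix <- function(values) new("SimilarityMatrix", values = values)

#' @rdname SimilarityMatrix-class
#' @param x a `SimilarityMatrix`.
#' @param ... ignored.
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)

#' @rdname accessors
#' @export
setMethod("spectrumLabels", "SimilarityMatrix", function(x) rownames(x@values))

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix: %d spectra, off-diagonal range [%.3f, %.3f]\n",
              nrow(object@values),
              min(object@values[upper.tri(object@values)]),
              max(object@values[upper.tri(object@values)])))
})

#' UPGMA dendrogram
#'
#' Group-average (UPGMA) merge tree on spectral distances `d = 1 - r`.
#' `merge` follows the [stats::hclust] convention (negative entries are
#' leaves, positive entries earlier merges); `height` holds the merge
#' heights `d/2` so that leaf-to-root depth equals half the cophenetic
#' distance, as in an ultrametric tree.
#'
#' @slot merge integer matrix (n-1) x 2.
#' @slot height numeric, non-decreasing merge heights (d/2).
#' @slot labels leaf labels.
#'
#' @param merge,height,labels see slots.
#' @return `SpectralDendrogram()` returns a validated object.
#' @seealso [upgmaTree()], [asHclust()], [writeNewickTree()]
#' @export
setClass("SpectralDendrogram",
  representation(merge = "matrix", height = "numeric", labels = "character"))

setValidity("SpectralDendrogram", function(object) {
  msg <- character()
  n <- length(object@labels)
  if (nrow(object@merge) != n - 1L) msg <- c(msg, "need n-1 merges for n leaves")
  if (length(object@height) != nrow(object@merge))
    msg <- c(msg, "one height per merge")
  if (length(object@height) > 1L && any(diff(object@height) < -1e-9))
    msg <- c(msg, "heights must be non-decreasing")
  if (length(msg)) msg else TRUE
})

#' @rdname SpectralDendrogram-class
#' @export
SpectralDendrogram <- function(merge, height, labels)
  new("SpectralDendrogram", merge = merge, height = height,
      labels = as.character(labels))

setMethod("show", "SpectralDendrogram", function(object) {
  cat(sprintf("SpectralDendrogram (UPGMA): %d leaves, root height %.4f\n",
              length(object@labels), max(object@height)))
})

#' Mantel test result
#'
#' @slot statistic Pearson correlation over the off-diagonal upper
#'   triangles of the two matrices.
#' @slot pValue one-sided permutation p-value,
#'   `(1 + #permuted r >= observed r) / (nPermutations + 1)`.
#' @slot nPermutations number of joint row/column permutations.
#' @slot seed seed used (NA if none supplied).
#'
#' @export
setClass("MantelResult",
  representation(statistic = "numeric", pValue = "numeric",
                 nPermutations = "integer", seed = "integer"))

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("Mantel test: r = %.4f, one-sided p = %.4g (%d permutations)\n",
              object@statistic, object@pValue, object@nPermutations))
})

#' Latent species fingerprint for the synthetic generator
#'
#' @slot id species identifier.
#' @slot mz latent peak masses (Da) inside the acquisition range.
#' @slot intensity latent relative peak heights in `(0, 100]`.
#'
#' @param id,mz,intensity see slots.
#' @export
setClass("SpeciesProfile",
  representation(id = "character", mz = "numeric", intensity = "numeric"))

setValidity("SpeciesProfile", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity lengths differ")
  if (anyDuplicated(object@mz)) msg <- c(msg, "latent masses must be unique")
  if (length(object@mz) &&
      (min(object@mz) < .ACQUISITION_RANGE[1] || max(object@mz) > .ACQUISITION_RANGE[2]))
    msg <- c(msg, "latent masses must lie in the 2,000-20,000 Da range")
  if (length(object@intensity) &&
      (any(object@intensity <= 0) || any(object@intensity > 100)))
    msg <- c(msg, "latent heights must lie in (0, 100]")
  if (length(msg)) msg else TRUE
})

#' @rdname SpeciesProfile-class
#' @export
SpeciesProfile <- function(id, mz, intensity) {
  o <- order(mz)
  new("SpeciesProfile", id = as.character(id), mz = as.numeric(mz)[o],
      intensity = as.numeric(intensity)[o])
}

#' @rdname accessors
#' @export
setMethod("mz", "SpeciesProfile", function(x) x@mz)
#' @rdname accessors
#' @export
setMethod("intensity", "SpeciesProfile", function(x) x@intensity)

setMethod("show", "SpeciesProfile", function(object) {
  cat(sprintf("SpeciesProfile '%s': %d latent peaks\n",
              object@id, length(object@mz)))
})

#' Replicate noise model for the synthetic generator
#'
#' Describes how a replicate spectrum deviates from its species profile:
#' Gaussian m/z calibration jitter, multiplicative lognormal intensity
#' noise, per-peak dropout, a linear baseline, Gaussian peak shape, and the
#' sampling grid.  The defaults emulate the replicate-to-replicate
#' variability seen across media and cultivation times, where intensities
#' fluctuate but peak positions are stable.
#'
#' @slot mzJitterSd SD of the per-peak m/z shift (Da).
#' @slot intensityCv coefficient of variation of the multiplicative
#'   lognormal intensity noise.
#' @slot dropoutProb probability in `[0, 1)` that a latent peak is absent
#'   from a replicate (degenerate value 1 is allowed for testing).
#' @slot baselineAmplitude baseline intensity at the low-mass edge
#'   (arbitrary units on the latent 0-100 scale).
#' @slot baselineSlope baseline change per Da.
#' @slot peakWidth Gaussian sigma of rendered peaks (Da).
#' @slot gridStep sampling step of the uniform m/z grid (Da).
#'
#' @param mzJitterSd,intensityCv,dropoutProb,baselineAmplitude,baselineSlope,peakWidth,gridStep
#'   see slots.
#' @return `noiseModel()` returns a validated `NoiseModel`.
#' @export
setClass("NoiseModel",
  representation(mzJitterSd = "numeric", intensityCv = "numeric",
                 dropoutProb = "numeric", baselineAmplitude = "numeric",
                 baselineSlope = "numeric", peakWidth = "numeric",
                 gridStep = "numeric"))

setValidity("NoiseModel", function(object) {
  msg <- character()
  nn <- c(mzJitterSd = object@mzJitterSd, intensityCv = object@intensityCv,
          baselineAmplitude = object@baselineAmplitude,
          peakWidth = object@peakWidth, gridStep = object@gridStep)
  if (any(nn < 0)) msg <- c(msg, "noise parameters must be non-negative")
  if (object@dropoutProb < 0 || object@dropoutProb > 1)
    msg <- c(msg, "dropoutProb must lie in [0, 1]")
  if (object@peakWidth <= 0 || object@gridStep <= 0)
    msg <- c(msg, "peakWidth and gridStep must be positive")
  if (length(msg)) msg else TRUE
})

#' @rdname NoiseModel-class
#' @export
noiseModel <- function(mzJitterSd = 2, intensityCv = 0.25, dropoutProb = 0.03,
                       baselineAmplitude = 5, baselineSlope = -5 / 18000,
                       peakWidth = 3, gridStep = 1) {
  new("NoiseModel", mzJitterSd = mzJitterSd, intensityCv = intensityCv,
      dropoutProb = dropoutProb, baselineAmplitude = baselineAmplitude,
      baselineSlope = baselineSlope, peakWidth = peakWidth,
      gridStep = gridStep)
}

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(paste0("NoiseModel: jitter sd %.2g Da, intensity CV %.2g, ",
                     "dropout %.2g, peak sigma %.2g Da, grid %.2g Da\n"),
              object@mzJitterSd, object@intensityCv, object@dropoutProb,
              object@peakWidth, object@gridStep))
})
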