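#' Accessor generics
#'
#' Small accessor generics shared across the spectrum and peak-matrix
#' classes: `mz()` returns mass-to-charge positions, `intensity()` the
#' matching intensities, `spectrumLabels()` the strain/replicate
#' identifiers, `processingStage()` the preprocessing state of a
#' [Spectrum], `peakPositions()` the consensus m/z positions of an aligned
#' or binarized peak matrix, `peakIntensities()`/`peakPresence()` the
#' relative-intensity and 0/1 assay matrices, and `mzWindow()` the m/z
#' window retained at binarization.
#'
#' @param x object to access.
#' @return The corresponding slot or assay; see the class documentation.
#' @name accessors
#' @examples
#' s <- Spectrum("a", mz = c(1, 2, 3), intensity = c(0, 5, 0))
#' mz(s)
#' processingStage(s)
NULL

#' @rdname accessors
#' @export
setGeneric("mz", function(x) standardGeneric("mz"))

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' @rdname accessors
#' @export
setGeneric("spectrumLabels", function(x) standardGeneric("spectrumLabels"))

#' @rdname accessors
#' @export
setGeneric("processingStage", function(x) standardGeneric("processingStage"))

#' @rdname accessors
#' @export
setGeneric("peakPositions", function(x) standardGeneric("peakPositions"))

#' @rdname accessors
#' @export
setGeneric("peakIntensities", function(x) standardGeneric("peakIntensities"))

#' @rdname accessors
#' @export
setGeneric("peakPresence", function(x) standardGeneric("peakPresence"))

#' @rdname accessors
#' @export
setGeneric("mzWindow", function(x) standardGeneric("mzWindow"))
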