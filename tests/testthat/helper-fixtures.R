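## Small in-code fixtures shared across test files.

## Gaussian peak profile on a uniform grid.
gaussianSpectrum <- function(centers, heights, width = 3, label = "toy",
                             range = c(2000, 20000), step = 1,
                             stage = "raw", offset = 0) {
  grid <- seq(range[1], range[2], by = step)
  y <- rep(offset, length(grid))
  for (i in seq_along(centers))
    y <- y + heights[i] * exp(-(grid - centers[i])^2 / (2 * width^2))
  Spectrum(label, grid, y, stage = stage)
}

## Run the in-memory fingerprinting chain: preprocess -> (average) ->
## peaks -> align -> binarize.
bitsFromSpectra <- function(spectra, groups = NULL,
                            config = preprocessConfig(), maxShift = 20,
                            threshold = 5, window = c(3500, 20000)) {
  rel <- lapply(spectra, preprocessSpectrum, config = config)
  strains <- if (is.null(groups)) rel else {
    out <- lapply(names(groups), function(g)
      toRelative(averageSpectra(rel[groups[[g]]], label = g)))
    names(out) <- names(groups)
    out
  }
  pls <- lapply(strains, pickPeaks)
  binarizePeaks(alignPeaks(unname(pls), maxShift = maxShift),
                threshold = threshold, window = window)
}

## Random symmetric similarity-like matrix with unit diagonal.
randomSymmetricMatrix <- function(n, labels = sprintf("s%d", seq_len(n))) {
  m <- matrix(stats::runif(n * n), n, n, dimnames = list(labels, labels))
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}
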