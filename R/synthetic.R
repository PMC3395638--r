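#' Generate latent species fingerprints
#'
#' Draws per-species sets of latent peak masses and heights emulating a
#' multi-strain spectral library.  Masses are uniform over the
#' acquisition range with a minimum separation both within and between
#' species (default 50 Da, comfortably above the matching radius), so
#' unrelated species share no alignable peaks.  Heights are log-uniform
#' over 5-100% so that some peaks sit near the binarization threshold.
#' Optional sibling pairs -- species (1,2), (3,4), ... -- share exactly
#' `round(f * nPeaks)` latent masses (with identical heights, as for a
#' conserved protein), emulating pairs of closely related species whose
#' spectra overlap.
#'
#' @param nSpecies number of species.
#' @param nPeaks latent peaks per species (>= 5).
#' @param sharedFractions numeric vector of shared-peak fractions in
#'   `[0, 1)`; entry `k` makes species `2k-1` and `2k` siblings.
#' @param seed optional integer seed (caller's RNG untouched).
#' @param mzRange acquisition range, Da.
#' @param minSeparation minimum distance between distinct latent masses, Da.
#' @return list of [SpeciesProfile] objects (`sp1`, `sp2`, ...), with the
#'   sibling pairing in `attr(x, "siblings")`.
#' @export
makeSpeciesProfiles <- function(nSpecies, nPeaks = 30,
                                sharedFractions = numeric(0), seed = NULL,
                                mzRange = c(2000, 20000),
                                minSeparation = 50) {
  if (nPeaks < 5) stop("nPeaks must be >= 5")
  if (length(sharedFractions) &&
      (any(sharedFractions < 0) || any(sharedFractions >= 1)))
    stop("shared fractions must lie in [0, 1)")
  if (2 * length(sharedFractions) > nSpecies)
    stop("more sibling pairs than species")
  total <- nSpecies * nPeaks
  if (total * minSeparation > 0.8 * diff(mzRange))
    stop("infeasible separation constraints: ", total, " masses at ",
         minSeparation, " Da minimum separation do not fit in the range")

  withLocalSeed(seed, {
    used <- numeric(0)
    drawMasses <- function(k) {
      out <- numeric(0)
      tries <- 0L
      while (length(out) < k) {
        tries <- tries + 1L
        if (tries > 10000L * k)
          stop("infeasible separation constraints")
        cand <- stats::runif(1, mzRange[1] + minSeparation,
                             mzRange[2] - minSeparation)
        if (!length(used) || min(abs(used - cand)) >= minSeparation) {
          out <- c(out, cand)
          used <<- c(used, cand)
        }
      }
      out
    }
    drawHeights <- function(k) exp(stats::runif(k, log(5), log(100)))

    profiles <- vector("list", nSpecies)
    sib <- integer(0)
    for (k in seq_along(sharedFractions)) {
      i <- 2L * k - 1L; j <- 2L * k
      nShared <- round(sharedFractions[k] * nPeaks)
      sharedMz <- drawMasses(nShared)
      sharedH <- drawHeights(nShared)
      ownI <- drawMasses(nPeaks - nShared)
      ownJ <- drawMasses(nPeaks - nShared)
      profiles[[i]] <- SpeciesProfile(sprintf("sp%d", i),
                                      c(sharedMz, ownI),
                                      c(sharedH, drawHeights(nPeaks - nShared)))
      profiles[[j]] <- SpeciesProfile(sprintf("sp%d", j),
                                      c(sharedMz, ownJ),
                                      c(sharedH, drawHeights(nPeaks - nShared)))
      sib <- c(sib, i, j)
    }
    for (i in setdiff(seq_len(nSpecies), sib))
      profiles[[i]] <- SpeciesProfile(sprintf("sp%d", i),
                                      drawMasses(nPeaks), drawHeights(nPeaks))
    names(profiles) <- vapply(profiles, function(p) p@id, character(1))
    attr(profiles, "siblings") <-
      if (length(sharedFractions))
        data.frame(a = sprintf("sp%d", seq(1, by = 2,
                                           length.out = length(sharedFractions))),
                   b = sprintf("sp%d", seq(2, by = 2,
                                           length.out = length(sharedFractions))),
                   shared_fraction = sharedFractions)
      else data.frame(a = character(0), b = character(0),
                      shared_fraction = numeric(0))
    profiles
  })
}

#' Render one replicate spectrum from a species profile
#'
#' Sum of Gaussian peaks at jittered latent masses with multiplicative
#' lognormal height noise and per-peak dropout, on a uniform m/z grid,
#' plus a linear baseline clipped at zero.  Stage is `"raw"`.
#'
#' @param profile a [SpeciesProfile].
#' @param noise a [noiseModel()].
#' @param label spectrum label (defaults to the species id).
#' @param seed optional integer seed.
#' @param mzRange acquisition range, Da.
#' @return a raw [Spectrum].
#' @export
renderReplicate <- function(profile, noise = noiseModel(), label = NULL,
                            seed = NULL, mzRange = c(2000, 20000)) {
  stopifnot(is(profile, "SpeciesProfile"), is(noise, "NoiseModel"))
  if (is.null(label)) label <- profile@id
  grid <- seq(mzRange[1], mzRange[2], by = noise@gridStep)
  withLocalSeed(seed, {
    k <- length(profile@mz)
    keep <- stats::runif(k) >= noise@dropoutProb
    y <- numeric(length(grid))
    if (any(keep)) {
      centers <- profile@mz[keep] +
        stats::rnorm(sum(keep), sd = noise@mzJitterSd)
      sdlog <- sqrt(log(1 + noise@intensityCv^2))
      heights <- profile@intensity[keep] *
        exp(stats::rnorm(sum(keep), sd = sdlog))
      w <- noise@peakWidth
      for (i in seq_along(centers)) {
        lo <- max(1L, ceiling((centers[i] - 6 * w - mzRange[1]) /
                                noise@gridStep) + 1L)
        hi <- min(length(grid), floor((centers[i] + 6 * w - mzRange[1]) /
                                        noise@gridStep) + 1L)
        if (lo > hi) next
        idx <- lo:hi
        y[idx] <- y[idx] +
          heights[i] * exp(-(grid[idx] - centers[i])^2 / (2 * w^2))
      }
    }
    baseline <- pmax(noise@baselineAmplitude +
                       noise@baselineSlope * (grid - mzRange[1]), 0)
    Spectrum(label, grid, y + baseline, stage = "raw")
  })
}

#' Simulate a multi-species spectral library
#'
#' Convenience driver: draws species profiles, renders `nReplicates`
#' spectra per species, and optionally writes everything (spectrum text
#' files with provenance headers, truth table, latent profiles) to a
#' directory.
#'
#' @param nSpecies,nReplicates library dimensions.
#' @param nPeaks latent peaks per species.
#' @param sharedFractions sibling-pair shared fractions, see
#'   [makeSpeciesProfiles()].
#' @param noise a [noiseModel()].
#' @param seed optional integer seed governing profiles and replicates.
#' @param outdir optional output directory.
#' @return a list with `profiles`, `spectra` (list of raw [Spectrum],
#'   labelled `sp<i>_r<j>`), and `truth` (`data.frame` label/species).
#' @export
simulateLibrary <- function(nSpecies = 5, nReplicates = 4, nPeaks = 30,
                            sharedFractions = numeric(0),
                            noise = noiseModel(), seed = NULL,
                            outdir = NULL) {
  withLocalSeed(seed, {
    profiles <- makeSpeciesProfiles(nSpecies, nPeaks, sharedFractions)
    spectra <- list()
    for (p in profiles) {
      for (r in seq_len(nReplicates)) {
        lab <- sprintf("%s_r%d", p@id, r)
        spectra[[lab]] <- renderReplicate(p, noise, label = lab)
      }
    }
    truth <- data.frame(
      label = names(spectra),
      species = sub("_r\\d+$", "", names(spectra)),
      stringsAsFactors = FALSE)
    if (!is.null(outdir)) {
      dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
      prov <- c(sprintf("seed: %s", if (is.null(seed)) "NA" else seed),
                sprintf("nSpecies: %d, nReplicates: %d, nPeaks: %d",
                        nSpecies, nReplicates, nPeaks),
                sprintf("noise: jitter %.3g Da, cv %.3g, dropout %.3g",
                        noise@mzJitterSd, noise@intensityCv,
                        noise@dropoutProb))
      for (lab in names(spectra))
        writeSpectrum(spectra[[lab]],
                      file.path(outdir, paste0(lab, ".txt")), headers = prov)
      utils::write.csv(truth, file.path(outdir, "truth.csv"),
                       row.names = FALSE)
      latent <- do.call(rbind, lapply(profiles, function(p)
        data.frame(species = p@id, mz = p@mz, intensity = p@intensity)))
      utils::write.csv(latent, file.path(outdir, "latent_profiles.csv"),
                       row.names = FALSE)
    }
    list(profiles = profiles, spectra = spectra, truth = truth)
  })
}

#' Correlated 16S-like similarity table
#'
#' Maps the latent peak-sharing structure of a profile set to a 16S-like
#' percent-identity matrix: similarity = 97 + 3 * Jaccard(latent mass
#' sets) plus optional symmetric Gaussian noise, clamped to
#' \[90, 100\], diagonal 100.  With zero noise the matrix is a monotone
#' (affine) transform of peak sharing, so a Mantel test against the
#' spectral similarity structure is perfectly correlated by construction.
#'
#' @param profiles list of [SpeciesProfile] (>= 3).
#' @param noiseSd SD of the added similarity noise (percentage points).
#' @param seed optional integer seed.
#' @return symmetric numeric matrix with species ids as dimnames.
#' @export
makeCorrelated16S <- function(profiles, noiseSd = 0.2, seed = NULL) {
  if (length(profiles) < 3L) stop("need at least 3 species")
  ids <- vapply(profiles, function(p) p@id, character(1))
  n <- length(profiles)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  withLocalSeed(seed, {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        a <- profiles[[i]]@mz; b <- profiles[[j]]@mz
        jac <- length(intersect(a, b)) / length(union(a, b))
        s <- 97 + 3 * jac + if (noiseSd > 0) stats::rnorm(1, sd = noiseSd) else 0
        m[i, j] <- m[j, i] <- min(max(s, 90), 100)
      }
    }
    m
  })
}
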