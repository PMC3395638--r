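test_that("preprocess configuration is validated", {
  expect_error(preprocessConfig(sgWindow = 6), "odd")
  expect_error(preprocessConfig(sgWindow = 3, sgPolyorder = 3), "odd")
  expect_error(preprocessConfig(sgCycles = -1), "sgCycles")
  expect_error(preprocessConfig(baselineHalfwidth = 0), "positive")
  expect_identical(preprocessConfig()$sgCycles, 3L)
})

test_that("Savitzky-Golay preserves constants and interior ramps", {
  s <- Spectrum("c", 1:50 + 2000, rep(7, 50))
  expect_equal(intensity(smoothSpectrum(s)), rep(7, 50))

  ramp <- Spectrum("r", 1:50 + 2000, seq(0, 98, by = 2))
  sm <- smoothSpectrum(ramp, preprocessConfig(sgWindow = 7, sgPolyorder = 2,
                                              sgCycles = 1))
  expect_equal(intensity(sm)[4:47], intensity(ramp)[4:47], tolerance = 1e-10)
})

test_that("one smoothing cycle equals the sliding least-squares oracle", {
  set.seed(11)
  y <- runif(80)
  s <- Spectrum("x", seq_len(80) + 3000, y)
  sm <- smoothSpectrum(s, preprocessConfig(sgWindow = 5, sgPolyorder = 2,
                                           sgCycles = 1))
  expect_equal(intensity(sm), pmax(sgOracle(y, 5, 2), 0), tolerance = 1e-9)
  expect_identical(processingStage(sm), "smoothed")
})

test_that("smoothing window larger than the spectrum is an error", {
  s <- Spectrum("tiny", 2000:2004, rep(1, 5))
  expect_error(smoothSpectrum(s, preprocessConfig(sgWindow = 7)), "larger")
})

test_that("top-hat baseline keeps narrow peaks and removes smooth drift", {
  ## isolated narrow peaks on zero baseline: unchanged
  pk <- gaussianSpectrum(c(5000, 9000), c(100, 40), width = 3,
                         range = c(4000, 10000), stage = "smoothed")
  bl <- subtractBaseline(pk, preprocessConfig(baselineHalfwidth = 50))
  expect_equal(intensity(bl), intensity(pk), tolerance = 1e-9)
  expect_identical(processingStage(bl), "baselined")

  ## pure linear drift: removed to within 1% of the drift range
  grid <- seq(2000, 20000, by = 1)
  drift <- Spectrum("d", grid, seq(0, 90, length.out = length(grid)),
                    stage = "smoothed")
  out <- subtractBaseline(drift, preprocessConfig(baselineHalfwidth = 50))
  expect_lt(max(intensity(out)), 0.01 * 90)

  ## peak 100 on constant offset 20: apex restored to 100
  toy <- gaussianSpectrum(6000, 100, width = 3, range = c(5500, 6500),
                          stage = "smoothed", offset = 20)
  sub <- subtractBaseline(toy, preprocessConfig(baselineHalfwidth = 50))
  expect_equal(max(intensity(sub)), 100, tolerance = 1e-6)
  ## and matches the explicit double-loop opening oracle
  expect_equal(intensity(sub), tophatOracle(intensity(toy), 50),
               tolerance = 1e-12)
})

test_that("baseline method 'none' passes intensities through", {
  s <- Spectrum("n", 2000:2010, c(0:5, 4:0), stage = "smoothed")
  cfg <- preprocessConfig(baselineMethod = "none")
  expect_equal(intensity(subtractBaseline(s, cfg)), intensity(s))
})

test_that("relative scaling normalizes to base peak 100 and is idempotent", {
  s <- Spectrum("r", 2000:2002, c(2, 8, 4), stage = "baselined")
  r1 <- toRelative(s)
  expect_equal(intensity(r1), c(25, 100, 50))
  expect_identical(processingStage(r1), "relative")
  expect_equal(intensity(toRelative(r1)), intensity(r1))

  z <- toRelative(Spectrum("z", 2000:2002, c(0, 0, 0), stage = "baselined"))
  expect_equal(intensity(z), c(0, 0, 0))
  expect_true(z@metadata$empty)
})

test_that("stage contracts are enforced along the chain", {
  raw <- Spectrum("x", 2000:2010, rep(1, 11))
  expect_error(toRelative(raw), "stage")
  rel <- toRelative(Spectrum("x", 2000:2010, c(rep(1, 10), 2),
                             stage = "baselined"))
  expect_error(smoothSpectrum(rel), "stage")
  expect_error(pickPeaks(raw), "relative")
})

test_that("averaging replicates is the pointwise mean", {
  a <- toRelative(Spectrum("a", 2000:2001, c(0, 100), stage = "baselined"))
  b <- toRelative(Spectrum("b", 2000:2001, c(100, 0), stage = "baselined"))
  avg <- averageSpectra(list(a, b))
  expect_equal(intensity(avg), c(50, 50))
  expect_identical(avg@metadata$members, c("a", "b"))

  expect_equal(intensity(averageSpectra(list(a, a))), intensity(a))
  expect_error(averageSpectra(list()), "empty")
  expect_error(averageSpectra(list(a, Spectrum("r", 2000:2001, c(1, 2)))),
               "relative")
})

test_that("mixed grids are resampled to the coarsest common grid", {
  a <- toRelative(Spectrum("a", seq(2000, 2010, by = 1),
                           c(0:5, 4:0) * 20, stage = "baselined"))
  b <- toRelative(Spectrum("b", seq(2000, 2010, by = 2),
                           c(0, 2, 5, 3, 1, 0) * 20, stage = "baselined"))
  expect_error(averageSpectra(list(a, b), resample = FALSE), "mixed")
  avg <- averageSpectra(list(a, b))
  expect_equal(stats::median(diff(mz(avg))), 2)
  expect_true(all(intensity(avg) >= 0))
})

test_that("averaging 5 jittered replicates beats the best single replicate", {
  ## variance-reduction property, 20 seeded rounds
  profile <- makeSpeciesProfiles(1, nPeaks = 20, seed = 99)[[1]]
  template <- renderReplicate(profile,
    noiseModel(mzJitterSd = 0, intensityCv = 0, dropoutProb = 0,
               baselineAmplitude = 0))
  tmpl <- intensity(toRelative(subtractBaseline(template,
    preprocessConfig(baselineMethod = "none"))))
  noisy <- noiseModel(mzJitterSd = 0.5, intensityCv = 0.4, dropoutProb = 0,
                      baselineAmplitude = 0)
  rmsAvg <- rmsBest <- numeric(20)
  for (i in 1:20) {
    reps <- lapply(1:5, function(r)
      toRelative(subtractBaseline(
        renderReplicate(profile, noisy, label = sprintf("r%d", r),
                        seed = 1000 * i + r),
        preprocessConfig(baselineMethod = "none"))))
    avg <- averageSpectra(reps)
    rmsAvg[i] <- sqrt(mean((intensity(avg) - tmpl)^2))
    rmsBest[i] <- min(vapply(reps, function(s)
      sqrt(mean((intensity(s) - tmpl)^2)), numeric(1)))
  }
  expect_lt(mean(rmsAvg), mean(rmsBest))
})

test_that("preprocessing is deterministic and non-negative at every stage", {
  set.seed(5)
  profile <- makeSpeciesProfiles(1, nPeaks = 15, seed = 5)[[1]]
  raw <- renderReplicate(profile, seed = 6)
  cfg <- preprocessConfig()
  s1 <- preprocessSpectrum(raw, cfg)
  s2 <- preprocessSpectrum(raw, cfg)
  expect_identical(intensity(s1), intensity(s2))
  sm <- smoothSpectrum(raw, cfg)
  bl <- subtractBaseline(sm, cfg)
  for (s in list(sm, bl, s1)) expect_true(all(intensity(s) >= 0))
})

test_that("smoothing moves synthetic Gaussian apexes by less than one step", {
  profile <- makeSpeciesProfiles(1, nPeaks = 12, seed = 21)[[1]]
  raw <- renderReplicate(profile,
    noiseModel(mzJitterSd = 0, intensityCv = 0, dropoutProb = 0,
               baselineAmplitude = 0, peakWidth = 3))
  rel0 <- toRelative(subtractBaseline(raw,
    preprocessConfig(baselineMethod = "none")))
  rel1 <- preprocessSpectrum(raw)
  p0 <- mz(pickPeaks(rel0))
  p1 <- mz(pickPeaks(rel1))
  expect_equal(length(p0), length(p1))
  expect_true(all(abs(p0 - p1) <= 1))
})
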