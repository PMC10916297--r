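test_that("a config with no background, no peaks and no noise yields an all-zero frame", {
  cfg <- frameSimConfig(geometry = smallGeometry(32L), bgAmplitude = 0,
                        bgFloor = 0, nPeaks = 0L, seed = 1)
  sim <- simulateFrame(cfg, 0, forceHit = TRUE)
  expect_true(all(sim$frame@values == 0L))
  expect_equal(nPeaks(sim$truthPeaks), 0L)
})

test_that("flat Poisson background reproduces its mean (law of large numbers)", {
  cfg <- frameSimConfig(geometry = geometryModel(512, 512, 200e-6, 0.08),
                        bgAmplitude = 0, bgFloor = 5, nPeaks = 0L, seed = 11)
  sim <- simulateFrame(cfg, 0, forceHit = FALSE)
  expect_lt(abs(mean(sim$frame@values) - 5), 0.05)
})

test_that("forced hits carry exactly nPeaks truth peaks honoring the separation constraint", {
  cfg <- frameSimConfig(geometry = smallGeometry(128L), nPeaks = 40L,
                        minPeakSeparation = 8, seed = 3)
  sim <- simulateFrame(cfg, 0, forceHit = TRUE)
  tt <- peakTable(sim$truthPeaks)
  expect_equal(nrow(tt), 40L)
  d <- as.matrix(dist(tt[, c("fastPos", "slowPos")]))
  diag(d) <- Inf
  expect_true(all(d >= 8))
  # positions inside the panel, 1/d below the geometric corner maximum
  expect_true(all(tt$fastPos > -0.5 & tt$fastPos < 127.5))
  expect_true(all(tt$invD <= maxInvD(cfg@geometry)))
})

test_that("impossible peak packing fails with an error naming the separation constraint", {
  cfg <- frameSimConfig(geometry = smallGeometry(32L), nPeaks = 40L,
                        minPeakSeparation = 20, seed = 1)
  expect_error(simulateFrame(cfg, 0, forceHit = TRUE), "separation")
})

test_that("frames are deterministic in (seed, frameId) and differ across frames", {
  cfg <- frameSimConfig(geometry = smallGeometry(32L), nPeaks = 5L, seed = 9)
  a <- simulateFrame(cfg, 4, forceHit = TRUE)
  b <- simulateFrame(cfg, 4, forceHit = TRUE)
  expect_identical(a$frame@values, b$frame@values)
  expect_identical(peakTable(a$truthPeaks), peakTable(b$truthPeaks))
  expect_false(identical(a$frame@values,
                         simulateFrame(cfg, 5, forceHit = TRUE)$frame@values))
  # same-seed datasets are bit-identical
  s1 <- simulateDataset(cfg, 6)
  s2 <- simulateDataset(cfg, 6)
  expect_identical(s1$stack@values, s2$stack@values)
  expect_identical(s1$truth, s2$truth)
})

test_that("a hit frame never has fewer photons than its non-hit twin", {
  cfg <- frameSimConfig(geometry = smallGeometry(48L), nPeaks = 10L, seed = 21)
  for (id in 0:4) {
    h <- simulateFrame(cfg, id, forceHit = TRUE)
    n <- simulateFrame(cfg, id, forceHit = FALSE)
    expect_true(all(h$frame@values - n$frame@values >= 0L))
  }
})

test_that("hit flags follow the configured hit rate", {
  base <- frameSimConfig(geometry = smallGeometry(16L), nPeaks = 2L,
                         minPeakSeparation = 1, seed = 5)
  cfg0 <- base; cfg0@hitRate <- 0
  cfg1 <- base; cfg1@hitRate <- 1
  expect_equal(sum(simulateDataset(cfg0, 30)$truth$isHit), 0L)
  expect_equal(sum(simulateDataset(cfg1, 30)$truth$isHit), 30L)
  cfg <- base; cfg@hitRate <- 0.3
  frac <- mean(simulateDataset(cfg, 2000)$truth$isHit)
  expect_lt(abs(frac - 0.3), 0.03)
})

test_that("integrating mode applies gain, offset and readout noise", {
  cfg <- frameSimConfig(geometry = smallGeometry(64L), bgAmplitude = 0,
                        bgFloor = 10, nPeaks = 0L,
                        detectorKind = "integrating", gain = 73.14,
                        offset = -50, readoutSigma = 3, seed = 2)
  sim <- simulateFrame(cfg, 0, forceHit = FALSE)
  expect_equal(sim$frame@valueKind, "adu_real")
  # mean ~ 10 photons * gain + offset
  expect_lt(abs(mean(sim$frame@values) - (10 * 73.14 - 50)), 5)
  expect_true(any(sim$frame@values != round(sim$frame@values)))
})

test_that("noiseless observations equal their per-reflection truth", {
  cfg <- obsSimConfig(nUniqueHkl = 100L, meanMultiplicity = 4,
                      scaleJitterSd = 0, noiseSigma0 = 0, noiseFrac = 0,
                      seed = 7)
  obs <- simulateObservations(cfg)
  o <- observations(obs)
  key <- paste(o$h, o$k, o$l)
  tkey <- paste(obs@truth$h, obs@truth$k, obs@truth$l)
  expect_equal(o$intensity, obs@truth$iTrue[match(key, tkey)], tolerance = 1e-12)
})

test_that("total observation count follows the multiplicity model", {
  obs <- simulateObservations(obsSimConfig(nUniqueHkl = 500L,
                                           meanMultiplicity = 8, seed = 13))
  expect_lt(abs(nObservations(obs) - 4000), 200)
})

test_that("Bijvoet differences vanish without anomalous signal and appear with it", {
  noAno <- simulateObservations(obsSimConfig(nUniqueHkl = 300L,
                                             meanMultiplicity = 12,
                                             scaleJitterSd = 0.05,
                                             anomalousFraction = 0, seed = 3))
  m <- mergedTable(mergeObservations(noAno, byFriedel = TRUE))
  plus <- m[m$friedelSign == 1L, ]; minus <- m[m$friedelSign == -1L, ]
  key <- function(d) paste(d$h, d$k, d$l)
  common <- intersect(key(plus), key(minus))
  dI <- plus$intensity[match(common, key(plus))] -
        minus$intensity[match(common, key(minus))]
  iBar <- (plus$intensity[match(common, key(plus))] +
           minus$intensity[match(common, key(minus))]) / 2
  expect_lt(abs(mean(dI / pmax(iBar, 1))), 0.05)

  # noiseless anomalous data: |I+ - I-| / Imean = anomalousFraction exactly
  ano <- simulateObservations(obsSimConfig(nUniqueHkl = 100L,
                                           meanMultiplicity = 6,
                                           scaleJitterSd = 0, noiseSigma0 = 0,
                                           noiseFrac = 0,
                                           anomalousFraction = 0.2, seed = 4))
  ma <- mergedTable(mergeObservations(ano, byFriedel = TRUE))
  plus <- ma[ma$friedelSign == 1L, ]; minus <- ma[ma$friedelSign == -1L, ]
  common <- intersect(key(plus), key(minus))
  rel <- abs(plus$intensity[match(common, key(plus))] -
             minus$intensity[match(common, key(minus))]) /
         ((plus$intensity[match(common, key(plus))] +
           minus$intensity[match(common, key(minus))]) / 2)
  expect_equal(unname(rel), rep(0.2, length(common)), tolerance = 1e-9)
})

test_that("invalid configurations are rejected", {
  expect_error(frameSimConfig(hitRate = 1.5), "hitRate")
  expect_error(frameSimConfig(minPeakSeparation = 0.5), "minPeakSeparation")
  expect_error(frameSimConfig(detectorKind = "integrating", gain = 0), "gain")
  expect_error(obsSimConfig(dMin = 20, dMax = 2), "dMin < dMax")
  expect_error(obsSimConfig(scaleJitterSd = -1), "scaleJitterSd")
})
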