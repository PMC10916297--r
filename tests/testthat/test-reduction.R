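test_that("binning sums b x b blocks and conserves total intensity", {
  f <- detectorFrame(matrix(1L, 4, 4))
  b <- binFrame(f, 2)
  expect_equal(b@values, matrix(4L, 2, 2))
  expect_equal(sum(b@values), 16L)
  expect_equal(binFrame(detectorFrame(matrix(c(1L, 3L, 2L, 4L), 2, 2),
                                      valueKind = "adu_integer"), 2)@values,
               matrix(10L, 1, 1))
  # conservation on random frames
  set.seed(99)
  for (i in 1:25) {
    v <- matrix(rpois(16 * 16, 20), 16, 16)
    expect_identical(sum(binFrame(detectorFrame(v), 2)@values), sum(v))
    expect_identical(sum(binFrame(detectorFrame(v), 4)@values), sum(v))
  }
})

test_that("binning masks any output pixel with a masked contributor and drops trailing pixels", {
  v <- matrix(1L, 4, 4)
  mask <- matrix(TRUE, 4, 4); mask[1, 2] <- FALSE
  b <- binFrame(detectorFrame(v, mask = mask), 2)
  expect_identical(b@mask, matrix(c(FALSE, TRUE, TRUE, TRUE), 2, 2))
  expect_warning(b5 <- binFrame(detectorFrame(matrix(1L, 5, 7)), 2), "trailing")
  expect_equal(dim(b5@values), c(2L, 3L))
  expect_error(binFrame(detectorFrame(matrix(1L, 4, 4)), 1), "factor")
  expect_error(binFrame(detectorFrame(matrix(1L, 4, 4)), 5), "factor")
})

test_that("peak remapping follows the pixel-center convention and is invertible", {
  pk <- peakList(data.frame(fastPos = 5, slowPos = 3, intensity = 7,
                            invD = 0.3))
  r <- peakTable(remapPeaks(pk, 2))
  expect_equal(r$fastPos, 2.25)
  expect_equal(r$slowPos, 1.25)
  expect_equal(r$intensity, 7)   # intensities and 1/d unchanged
  expect_equal(r$invD, 0.3)
  # the panel corner is the fixed point of the map
  corner <- peakList(data.frame(fastPos = -0.5, slowPos = -0.5, intensity = 1))
  for (b in c(2, 3, 4))
    expect_equal(peakTable(remapPeaks(corner, b))$fastPos, -0.5)
  # remap then un-map recovers the original to machine precision
  set.seed(12)
  pks <- peakList(data.frame(fastPos = runif(50, 0, 127),
                             slowPos = runif(50, 0, 127),
                             intensity = runif(50, 1, 100)))
  for (b in c(2, 3, 8)) {
    back <- remapPeaks(remapPeaks(pks, b), b, inverse = TRUE)
    expect_equal(peakTable(back)$fastPos, peakTable(pks)$fastPos,
                 tolerance = 1e-12)
    expect_equal(peakTable(back)$slowPos, peakTable(pks)$slowPos,
                 tolerance = 1e-12)
  }
})

test_that("peak-only retention keeps windows around peaks and masks the rest", {
  f <- detectorFrame(matrix(7L, 32, 32))
  allMasked <- peakOnlyMask(f, peakList(), radius = 3)
  expect_true(all(!allMasked@mask))
  expect_true(all(allMasked@values == 0L))
  one <- peakOnlyMask(f, peakList(data.frame(fastPos = 15, slowPos = 15,
                                             intensity = 1)), radius = 3)
  expect_equal(sum(one@mask), 49L)  # one 7x7 Chebyshev window
  expect_equal(sum(one@values), 49L * 7L)
})

test_that("peak-only frames compress to fewer stored bytes than full frames", {
  cfg <- frameSimConfig(geometry = smallGeometry(64L), nPeaks = 10L,
                        peakMeanIntensity = 600, minPeakSeparation = 6,
                        seed = 23)
  sim <- simulateFrame(cfg, 0, forceHit = TRUE)
  masked <- peakOnlyMask(sim$frame, sim$truthPeaks, radius = 3)
  toStack <- function(fr) frameStack(array(fr@values, c(64, 64, 1)),
                                     valueKind = fr@valueKind)
  full <- codecSurvey(toStack(sim$frame), list(codecSpec("gzip")))
  po <- codecSurvey(toStack(masked), list(codecSpec("gzip")))
  expect_lt(po$storedBytes, full$storedBytes)
})

test_that("uniform quantization rounds to the nearest step with ties away from zero", {
  expect_equal(quantizeUniform(0, 1024), 0)
  expect_equal(quantizeUniform(1500, 1024), 1024)
  expect_equal(quantizeUniform(1536, 1024), 2048)   # tie -> away from zero
  expect_equal(quantizeUniform(-600, 1024), -1024)
  expect_equal(quantizeUniform(-1536, 1024), -2048)
  x <- c(-5000:5000) * 0.37
  q <- quantizeUniform(x, 64)
  expect_true(all(q %% 64 == 0))
  expect_true(all(abs(q - x) <= 32))
  expect_equal(quantizeUniform(q, 64), q)  # idempotent
})

test_that("ADU-to-photon conversion matches the detector gain model", {
  expect_equal(aduToPhotons(1024, gain = 73.14), 14)  # ~14 photons at 9 keV
  expect_equal(aduToPhotons(100, gain = 50, offset = 100), 0)
  expect_equal(aduToPhotons(100 + 2.49 * 50, gain = 50, offset = 100), 2)
  expect_equal(aduToPhotons(-300, gain = 73.14), -4)  # negatives permitted
  f <- detectorFrame(matrix(c(-100, 0, 73.14, 1024), 2, 2),
                     valueKind = "adu_real")
  ph <- aduToPhotons(f, 73.14)
  expect_equal(ph@valueKind, "adu_integer")
  expect_identical(ph@values, matrix(c(-1L, 0L, 1L, 14L), 2, 2))
  # counting-detector frames already hold photons; converting them is an error
  expect_error(aduToPhotons(detectorFrame(matrix(3L, 2, 2)), 73.14), "already")
  # integer input with unit gain is a fixed point
  expect_equal(aduToPhotons(-20:20, gain = 1), -20:20)
})

test_that("MSB rounding hits the documented examples and rejects bad input", {
  expect_equal(msbRound(13, 1), 16)  # R_1 neighbors 8/16, distances 5 vs 3
  expect_equal(msbRound(13, 2), 12)  # R_2 neighbors 12/16, distances 1 vs 3
  expect_equal(msbRound(13, 3), 14)  # tie 12/14 -> away from zero
  expect_equal(msbRound(13, 1, truncate = TRUE), 8)  # keep MSB, zero the rest
  expect_equal(msbRound(-13, 3), -14)  # magnitude quantized, sign restored
  expect_equal(msbRound(0:7, 3), 0:7)  # small integers exactly representable
  expect_error(msbRound(13, 4), "keepBits")
  expect_error(msbRound(13.5, 2), "integer")
})

test_that("MSB rounding is idempotent with bounded relative error", {
  set.seed(4)
  x <- c(-1, 1, sample(-1e6:1e6, 3000))
  for (k in 1:3) {
    q <- msbRound(x, k)
    expect_identical(msbRound(q, k), q)
    nz <- x != 0
    expect_true(all(abs(q[nz] - x[nz]) <= 2^(-k) * abs(x[nz])))
  }
})

test_that("8-bit minifloat encoding matches its stated format", {
  enc <- toMinifloat8(c(0, 13, 200000, -5))
  expect_equal(enc$quantized, c(0, 14, 114688, -5))
  expect_identical(enc$codes[1], as.raw(0))
  expect_equal(length(enc$decodeMap), 256L)
  # decode(encode()) is idempotent
  set.seed(8)
  x <- sample(-70000:70000, 2000)
  q <- toMinifloat8(x)$quantized
  expect_equal(toMinifloat8(q)$quantized, q)
  # round-trip through raw codes
  expect_equal(fromMinifloat8(toMinifloat8(x)$codes), q)
  expect_error(toMinifloat8(2.5), "integer")
})

test_that("quantizer dispatch through QuantizationSpec matches direct calls", {
  x <- c(-900, 0, 13, 1536, 5000)
  expect_equal(applyQuantizer(x, quantizationSpec("uniform", step = 1024)),
               quantizeUniform(x, 1024))
  expect_equal(applyQuantizer(x, quantizationSpec("msb", keepBits = 2)),
               msbRound(x, 2))
  expect_equal(applyQuantizer(x, quantizationSpec("minifloat8")),
               toMinifloat8(x)$quantized)
  expect_equal(applyQuantizer(x, quantizationSpec("photon", gain = 73.14)),
               aduToPhotons(x, 73.14))
  expect_error(applyQuantizer(x, quantizationSpec("msb", keepBits = 5)),
               "keepBits")
})

test_that("vetoing retains exactly the hits, bit-identically", {
  base <- frameSimConfig(geometry = smallGeometry(48L), nPeaks = 15L,
                         peakMeanIntensity = 900, minPeakSeparation = 5,
                         seed = 77)
  cfg0 <- base; cfg0@hitRate <- 0
  sim0 <- simulateDataset(cfg0, 10)
  v0 <- vetoNonHits(sim0$stack, base@geometry, minPeaks = 8L)
  expect_equal(nFrames(v0$stack), 0L)
  expect_equal(v0$report@framesIn, 10L)
  cfg1 <- base; cfg1@hitRate <- 1
  sim1 <- simulateDataset(cfg1, 10)
  v1 <- vetoNonHits(sim1$stack, base@geometry, minPeaks = 8L)
  expect_equal(nFrames(v1$stack), 10L)
  expect_identical(v1$stack@values, sim1$stack@values)  # raw retention
  expect_equal(v1$report@maxAbsError, 0)
})
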