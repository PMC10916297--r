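# Hand-built observation/merged fixtures
obsFixture <- function(patterns = 1:4, nHkl = 6, noise = 0, seed = 1) {
  set.seed(seed)
  rows <- expand.grid(hkl = seq_len(nHkl), patternId = patterns)
  iTrue <- 100 * rows$hkl
  data.frame(h = rows$hkl, k = 0L, l = 0L, friedelSign = 1L,
             intensity = iTrue + rnorm(nrow(rows), 0, noise),
             sigma = pmax(noise, 1), patternId = rows$patternId,
             invD = 0.1 + 0.05 * rows$hkl)
}

mergedFixture <- function(I, invD = seq(0.1, 0.5, length.out = length(I))) {
  new("MergedTable",
      merged = data.frame(h = seq_along(I), k = 0L, l = 0L, friedelSign = 0L,
                          intensity = I, sigma = 1,
                          multiplicity = 2L, invD = invD))
}

test_that("split-half assigns patterns by rank parity, deterministically", {
  obs <- observationTable(obsFixture(patterns = c(4L, 2L, 1L, 3L)))
  halves <- splitHalf(obs)
  expect_setequal(unique(observations(halves$a)$patternId), c(1L, 3L))
  expect_setequal(unique(observations(halves$b)$patternId), c(2L, 4L))
  expect_equal(nObservations(halves$a) + nObservations(halves$b),
               nObservations(obs))
  # shuffling row order does not change the halves
  o <- observations(obs)
  shuffled <- observationTable(o[sample(nrow(o)), ])
  h2 <- splitHalf(shuffled)
  expect_setequal(unique(observations(h2$a)$patternId), c(1L, 3L))
  # single pattern errors
  expect_error(splitHalf(observationTable(obsFixture(patterns = 1L))),
               "2 patterns")
})

test_that("merging reports mean, multiplicity and SD-of-mean sigma", {
  o <- data.frame(h = c(1L, 1L, 1L, 2L), k = 0L, l = 0L, friedelSign = 1L,
                  intensity = c(10, 12, 14, 100), sigma = c(1, 1, 1, 7),
                  patternId = 1:4, invD = 0.2)
  m <- mergedTable(mergeObservations(observationTable(o)))
  m1 <- m[m$h == 1L, ]; m2 <- m[m$h == 2L, ]
  expect_equal(m1$intensity, 12)
  expect_equal(m1$multiplicity, 3L)
  expect_equal(m1$sigma, sd(c(10, 12, 14)) / sqrt(3))
  # single-observation reflections carry their input sigma
  expect_equal(m2$sigma, 7)
  expect_equal(m2$multiplicity, 1L)
})

test_that("R_split is zero for identical halves and matches its closed form", {
  A <- mergedFixture(c(100, 200, 300))
  expect_equal(rSplit(A, A)$overall, 0)
  a1 <- mergedFixture(100); b1 <- mergedFixture(50)
  expect_equal(rSplit(a1, b1)$overall, (1 / sqrt(2)) * 50 / 75,
               tolerance = 1e-12)
  expect_equal(rSplit(a1, b1)$overall, 0.4714, tolerance = 1e-4)
  # symmetry and scale invariance
  A <- mergedFixture(c(120, 80, 40, 220)); B <- mergedFixture(c(100, 90, 55, 180))
  expect_equal(rSplit(A, B)$overall, rSplit(B, A)$overall)
  A2 <- A; A2@merged$intensity <- 3 * A2@merged$intensity
  B2 <- B; B2@merged$intensity <- 3 * B2@merged$intensity
  expect_equal(rSplit(A2, B2)$overall, rSplit(A, B)$overall, tolerance = 1e-12)
  # zero denominator -> undefined marker, not zero
  z <- mergedFixture(c(50, -50))
  expect_true(is.na(rSplit(z, mergedFixture(c(-50, 50)))$overall))
})

test_that("CC1/2 behaves as a Pearson correlation over common reflections", {
  A <- mergedFixture(c(10, 50, 90, 130, 170))
  expect_equal(ccHalf(A, A)$overall, 1)
  B <- A; B@merged$intensity <- 2 * A@merged$intensity + 7
  expect_equal(ccHalf(A, B)$overall, 1)      # affine invariance
  C <- A; C@merged$intensity <- -A@merged$intensity
  expect_equal(ccHalf(A, C)$overall, -1)
  # < 3 common reflections -> undefined
  expect_true(is.na(ccHalf(mergedFixture(c(1, 2)), mergedFixture(c(2, 1)))$overall))
})

test_that("CC* follows its closed form and flags undefined inputs", {
  expect_equal(ccStar(1), 1)
  expect_equal(ccStar(0.5), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(ccStar(0.5), 0.8165, tolerance = 1e-4)
  expect_message(v <- ccStar(0), "undefined")
  expect_true(is.na(v))
  expect_message(v2 <- ccStar(-0.5), "undefined")
  expect_true(is.na(v2))
  expect_error(ccStar(-1))
  expect_error(ccStar(1.2))
  # monotone increasing on (0, 1]
  cs <- suppressMessages(ccStar(seq(0.05, 1, by = 0.05)))
  expect_true(all(diff(cs) > 0))
})

test_that("anomalous correlation separates null from signal-bearing data", {
  mkAno <- function(dI, sign = 1L) {
    plus <- data.frame(h = seq_along(dI), k = 0L, l = 0L, friedelSign = 1L,
                       intensity = 1000 + dI / 2, sigma = 1,
                       multiplicity = 2L, invD = 0.2)
    minus <- plus; minus$friedelSign <- -1L; minus$intensity <- 1000 - dI / 2
    new("MergedTable", merged = rbind(plus, minus))
  }
  set.seed(10)
  dI <- rnorm(50, 0, 30)
  A <- mkAno(dI)
  expect_equal(ccAno(A, A)$overall, 1)
  # anomalous-free data: cc_ano consistent with zero
  nullObs <- simulateObservations(obsSimConfig(nUniqueHkl = 500L,
                                               meanMultiplicity = 12,
                                               anomalousFraction = 0,
                                               scaleJitterSd = 0.1, seed = 6))
  halves <- splitHalf(nullObs)
  ccNull <- ccAno(mergeObservations(halves$a, byFriedel = TRUE),
                  mergeObservations(halves$b, byFriedel = TRUE))
  expect_lt(abs(ccNull$overall), 0.2)
  # strong anomalous signal, low noise: cc_ano near 1
  anoObs <- simulateObservations(obsSimConfig(nUniqueHkl = 300L,
                                              meanMultiplicity = 16,
                                              anomalousFraction = 0.5,
                                              scaleJitterSd = 0.02,
                                              noiseSigma0 = 1,
                                              noiseFrac = 0.01, seed = 8))
  halves <- splitHalf(anoObs)
  ccSig <- ccAno(mergeObservations(halves$a, byFriedel = TRUE),
                 mergeObservations(halves$b, byFriedel = TRUE))
  expect_gt(ccSig$overall, 0.9)
  expect_error(ccAno(mergedFixture(1:5), mergedFixture(1:5)), "byFriedel")
})

test_that("completeness and I/sigma summaries are exact on constructed input", {
  ref <- data.frame(h = 1:10, k = 0L, l = 0L,
                    invD = seq(0.15, 0.45, length.out = 10))
  merged <- new("MergedTable", merged = data.frame(
    h = 1:8, k = 0L, l = 0L, friedelSign = 0L,
    intensity = 100, sigma = 10, multiplicity = 2L,
    invD = seq(0.15, 0.45, length.out = 10)[1:8]))
  shells <- shellScheme(1, dMin = 2, dMax = 10)
  sc <- snrAndCompleteness(merged, ref, shells)
  expect_equal(sc$overall$completeness, 0.8)
  expect_equal(sc$overall$meanIOverSigma, 10)   # sigma = I/10 exactly
  # full coverage -> completeness 1 in every shell
  full <- new("MergedTable", merged = data.frame(
    h = 1:10, k = 0L, l = 0L, friedelSign = 0L, intensity = 50, sigma = 5,
    multiplicity = 2L, invD = ref$invD))
  sc2 <- snrAndCompleteness(full, ref, shellScheme(3, dMin = 2.2, dMax = 6.7))
  ok <- !is.na(sc2$byShell$completeness)
  expect_true(all(sc2$byShell$completeness[ok] == 1))
})

test_that("merged means converge to the truth as multiplicity grows", {
  bias <- vapply(c(4, 16, 64), function(mult) {
    obs <- simulateObservations(obsSimConfig(nUniqueHkl = 300L,
                                             meanMultiplicity = mult,
                                             scaleJitterSd = 0.3, seed = 14))
    m <- mergedTable(mergeObservations(obs))
    key <- paste(m$h, m$k, m$l)
    tkey <- paste(obs@truth$h, obs@truth$k, obs@truth$l)
    iTrue <- obs@truth$iTrue[match(key, tkey)]
    mean(abs(m$intensity - iTrue) / pmax(iTrue, 1))
  }, numeric(1))
  expect_true(all(diff(bias) < 0))
})

test_that("shrinking the pattern set degrades R_split (never improves it)", {
  obs <- simulateObservations(obsSimConfig(nUniqueHkl = 600L,
                                           meanMultiplicity = 32,
                                           nPatterns = 512L, seed = 19))
  o <- observations(obs)
  rs <- vapply(c(1, 4, 16), function(frac) {
    sub <- observationTable(o[o$patternId <= 512 / frac, , drop = FALSE],
                            truth = obs@truth)
    mergingMetrics(sub)$rSplit$overall
  }, numeric(1))
  expect_true(all(diff(rs) >= 0))
  # quantitative 1/sqrt(N) scaling between N and 4N patterns, within 20%;
  # averaged over the four disjoint quarter-subsets to reduce split variance
  rsQuarter <- mean(vapply(0:3, function(q) {
    sub <- observationTable(o[o$patternId > q * 128 &
                              o$patternId <= (q + 1) * 128, , drop = FALSE],
                            truth = obs@truth)
    mergingMetrics(sub)$rSplit$overall
  }, numeric(1)))
  expect_lt(abs(rsQuarter / rs[1] - 2), 0.4)
})

test_that("coarser quantization of intensities degrades the merged metrics", {
  obs <- simulateObservations(obsSimConfig(nUniqueHkl = 800L,
                                           meanMultiplicity = 16, seed = 25))
  chains <- list(raw = list(),
                 msb3 = list(quantizationSpec("msb", keepBits = 3)),
                 msb1 = list(quantizationSpec("msb", keepBits = 1)))
  q <- qualityVsReduction(obs, chains)
  expect_equal(q$chain, c("raw", "msb3", "msb1"))
  expect_gte(q$rSplit[q$chain == "msb1"], q$rSplit[q$chain == "msb3"])
  expect_gte(q$rSplit[q$chain == "msb3"], q$rSplit[q$chain == "raw"])
  # identity chain reproduces the baseline exactly
  expect_equal(q$rSplit[q$chain == "raw"], mergingMetrics(obs)$rSplit$overall)
})
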