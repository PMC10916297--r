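#' Frame-simulation configuration
#'
#' Parameters of the synthetic diffraction-frame generator: a smooth radial
#' background (Gaussian bump of amplitude \code{bgAmplitude} and width
#' \code{bgWidth} over a flat floor \code{bgFloor}), sparse Gaussian Bragg
#' peaks with exponentially distributed total intensities attenuated by a
#' Wilson-type falloff with resolution, Poisson photon noise, and (for
#' integrating detectors) gain/offset conversion to ADU with additive Gaussian
#' readout noise. A frame is a "hit" (contains crystal diffraction) with
#' probability \code{hitRate}.
#'
#' @slot geometry a [GeometryModel-class].
#' @slot bgAmplitude peak background level b0 at the beam center,
#'   photons/pixel.
#' @slot bgFloor flat background floor b1, photons/pixel.
#' @slot bgWidth radial 1/e^(1/2) width of the background bump, pixels.
#' @slot nPeaks Bragg peaks per hit frame.
#' @slot minPeakSeparation minimum pairwise peak distance, pixels.
#' @slot peakSigma Gaussian peak width, pixels.
#' @slot peakMeanIntensity mean total peak intensity, photons.
#' @slot wilsonB Wilson B-factor (Angstrom^2) attenuating peak intensity with
#'   resolution.
#' @slot hitRate fraction of frames containing diffraction, in [0, 1].
#' @slot detectorKind \code{"counting"} (integer photon counts) or
#'   \code{"integrating"} (real-valued ADU).
#' @slot gain ADU per photon (integrating).
#' @slot offset ADU offset (integrating).
#' @slot readoutSigma Gaussian readout noise SD in ADU (integrating).
#' @slot seed root RNG seed; per-frame child streams are derived from it so
#'   any frame is reproducible in isolation.
#' @name FrameSimConfig-class
#' @rdname FrameSimConfig-class
#' @exportClass FrameSimConfig
setClass("FrameSimConfig", representation(
  geometry = "GeometryModel",
  bgAmplitude = "numeric", bgFloor = "numeric", bgWidth = "numeric",
  nPeaks = "integer", minPeakSeparation = "numeric", peakSigma = "numeric",
  peakMeanIntensity = "numeric", wilsonB = "numeric",
  hitRate = "numeric", detectorKind = "character",
  gain = "numeric", offset = "numeric", readoutSigma = "numeric",
  seed = "integer"
))

setValidity("FrameSimConfig", function(object) {
  msg <- character()
  if (object@hitRate < 0 || object@hitRate > 1)
    msg <- c(msg, "hitRate must be in [0, 1]")
  if (object@minPeakSeparation < 1)
    msg <- c(msg, "minPeakSeparation must be >= 1 pixel")
  if (!object@detectorKind %in% c("counting", "integrating"))
    msg <- c(msg, "detectorKind must be counting or integrating")
  if (object@detectorKind == "integrating" &&
      !(is.finite(object@gain) && object@gain > 0))
    msg <- c(msg, "integrating mode needs gain > 0")
  if (object@bgAmplitude < 0 || object@bgFloor < 0)
    msg <- c(msg, "background levels must be >= 0")
  if (object@bgWidth <= 0) msg <- c(msg, "bgWidth must be > 0")
  if (object@peakSigma <= 0) msg <- c(msg, "peakSigma must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a FrameSimConfig
#'
#' Defaults describe a plausible small SX experiment: a 128 x 128 panel of
#' 200 um pixels at 80 mm and 12.398 keV (1 A), a smooth background of about
#' 5 photons/pixel near the beam center falling to a floor of 1, 25 bright
#' peaks per hit with mean 400 photons, Wilson B of 15 A^2, and a 30% hit
#' rate. Counting mode by default; integrating mode adds gain 73.14
#' ADU/photon, zero offset and 3 ADU readout noise.
#'
#' @param geometry a [GeometryModel-class].
#' @param bgAmplitude,bgFloor,bgWidth background model (photons/pixel, pixels).
#' @param nPeaks,minPeakSeparation,peakSigma,peakMeanIntensity,wilsonB peak
#'   model.
#' @param hitRate fraction of hit frames.
#' @param detectorKind \code{"counting"} or \code{"integrating"}.
#' @param gain,offset,readoutSigma ADU conversion (integrating mode).
#' @param seed root seed.
#' @return a [FrameSimConfig-class].
#' @examples
#' cfg <- frameSimConfig(seed = 7)
#' sim <- simulateFrame(cfg, frameId = 0, forceHit = TRUE)
#' sim$frame
#' sim$truthPeaks
#' @export
frameSimConfig <- function(geometry = geometryModel(128, 128, 200e-6, 0.08),
                           bgAmplitude = 4, bgFloor = 1, bgWidth = 60,
                           nPeaks = 25L, minPeakSeparation = 8,
                           peakSigma = 1.2, peakMeanIntensity = 400,
                           wilsonB = 15, hitRate = 0.3,
                           detectorKind = "counting",
                           gain = 73.14, offset = 0, readoutSigma = 3,
                           seed = 1L) {
  new("FrameSimConfig", geometry = geometry, bgAmplitude = bgAmplitude,
      bgFloor = bgFloor, bgWidth = bgWidth, nPeaks = as.integer(nPeaks),
      minPeakSeparation = minPeakSeparation, peakSigma = peakSigma,
      peakMeanIntensity = peakMeanIntensity, wilsonB = wilsonB,
      hitRate = hitRate, detectorKind = detectorKind, gain = gain,
      offset = offset, readoutSigma = readoutSigma, seed = as.integer(seed))
}

setMethod("show", "FrameSimConfig", function(object) {
  cat(sprintf("FrameSimConfig: %d x %d %s detector, bg %g+%g ph/px, %d peaks (mean %g ph), hit rate %g, seed %d\n",
              object@geometry@nFast, object@geometry@nSlow,
              object@detectorKind, object@bgFloor, object@bgAmplitude,
              object@nPeaks, object@peakMeanIntensity, object@hitRate,
              object@seed))
})

## Deterministic per-frame child seed from the root seed: two steps of a
## Lehmer-style recurrence over the Mersenne prime 2^31 - 1, mixing in the
## frame id. Keeps every intermediate below 2^53 so double arithmetic is exact.
.childSeed <- function(root, id, salt = 0) {
  m <- 2147483647
  x <- (as.numeric(root) %% m) + 1
  x <- (x * 48271 + as.numeric(id) + 1) %% m
  x <- (x * 48271 + as.numeric(salt) * 7919 + 1) %% m
  as.integer(x)
}

## Rejection-sample nPeaks positions with pairwise Euclidean separation >=
## minSep, uniformly over the panel (0.5 px margin). Bounded attempts.
.samplePeakPositions <- function(nFast, nSlow, nPeaks, minSep,
                                 maxAttempts = 200L * max(nPeaks, 1L)) {
  fast <- numeric(0); slow <- numeric(0)
  attempts <- 0L
  while (length(fast) < nPeaks) {
    if (attempts >= maxAttempts)
      stop(sprintf(paste0("could not place %d peaks with pairwise separation ",
                          ">= %g px on a %d x %d panel after %d attempts; ",
                          "relax minPeakSeparation or reduce nPeaks"),
                   nPeaks, minSep, nFast, nSlow, maxAttempts))
    attempts <- attempts + 1L
    f <- stats::runif(1, 0.5, nFast - 1.5)
    s <- stats::runif(1, 0.5, nSlow - 1.5)
    if (length(fast) == 0L ||
        all((fast - f)^2 + (slow - s)^2 >= minSep^2)) {
      fast <- c(fast, f); slow <- c(slow, s)
    }
  }
  data.frame(fastPos = fast, slowPos = slow)
}

#' Simulate one detector frame with ground-truth peaks
#'
#' Builds the expected photon image (radial background plus, for hits,
#' Gaussian Bragg peaks), draws Poisson photon counts, and for integrating
#' detectors converts photons to ADU with gain, offset and Gaussian readout
#' noise. The returned ground truth records the sampled peak centers, their
#' total intensities and 1/d.
#'
#' The frame's RNG stream is derived deterministically from
#' \code{config@seed} and \code{frameId}, so any single frame of a dataset can
#' be regenerated in isolation.
#'
#' @param config a [FrameSimConfig-class].
#' @param frameId integer frame id.
#' @param forceHit \code{NA} (default) to draw hit status from
#'   \code{config@hitRate}, otherwise \code{TRUE}/\code{FALSE}.
#' @return a list with elements \code{frame} ([DetectorFrame-class]),
#'   \code{truthPeaks} ([PeakList-class]; empty for non-hits) and
#'   \code{isHit}.
#' @export
simulateFrame <- function(config, frameId = 0L, forceHit = NA) {
  geo <- config@geometry
  nF <- geo@nFast; nS <- geo@nSlow
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.childSeed(config@seed, frameId))

  isHit <- if (is.na(forceHit)) stats::runif(1) < config@hitRate else isTRUE(forceHit)

  r <- .radiusMatrix(geo)  # nSlow x nFast
  bgLambda <- config@bgAmplitude * exp(-r^2 / (2 * config@bgWidth^2)) + config@bgFloor
  ## Background, peak and readout draws come from separate salted
  ## sub-streams of the frame's seed: a hit differs from the non-hit frame
  ## of the same id only by the added peak photons.
  set.seed(.childSeed(config@seed, frameId, salt = 1))
  photons <- matrix(stats::rpois(nS * nF, bgLambda), nS, nF)

  lambda <- matrix(0, nS, nF)
  truth <- NULL
  if (isHit && config@nPeaks > 0L) {
    set.seed(.childSeed(config@seed, frameId, salt = 2))
    pos <- .samplePeakPositions(nF, nS, config@nPeaks, config@minPeakSeparation)
    invD <- pixelInvD(geo, pos$fastPos, pos$slowPos)
    ## Wilson-type falloff: I ~ Exp(mean) * exp(-2 B (1/(2d))^2)
    amp <- stats::rexp(config@nPeaks, rate = 1 / config@peakMeanIntensity) *
      exp(-2 * config@wilsonB * (invD / 2)^2)
    w <- ceiling(4 * config@peakSigma)
    for (p in seq_len(config@nPeaks)) {
      fc <- pos$fastPos[p]; sc <- pos$slowPos[p]
      fi <- max(0L, floor(fc - w)):min(nF - 1L, ceiling(fc + w))
      si <- max(0L, floor(sc - w)):min(nS - 1L, ceiling(sc + w))
      kern <- outer(exp(-(si - sc)^2 / (2 * config@peakSigma^2)),
                    exp(-(fi - fc)^2 / (2 * config@peakSigma^2)))
      kern <- kern / sum(kern)  # total expected photons in window = amp
      lambda[si + 1L, fi + 1L] <- lambda[si + 1L, fi + 1L] + amp[p] * kern
    }
    bgAt <- config@bgAmplitude *
      exp(-((pos$fastPos - geo@beamCenterFast)^2 +
            (pos$slowPos - geo@beamCenterSlow)^2) / (2 * config@bgWidth^2)) +
      config@bgFloor
    area <- 2 * pi * config@peakSigma^2
    truth <- data.frame(fastPos = pos$fastPos, slowPos = pos$slowPos,
                        intensity = amp,
                        snr = amp / sqrt(pmax(amp + bgAt * area, 1)),
                        invD = invD,
                        nPixels = rep(ceiling(area), config@nPeaks),
                        edge = pos$fastPos < w | pos$fastPos > nF - 1 - w |
                               pos$slowPos < w | pos$slowPos > nS - 1 - w)
  }

  if (isHit && config@nPeaks > 0L)
    photons <- photons + matrix(stats::rpois(nS * nF, lambda), nS, nF)
  if (config@detectorKind == "counting") {
    values <- photons
    storage.mode(values) <- "integer"
    kind <- "photon_count_integer"
  } else {
    values <- photons * config@gain + config@offset
    if (config@readoutSigma > 0) {
      set.seed(.childSeed(config@seed, frameId, salt = 3))
      values <- values + matrix(stats::rnorm(nS * nF, 0, config@readoutSigma), nS, nF)
    }
    kind <- "adu_real"
  }
  list(frame = detectorFrame(values, valueKind = kind, frameId = frameId),
       truthPeaks = peakList(truth, frameId = frameId),
       isHit = isHit)
}

#' Simulate a stack of frames with a hit/non-hit truth table
#'
#' @param config a [FrameSimConfig-class].
#' @param nFrames number of frames (>= 1). Frame ids run \code{0:(nFrames-1)}.
#' @return a list with \code{stack} ([FrameStack-class]), \code{truth}
#'   (data.frame \code{frameId, isHit, nTruePeaks}) and \code{truthPeaks}
#'   (list of [PeakList-class], one per frame).
#' @examples
#' sim <- simulateDataset(frameSimConfig(geometry = geometryModel(48, 48, 200e-6, 0.08),
#'                                       nPeaks = 6L, seed = 3), nFrames = 4)
#' sim$truth
#' @export
simulateDataset <- function(config, nFrames) {
  stopifnot(nFrames >= 1)
  frames <- vector("list", nFrames)
  truthPeaks <- vector("list", nFrames)
  isHit <- logical(nFrames)
  for (i in seq_len(nFrames)) {
    sim <- simulateFrame(config, frameId = i - 1L)
    frames[[i]] <- sim$frame@values
    truthPeaks[[i]] <- sim$truthPeaks
    isHit[i] <- sim$isHit
  }
  values <- array(unlist(frames, use.names = FALSE),
                  dim = c(config@geometry@nSlow, config@geometry@nFast, nFrames))
  if (config@detectorKind == "counting") storage.mode(values) <- "integer"
  kind <- if (config@detectorKind == "counting") "photon_count_integer" else "adu_real"
  list(stack = frameStack(values, valueKind = kind,
                          frameIds = seq_len(nFrames) - 1L),
       truth = data.frame(frameId = seq_len(nFrames) - 1L, isHit = isHit,
                          nTruePeaks = vapply(truthPeaks, nPeaks, integer(1))),
       truthPeaks = truthPeaks)
}

#' Observation-simulation configuration
#'
#' Generates unmerged reflection observations with known truth. Unique
#' reflections get 1/d values from an integer-lattice model scaled to the
#' resolution range; true intensities are exponential with a Wilson-type mean
#' falling off with resolution; each observation multiplies the truth by a
#' lognormal per-observation scale (emulating the large SX partiality and
#' scale errors) and adds Gaussian noise with
#' \eqn{\sigma(I) = \sqrt{\sigma_0^2 + (f \cdot I)^2}}.
#'
#' @slot nUniqueHkl unique reflections.
#' @slot meanMultiplicity mean observations per reflection (> 0); per-hkl
#'   multiplicity is 1 + Poisson(meanMultiplicity - 1).
#' @slot wilsonI0 mean intensity at zero scattering angle (arbitrary units).
#' @slot wilsonB Wilson B (Angstrom^2) for the falloff of the mean.
#' @slot scaleJitterSd SD of the lognormal per-observation scale (>= 0).
#' @slot noiseSigma0 additive noise floor (intensity units).
#' @slot noiseFrac fractional noise coefficient.
#' @slot anomalousFraction relative Bijvoet difference: Friedel mates get
#'   intensities \code{I (1 +/- anomalousFraction/2)} with a random sign per
#'   reflection.
#' @slot dMin,dMax resolution range in Angstrom.
#' @slot nPatterns number of patterns observations are spread over.
#' @slot seed RNG seed.
#' @name ObsSimConfig-class
#' @rdname ObsSimConfig-class
#' @exportClass ObsSimConfig
setClass("ObsSimConfig", representation(
  nUniqueHkl = "integer", meanMultiplicity = "numeric",
  wilsonI0 = "numeric", wilsonB = "numeric",
  scaleJitterSd = "numeric", noiseSigma0 = "numeric", noiseFrac = "numeric",
  anomalousFraction = "numeric", dMin = "numeric", dMax = "numeric",
  nPatterns = "integer", seed = "integer"
))

setValidity("ObsSimConfig", function(object) {
  msg <- character()
  if (object@meanMultiplicity <= 0) msg <- c(msg, "meanMultiplicity must be > 0")
  if (object@dMin >= object@dMax) msg <- c(msg, "need dMin < dMax")
  if (object@scaleJitterSd < 0) msg <- c(msg, "scaleJitterSd must be >= 0")
  if (object@nPatterns < 2L) msg <- c(msg, "need nPatterns >= 2")
  if (length(msg)) msg else TRUE
})

#' Construct an ObsSimConfig
#' @param nUniqueHkl unique reflections (default 1000).
#' @param meanMultiplicity mean observations per reflection (default 8).
#' @param wilsonI0,wilsonB Wilson intensity model (defaults 1000, 15).
#' @param scaleJitterSd lognormal scale SD (default 0.3, the dominant SX
#'   error source).
#' @param noiseSigma0,noiseFrac additive and fractional noise (defaults 5,
#'   0.05).
#' @param anomalousFraction relative Bijvoet difference (default 0).
#' @param dMin,dMax resolution range (defaults 1.8, 20 Angstrom).
#' @param nPatterns patterns to spread observations over; default targets
#'   about 25 observations per pattern.
#' @param seed RNG seed.
#' @return an [ObsSimConfig-class].
#' @export
obsSimConfig <- function(nUniqueHkl = 1000L, meanMultiplicity = 8,
                         wilsonI0 = 1000, wilsonB = 15,
                         scaleJitterSd = 0.3, noiseSigma0 = 5,
                         noiseFrac = 0.05, anomalousFraction = 0,
                         dMin = 1.8, dMax = 20,
                         nPatterns = NULL, seed = 1L) {
  if (is.null(nPatterns))
    nPatterns <- max(2L, as.integer(round(nUniqueHkl * meanMultiplicity / 25)))
  new("ObsSimConfig", nUniqueHkl = as.integer(nUniqueHkl),
      meanMultiplicity = meanMultiplicity, wilsonI0 = wilsonI0,
      wilsonB = wilsonB, scaleJitterSd = scaleJitterSd,
      noiseSigma0 = noiseSigma0, noiseFrac = noiseFrac,
      anomalousFraction = anomalousFraction, dMin = dMin, dMax = dMax,
      nPatterns = as.integer(nPatterns), seed = as.integer(seed))
}

## Unique hkl triples: integer lattice points sorted by norm, one
## representative per Friedel pair, scaled so the n-th norm hits 1/dMin.
.hklLattice <- function(n, dMin, dMax) {
  L <- 2L
  repeat {
    g <- expand.grid(h = -L:L, k = -L:L, l = -L:L)
    g <- g[!(g$h == 0 & g$k == 0 & g$l == 0), ]
    keep <- g$l > 0 | (g$l == 0 & g$k > 0) | (g$l == 0 & g$k == 0 & g$h > 0)
    g <- g[keep, ]
    if (nrow(g) >= n) break
    L <- L + 1L
  }
  g$norm <- sqrt(g$h^2 + g$k^2 + g$l^2)
  g <- g[order(g$norm, g$h, g$k, g$l), ][seq_len(n), ]
  sLo <- 1 / dMax; sHi <- 1 / dMin
  g$invD <- sLo + (g$norm - min(g$norm)) / max(g$norm - min(g$norm), 1e-12) * (sHi - sLo)
  rownames(g) <- NULL
  g
}

#' Simulate an unmerged reflection-observation table with hidden truth
#'
#' @param config an [ObsSimConfig-class].
#' @return an [ObservationTable-class]; its \code{truth} slot carries the true
#'   per-reflection intensities (Friedel-mean).
#' @examples
#' obs <- simulateObservations(obsSimConfig(nUniqueHkl = 200L, seed = 5))
#' obs
#' @export
simulateObservations <- function(config) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(.childSeed(config@seed, 0, salt = 101))

  hkl <- .hklLattice(config@nUniqueHkl, config@dMin, config@dMax)
  meanI <- config@wilsonI0 * exp(-2 * config@wilsonB * (hkl$invD / 2)^2)
  iTrue <- stats::rexp(config@nUniqueHkl, rate = 1 / pmax(meanI, 1e-9))
  anoSign <- if (config@anomalousFraction > 0)
    sample(c(-1, 1), config@nUniqueHkl, replace = TRUE) else rep(0, config@nUniqueHkl)

  mult <- 1L + stats::rpois(config@nUniqueHkl,
                            max(config@meanMultiplicity - 1, 0))
  idx <- rep.int(seq_len(config@nUniqueHkl), mult)
  nObs <- length(idx)
  friedel <- ifelse(stats::runif(nObs) < 0.5, 1L, -1L)
  ## Friedel mates carry I_true * (1 +/- anomalousFraction/2), sign per hkl
  iMate <- iTrue[idx] *
    (1 + friedel * anoSign[idx] * config@anomalousFraction / 2)
  scale <- if (config@scaleJitterSd > 0)
    stats::rlnorm(nObs, 0, config@scaleJitterSd) else rep(1, nObs)
  sig <- sqrt(config@noiseSigma0^2 + (config@noiseFrac * iMate)^2)
  eps <- if (any(sig > 0)) stats::rnorm(nObs, 0, sig) else rep(0, nObs)
  obs <- data.frame(
    h = hkl$h[idx], k = hkl$k[idx], l = hkl$l[idx],
    friedelSign = friedel,
    intensity = scale * iMate + eps,
    sigma = pmax(sig, 1e-9),
    patternId = sample.int(config@nPatterns, nObs, replace = TRUE),
    invD = hkl$invD[idx])
  observationTable(obs, truth = data.frame(h = hkl$h, k = hkl$k, l = hkl$l,
                                           iTrue = iTrue))
}
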