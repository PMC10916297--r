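# Shared fixtures: tiny geometries, hand-built frames with injected Gaussian
# peaks, and independent brute-force oracles for the non-uniform quantizers.

smallGeometry <- function(n = 64L)
  geometryModel(n, n, pixelSize = 200e-6, detectorDistance = 0.08,
                photonEnergy = 12.398)

# Inject Gaussian peaks of given total intensities onto a Poisson(flat bg)
# frame; returns the frame and the injected truth as a PeakList.
injectedPeakFrame <- function(geometry, positions, amps, peakSigma = 1.5,
                              background = 10, seed = 1, poisson = TRUE) {
  set.seed(seed)
  nS <- geometry@nSlow; nF <- geometry@nFast
  lambda <- matrix(background, nS, nF)
  w <- ceiling(4 * peakSigma)
  for (p in seq_len(nrow(positions))) {
    fc <- positions$fastPos[p]; sc <- positions$slowPos[p]
    fi <- max(0L, floor(fc - w)):min(nF - 1L, ceiling(fc + w))
    si <- max(0L, floor(sc - w)):min(nS - 1L, ceiling(sc + w))
    kern <- outer(exp(-(si - sc)^2 / (2 * peakSigma^2)),
                  exp(-(fi - fc)^2 / (2 * peakSigma^2)))
    lambda[si + 1L, fi + 1L] <- lambda[si + 1L, fi + 1L] +
      amps[p] * kern / sum(kern)
  }
  values <- if (poisson) matrix(rpois(nS * nF, lambda), nS, nF)
            else round(lambda)
  storage.mode(values) <- "integer"
  truth <- peakList(data.frame(fastPos = positions$fastPos,
                               slowPos = positions$slowPos,
                               intensity = amps, snr = 0,
                               invD = pixelInvD(geometry, positions$fastPos,
                                                positions$slowPos),
                               nPixels = 1L, edge = FALSE))
  list(frame = detectorFrame(values), truth = truth)
}

# Well-separated grid positions inside the panel.
gridPositions <- function(n, panel, margin = 8, jitterSeed = NULL) {
  side <- ceiling(sqrt(n))
  coords <- seq(margin, panel - 1 - margin, length.out = side)
  g <- expand.grid(fastPos = coords, slowPos = coords)[seq_len(n), ]
  if (!is.null(jitterSeed)) {
    set.seed(jitterSeed)
    g$fastPos <- g$fastPos + runif(n, -1, 1)
    g$slowPos <- g$slowPos + runif(n, -1, 1)
  }
  g
}

# Independent oracle: all values representable with <= k significant bits,
# built by direct enumeration of mantissa x power-of-two products.
msbRepresentable <- function(k, maxVal) {
  vals <- 0
  for (m in 1:(2^k - 1)) {
    e <- 0
    repeat {
      v <- m * 2^e
      if (v > maxVal) break
      vals <- c(vals, v)
      e <- e + 1
    }
  }
  sort(unique(vals))
}

# Nearest member of a sorted set, ties away from zero (set is non-negative;
# callers handle sign).
nearestInSet <- function(x, set) {
  hi <- findInterval(x, set, all.inside = TRUE)
  lo <- set[hi]; up <- set[hi + 1L]
  ifelse(x - lo < up - x, lo, up)
}

# Independent enumeration of all 1/5/2 minifloat magnitudes (bias 15,
# subnormals, no NaN/Inf).
minifloatMagnitudes <- function() {
  vals <- c(0:3 * 2^-16)                      # exponent field 0: subnormal
  for (E in 1:31) vals <- c(vals, (4 + 0:3) * 2^(E - 17))
  sort(unique(vals))
}
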