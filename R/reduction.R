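## Round half away from zero; the package-wide tie rule for every quantizer,
## fixed so results are bit-reproducible.
.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Veto non-hit frames from a stack
#'
#' Runs the peak finder and hit classifier on every frame and retains the
#' hits unchanged: kept frames are bit-identical to the input (raw-format
#' retention, so later recalibration remains possible).
#'
#' @param stack a [FrameStack-class].
#' @param geometry a [GeometryModel-class].
#' @param params a [PeakFindParams-class].
#' @param minPeaks hit threshold, see [isHit()].
#' @return list with \code{stack} (retained frames), \code{report}
#'   ([ReductionReport-class]), \code{hits} (logical per input frame) and
#'   \code{peakLists} (the per-frame [PeakList-class] objects).
#' @export
vetoNonHits <- function(stack, geometry, params = peakFindParams(),
                        minPeaks = 10L) {
  n <- nFrames(stack)
  stopifnot(n >= 1)
  peakLists <- vector("list", n)
  hits <- logical(n)
  for (i in seq_len(n)) {
    peakLists[[i]] <- findPeaks(getFrame(stack, i), geometry, params)
    hits[i] <- isHit(peakLists[[i]], minPeaks)
  }
  kept <- stack@values[, , hits, drop = FALSE]
  out <- frameStack(kept, valueKind = stack@valueKind, mask = stack@mask,
                    frameIds = stack@frameIds[hits])
  report <- new("ReductionReport", framesIn = n, framesOut = sum(hits),
                chain = "veto",
                distinctValuesOut = length(unique(as.vector(kept))),
                maxAbsError = 0, maxRelError = 0)
  list(stack = out, report = report, hits = hits, peakLists = peakLists)
}

#' Bin a frame by summing b x b pixel blocks
#'
#' Each output pixel is the SUM of its b x b input block, so total intensity
#' (photon count) is conserved exactly. An output pixel is usable only when
#' every contributing input pixel is usable. If b does not divide a
#' dimension, the trailing rows/columns are dropped with a warning.
#'
#' @param frame a [DetectorFrame-class].
#' @param b integer binning factor >= 2, not exceeding either panel
#'   dimension.
#' @return the binned [DetectorFrame-class]; value kind is preserved.
#' @examples
#' f <- detectorFrame(matrix(1L, 4, 4))
#' binFrame(f, 2)@values  # 2 x 2 matrix of 4s
#' @export
binFrame <- function(frame, b) {
  b <- as.integer(b)
  v <- frame@values
  if (b < 2L || b > nrow(v) || b > ncol(v))
    stop("binning factor must satisfy 2 <= b <= panel size")
  nS <- (nrow(v) %/% b) * b
  nF <- (ncol(v) %/% b) * b
  if (nS < nrow(v) || nF < ncol(v)) {
    warning(sprintf("binning factor %d does not divide %d x %d; dropping %d trailing row(s) and %d column(s)",
                    b, nrow(v), ncol(v), nrow(v) - nS, ncol(v) - nF))
    v <- v[seq_len(nS), seq_len(nF), drop = FALSE]
  }
  m <- frame@mask[seq_len(nS), seq_len(nF), drop = FALSE]
  ## block sum via two reshapes
  blockSum <- function(x) {
    x <- matrix(colSums(matrix(x, nrow = b)), nrow = nS %/% b)         # rows
    t(matrix(colSums(matrix(t(x), nrow = b)), nrow = nF %/% b))        # cols
  }
  out <- blockSum(v)
  outMask <- blockSum(!m) == 0
  if (is.integer(frame@values) && max(abs(out)) <= .Machine$integer.max)
    storage.mode(out) <- "integer"
  detectorFrame(out, valueKind = frame@valueKind, mask = outMask,
                frameId = frame@frameId)
}

#' Bin every frame of a stack
#' @param stack a [FrameStack-class].
#' @param b binning factor, see [binFrame()].
#' @return the binned [FrameStack-class].
#' @export
binStack <- function(stack, b) {
  n <- nFrames(stack)
  first <- binFrame(getFrame(stack, 1), b)
  out <- array(0, dim = c(nrow(first@values), ncol(first@values), n))
  out[, , 1] <- first@values
  if (n > 1) for (i in 2:n)
    out[, , i] <- suppressWarnings(binFrame(getFrame(stack, i), b))@values
  if (is.integer(stack@values) && max(abs(out)) <= .Machine$integer.max)
    storage.mode(out) <- "integer"
  frameStack(out, valueKind = stack@valueKind, mask = first@mask,
             frameIds = stack@frameIds)
}

#' Remap peak coordinates into binned-image coordinates
#'
#' Peak positions found on the unbinned frame are recalculated into the
#' coordinates of the binned image (pixel-center convention: pixel i's
#' center at integer i), so the peak list can be stored alongside the binned
#' data without information loss. Intensities and 1/d are unchanged; the map
#' is exactly invertible.
#'
#' @param peaks a [PeakList-class] in original coordinates.
#' @param b binning factor >= 2.
#' @param inverse map binned coordinates back to original ones.
#' @return the remapped [PeakList-class].
#' @examples
#' pk <- peakList(data.frame(fastPos = 5, slowPos = 3, intensity = 1))
#' peakTable(remapPeaks(pk, 2))[, c("fastPos", "slowPos")]  # (2.25, 1.25)
#' @export
remapPeaks <- function(peaks, b, inverse = FALSE) {
  stopifnot(b >= 2)
  p <- peakTable(peaks)
  if (nrow(p)) {
    if (inverse) {
      p$fastPos <- (p$fastPos + 0.5) * b - 0.5
      p$slowPos <- (p$slowPos + 0.5) * b - 0.5
    } else {
      p$fastPos <- (p$fastPos + 0.5) / b - 0.5
      p$slowPos <- (p$slowPos + 0.5) / b - 0.5
    }
  }
  peakList(p, frameId = peaks@frameId)
}

#' Keep only pixels around detected peaks
#'
#' Retains pixel values within a Chebyshev radius of any peak center and
#' masks everything else (values set to 0, mask set unusable). Provided so
#' the information cost of peak-only storage can be quantified; discarding
#' the inter-peak pixels destroys the weak high-resolution signal that
#' merging many patterns would otherwise recover.
#'
#' @param frame a [DetectorFrame-class].
#' @param peaks a [PeakList-class].
#' @param radius Chebyshev radius in pixels (>= 1); a peak keeps a
#'   (2 radius + 1)^2 window.
#' @return the masked [DetectorFrame-class].
#' @export
peakOnlyMask <- function(frame, peaks, radius = 3L) {
  stopifnot(radius >= 1)
  radius <- as.integer(radius)
  v <- frame@values
  keep <- matrix(FALSE, nrow(v), ncol(v))
  p <- peakTable(peaks)
  for (i in seq_len(nrow(p))) {
    rc <- round(p$slowPos[i]) + 1L
    cc <- round(p$fastPos[i]) + 1L
    rows <- max(1L, rc - radius):min(nrow(v), rc + radius)
    cols <- max(1L, cc - radius):min(ncol(v), cc + radius)
    keep[rows, cols] <- TRUE
  }
  v[!keep] <- if (is.integer(v)) 0L else 0
  detectorFrame(v, valueKind = frame@valueKind, mask = frame@mask & keep,
                frameId = frame@frameId)
}

#' Uniform quantization to multiples of a step
#'
#' Each value is replaced by the nearest integer multiple of \code{step} ADU,
#' ties away from zero. Coarse steps (e.g. 1024 ADU on a ~73 ADU/photon
#' detector) trade intensity precision for compressibility.
#'
#' @param x a [DetectorFrame-class], [FrameStack-class] or numeric vector.
#' @param step quantization step, > 0.
#' @return same type as \code{x}, quantized; value kind unchanged.
#' @examples
#' quantizeUniform(c(0, 1500, 1536, -600), 1024)  # 0, 1024, 2048, -1024
#' @export
quantizeUniform <- function(x, step) {
  stopifnot(step > 0)
  q <- function(v) .roundHalfAway(v / step) * step
  .applyValues(x, q)
}

#' Convert integrating-detector ADU values to integer photon counts
#'
#' \code{round((value - offset) / gain)}, ties away from zero. Negative
#' results are permitted: calibrated integrating-detector data can go below
#' zero after dark-signal subtraction.
#'
#' @param x a [DetectorFrame-class], [FrameStack-class] (value kind
#'   \code{adu_real} or \code{adu_integer}) or numeric vector.
#' @param gain ADU per photon, > 0.
#' @param offset ADU offset.
#' @return same type as \code{x} with integer photon values; frames switch to
#'   value kind \code{adu_integer} (photon integers that may be negative).
#' @examples
#' aduToPhotons(1024, gain = 73.14)  # ~14 photons at 9 keV
#' @export
aduToPhotons <- function(x, gain, offset = 0) {
  stopifnot(gain > 0)
  q <- function(v) .roundHalfAway((v - offset) / gain)
  if (is(x, "DetectorFrame") || is(x, "FrameStack")) {
    if (x@valueKind == "photon_count_integer")
      stop("frame already holds photon counts")
    out <- .applyValues(x, q)
    out@valueKind <- "adu_integer"
    if (max(abs(out@values)) <= .Machine$integer.max)
      storage.mode(out@values) <- "integer"
    out
  } else q(x)
}

## floor(log2(a)) robust against log2() landing a hair off an exact power
.floorLog2 <- function(a) {
  f <- floor(log2(a))
  f <- ifelse(2^f > a, f - 1, f)
  ifelse(2^(f + 1) <= a, f + 1, f)
}

#' Round integers to k most-significant bits
#'
#' The non-uniform (relative-precision) quantizer: each magnitude is replaced
#' by the nearest value representable with \code{keepBits} significant binary
#' digits, i.e. a member of \eqn{\{0\} \cup \{m 2^e\}} with m carrying at
#' most k bits. Quantization levels are dense at low photon counts and
#' sparse at high ones, in proportion to counting noise, so weak reflections
#' keep their precision. Ties round away from zero; the sign is quantized as
#' magnitude and restored. With \code{truncate = TRUE} the value is instead
#' truncated (all bits below the kept ones zeroed), the simplest variant.
#'
#' The relative error of nearest rounding is bounded by \eqn{2^{-k}}.
#'
#' @param x a [DetectorFrame-class], [FrameStack-class] or numeric vector of
#'   integer-valued numbers (apply [aduToPhotons()] or [quantizeUniform()]
#'   first for reals).
#' @param keepBits 1, 2 or 3 kept most-significant bits.
#' @param truncate use truncation instead of nearest rounding.
#' @return same type as \code{x}, quantized.
#' @examples
#' msbRound(13, 1)  # 16
#' msbRound(13, 2)  # 12
#' msbRound(13, 3)  # 14 (tie 12/14 resolved away from zero)
#' msbRound(13, 1, truncate = TRUE)  # 8
#' @export
msbRound <- function(x, keepBits, truncate = FALSE) {
  if (!length(keepBits) == 1L || !keepBits %in% 1:3)
    stop("keepBits must be 1, 2 or 3")
  k <- as.integer(keepBits)
  q <- function(v) {
    if (any(v != floor(v)))
      stop("msbRound needs integer-valued input; convert to photons or quantize first")
    s <- sign(v); a <- abs(v)
    big <- a >= 2^k  # below 2^k every integer is representable
    if (any(big)) {
      ab <- a[big]
      step <- 2^(.floorLog2(ab) - (k - 1))
      m <- ab / step
      a[big] <- if (truncate) floor(m) * step
                else (floor(m) + (m - floor(m) >= 0.5)) * step
    }
    s * a
  }
  .applyValues(x, q)
}

## 1/5/2 minifloat decode table: 128 non-negative values indexed by code 0:127
.minifloatTable <- function() {
  codes <- 0:127
  E <- codes %/% 4L
  M <- codes %% 4L
  ifelse(E == 0L, M * 2^-16, (4 + M) * 2^(E - 17))
}

#' Encode integers as 8-bit minifloats (1 sign / 5 exponent / 2 mantissa)
#'
#' The floating-point analogue of 3-bit MSB rounding: 1 sign bit, 5 exponent
#' bits (bias 15, exponent field 0 reserved for subnormals, no infinity or
#' NaN codes — all 31 exponent values are numeric) and 2 mantissa bits.
#' Encoding maps each value to the nearest representable number (ties away
#' from zero) and clamps magnitudes beyond the largest representable value,
#' 1.75 * 2^16 = 114688. For integers with magnitude in [4, clamp] the
#' quantized value equals \code{msbRound(x, 3)} (implicit leading 1 plus two
#' mantissa bits = 3 significant bits).
#'
#' @param x a [DetectorFrame-class], [FrameStack-class] or numeric vector of
#'   integer-valued numbers.
#' @return list with \code{codes} (raw vector, or raw payload for
#'   frames/stacks), \code{decodeMap} (numeric[256]: value of every code) and
#'   \code{quantized} (same type as \code{x}: decode(encode(x))).
#' @examples
#' enc <- toMinifloat8(c(0, 13, 200000, -5))
#' enc$quantized  # 0, 14, 114688, -5
#' @export
toMinifloat8 <- function(x) {
  tab <- .minifloatTable()
  maxVal <- tab[128]
  encodeVec <- function(v) {
    if (any(v != floor(v)))
      stop("toMinifloat8 needs integer-valued input")
    a <- pmin(abs(v), maxVal)
    ## nearest representable, ties toward the larger magnitude (away from 0)
    hi <- findInterval(a, tab, rightmost.closed = FALSE, all.inside = TRUE)
    lo <- tab[hi]; up <- tab[hi + 1L]
    code <- ifelse(a - lo < up - a, hi - 1L, hi)  # tie -> larger
    code <- ifelse(a >= maxVal, 127L, code)
    neg <- v < 0 & tab[code + 1L] > 0
    as.integer(code + ifelse(neg, 128L, 0L))
  }
  decodeMap <- c(tab, -tab)  # codes 0:255
  decode <- function(codes) decodeMap[codes + 1L]
  if (is(x, "DetectorFrame") || is(x, "FrameStack")) {
    codes <- encodeVec(as.vector(x@values))
    quant <- x
    quant@values[] <- decode(codes)
    list(codes = as.raw(codes), decodeMap = decodeMap, quantized = quant)
  } else {
    codes <- encodeVec(x)
    list(codes = as.raw(codes), decodeMap = decodeMap,
         quantized = decode(codes))
  }
}

#' Decode 8-bit minifloat codes
#' @param codes raw vector from [toMinifloat8()].
#' @return numeric vector of decoded values.
#' @export
fromMinifloat8 <- function(codes) {
  decodeMap <- c(.minifloatTable(), -.minifloatTable())
  decodeMap[as.integer(codes) + 1L]
}

#' Apply a QuantizationSpec to values, a frame or a stack
#'
#' Dispatch helper turning a declarative [QuantizationSpec-class] into the
#' corresponding operator call.
#'
#' @param x values, [DetectorFrame-class] or [FrameStack-class].
#' @param spec a [QuantizationSpec-class].
#' @return quantized object of the same type.
#' @export
applyQuantizer <- function(x, spec) {
  validObject(spec)
  switch(spec@mode,
         uniform = quantizeUniform(x, spec@step),
         msb = msbRound(x, spec@keepBits),
         minifloat8 = toMinifloat8(x)$quantized,
         photon = aduToPhotons(x, spec@gain, spec@offset))
}

## apply a value-wise function through frame/stack containers
.applyValues <- function(x, f) {
  if (is(x, "DetectorFrame") || is(x, "FrameStack")) {
    v <- f(as.vector(x@values))
    if (is.integer(x@values) && all(v == floor(v)) &&
        max(abs(v)) <= .Machine$integer.max)
      v <- as.integer(v)
    dim(v) <- dim(x@values)
    out <- x
    out@values <- v
    out
  } else f(x)
}
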