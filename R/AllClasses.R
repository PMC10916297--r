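#' @import methods
NULL

#' Detector and beam geometry for a single rectangular panel
#'
#' Describes one flat rectangular detector panel normal to the beam, plus the
#' photon energy. The scattering-vector magnitude 1/d of any pixel is derived
#' from these fields; the X-ray wavelength is \code{12.398 / photonEnergy}
#' Angstrom with the energy in keV.
#'
#' @slot nFast,nSlow integer pixel counts along the fast and slow axes.
#' @slot pixelSize pixel edge length in meters.
#' @slot detectorDistance sample-to-detector distance in meters.
#' @slot beamCenterFast,beamCenterSlow beam center in (continuous) pixel
#'   coordinates; pixel \code{i}'s center sits at integer \code{i}, counting
#'   from 0.
#' @slot photonEnergy photon energy in keV.
#'
#' @seealso [geometryModel()] for the validated constructor, [pixelInvD()].
#' @name GeometryModel-class
#' @rdname GeometryModel-class
#' @exportClass GeometryModel
setClass("GeometryModel", representation(
  nFast = "integer", nSlow = "integer",
  pixelSize = "numeric", detectorDistance = "numeric",
  beamCenterFast = "numeric", beamCenterSlow = "numeric",
  photonEnergy = "numeric"
))

setValidity("GeometryModel", function(object) {
  msg <- character()
  pos <- c(nFast = object@nFast, nSlow = object@nSlow,
           pixelSize = object@pixelSize,
           detectorDistance = object@detectorDistance,
           photonEnergy = object@photonEnergy)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("strictly positive value required for: ",
                         paste(bad, collapse = ", ")))
  if (object@beamCenterFast < -0.5 || object@beamCenterFast > object@nFast - 0.5 ||
      object@beamCenterSlow < -0.5 || object@beamCenterSlow > object@nSlow - 0.5)
    msg <- c(msg, "beam center must lie inside the panel")
  if (length(msg)) msg else TRUE
})

#' Construct a GeometryModel
#'
#' @param nFast,nSlow panel size in pixels.
#' @param pixelSize pixel size in meters.
#' @param detectorDistance detector distance in meters.
#' @param beamCenterFast,beamCenterSlow beam center in pixels; defaults to the
#'   panel center.
#' @param photonEnergy photon energy in keV.
#' @return a [GeometryModel-class] object.
#' @examples
#' geo <- geometryModel(128, 128, pixelSize = 200e-6,
#'                      detectorDistance = 0.08, photonEnergy = 12.398)
#' wavelengthAngstrom(geo)
#' @export
geometryModel <- function(nFast, nSlow, pixelSize, detectorDistance,
                          beamCenterFast = (nFast - 1) / 2,
                          beamCenterSlow = (nSlow - 1) / 2,
                          photonEnergy = 12.398) {
  new("GeometryModel", nFast = as.integer(nFast), nSlow = as.integer(nSlow),
      pixelSize = pixelSize, detectorDistance = detectorDistance,
      beamCenterFast = beamCenterFast, beamCenterSlow = beamCenterSlow,
      photonEnergy = photonEnergy)
}

#' @describeIn GeometryModel-class X-ray wavelength in Angstrom.
#' @param geometry a [GeometryModel-class].
#' @export
wavelengthAngstrom <- function(geometry) 12.398 / geometry@photonEnergy

setMethod("show", "GeometryModel", function(object) {
  cat(sprintf("GeometryModel: %d x %d px, %.0f um pixels, %.3f m distance, %.3f keV (lambda %.3f A)\n",
              object@nFast, object@nSlow, object@pixelSize * 1e6,
              object@detectorDistance, object@photonEnergy,
              wavelengthAngstrom(object)))
})

## value kinds a frame may carry
.VALUE_KINDS <- c("photon_count_integer", "adu_real", "adu_integer")

#' A single 2D detector frame
#'
#' Holds one detector exposure: a pixel-value matrix (slow x fast), the kind of
#' value stored, a usability mask and a frame identifier. Counting detectors
#' store non-negative integer photon counts; integrating detectors store
#' calibrated ADU values which may be negative after dark subtraction.
#'
#' @slot values numeric or integer matrix, \code{nSlow x nFast}.
#' @slot valueKind one of \code{"photon_count_integer"}, \code{"adu_real"},
#'   \code{"adu_integer"}.
#' @slot mask logical matrix, same shape; \code{TRUE} = usable pixel. Masked
#'   pixels are excluded from every statistic computed by the package.
#' @slot frameId integer identifier.
#' @name DetectorFrame-class
#' @rdname DetectorFrame-class
#' @exportClass DetectorFrame
setClass("DetectorFrame", representation(
  values = "matrix", valueKind = "character", mask = "matrix",
  frameId = "integer"
))

setValidity("DetectorFrame", function(object) {
  msg <- character()
  if (!object@valueKind %in% .VALUE_KINDS)
    msg <- c(msg, paste0("valueKind must be one of: ",
                         paste(.VALUE_KINDS, collapse = ", ")))
  if (!identical(dim(object@values), dim(object@mask)))
    msg <- c(msg, "values and mask must have identical dimensions")
  if (!is.logical(object@mask))
    msg <- c(msg, "mask must be logical")
  if (object@valueKind == "photon_count_integer") {
    v <- object@values[object@mask]
    if (length(v) && any(v < 0, na.rm = TRUE))
      msg <- c(msg, "photon_count_integer values must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DetectorFrame
#'
#' @param values pixel matrix (slow x fast).
#' @param valueKind value kind string, see [DetectorFrame-class].
#' @param mask logical usability matrix; defaults to all usable.
#' @param frameId integer id.
#' @return a [DetectorFrame-class].
#' @export
detectorFrame <- function(values, valueKind = "photon_count_integer",
                          mask = NULL, frameId = 0L) {
  values <- as.matrix(values)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(values), ncol(values))
  new("DetectorFrame", values = values, valueKind = valueKind,
      mask = mask, frameId = as.integer(frameId))
}

setMethod("show", "DetectorFrame", function(object) {
  v <- object@values[object@mask]
  cat(sprintf("DetectorFrame #%d: %d x %d [%s], %d masked px, range [%g, %g]\n",
              object@frameId, nrow(object@values), ncol(object@values),
              object@valueKind, sum(!object@mask),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
})

#' A homogeneous stack of detector frames
#'
#' Frames of identical shape and value kind stored as one 3D array
#' (slow x fast x frame) with a shared usability mask. This is the unit the
#' reduction operators and the stack container work on.
#'
#' @slot values 3D array, slow x fast x frame.
#' @slot valueKind as in [DetectorFrame-class].
#' @slot mask shared logical matrix.
#' @slot frameIds integer vector, one id per frame.
#' @name FrameStack-class
#' @rdname FrameStack-class
#' @exportClass FrameStack
setClass("FrameStack", representation(
  values = "array", valueKind = "character", mask = "matrix",
  frameIds = "integer"
))

setValidity("FrameStack", function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L) msg <- c(msg, "values must be a 3D array")
  else {
    if (!identical(d[1:2], dim(object@mask)))
      msg <- c(msg, "mask shape must match frame shape")
    if (d[3] != length(object@frameIds))
      msg <- c(msg, "frameIds length must equal frame count")
  }
  if (!object@valueKind %in% .VALUE_KINDS)
    msg <- c(msg, "invalid valueKind")
  if (length(msg)) msg else TRUE
})

#' Construct a FrameStack
#' @param values 3D array (slow x fast x frame).
#' @param valueKind value kind string.
#' @param mask shared logical mask; defaults to all usable.
#' @param frameIds integer ids; default \code{0:(n-1)}.
#' @return a [FrameStack-class].
#' @export
frameStack <- function(values, valueKind = "photon_count_integer",
                       mask = NULL, frameIds = NULL) {
  d <- dim(values)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (is.null(frameIds)) frameIds <- seq_len(d[3]) - 1L
  new("FrameStack", values = values, valueKind = valueKind, mask = mask,
      frameIds = as.integer(frameIds))
}

#' @describeIn FrameStack-class number of frames.
#' @param x a FrameStack.
#' @export
nFrames <- function(x) dim(x@values)[3]

#' @describeIn FrameStack-class extract frame \code{i} as a [DetectorFrame-class].
#' @param i frame index (1-based).
#' @export
getFrame <- function(x, i) {
  detectorFrame(x@values[, , i, drop = TRUE], valueKind = x@valueKind,
                mask = x@mask, frameId = x@frameIds[i])
}

setMethod("show", "FrameStack", function(object) {
  d <- dim(object@values)
  cat(sprintf("FrameStack: %d frames of %d x %d [%s]\n",
              d[3], d[1], d[2], object@valueKind))
})

#' A list of Bragg peaks for one frame
#'
#' Positions use the continuous pixel convention: pixel \code{i}'s center is at
#' integer coordinate \code{i} and the pixel spans \code{[i - 0.5, i + 0.5)}.
#' The table is kept sorted by descending intensity.
#'
#' @slot peaks data.frame with columns \code{fastPos}, \code{slowPos},
#'   \code{intensity} (summed background-subtracted signal), \code{snr},
#'   \code{invD} (1/Angstrom), \code{nPixels}, \code{edge} (logical: component
#'   touched the panel border).
#' @slot frameId integer id of the frame the peaks belong to.
#' @name PeakList-class
#' @rdname PeakList-class
#' @exportClass PeakList
setClass("PeakList", representation(peaks = "data.frame", frameId = "integer"))

.PEAK_COLS <- c("fastPos", "slowPos", "intensity", "snr", "invD", "nPixels", "edge")

setValidity("PeakList", function(object) {
  msg <- character()
  if (!all(.PEAK_COLS %in% names(object@peaks)))
    msg <- c(msg, paste0("peaks must have columns: ",
                         paste(.PEAK_COLS, collapse = ", ")))
  else {
    p <- object@peaks
    if (nrow(p)) {
      if (any(p$snr < 0, na.rm = TRUE)) msg <- c(msg, "snr must be >= 0")
      if (is.unsorted(rev(p$intensity), strictly = FALSE))
        msg <- c(msg, "peaks must be sorted by descending intensity")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PeakList
#' @param peaks data.frame of peak rows (see [PeakList-class]); missing
#'   optional columns are filled with defaults. Rows are re-sorted by
#'   descending intensity.
#' @param frameId frame id.
#' @return a [PeakList-class].
#' @export
peakList <- function(peaks = NULL, frameId = 0L) {
  if (is.null(peaks) || nrow(peaks) == 0L) {
    peaks <- data.frame(fastPos = numeric(), slowPos = numeric(),
                        intensity = numeric(), snr = numeric(),
                        invD = numeric(), nPixels = integer(),
                        edge = logical())
  } else {
    if (is.null(peaks$snr)) peaks$snr <- 0
    if (is.null(peaks$invD)) peaks$invD <- 0
    if (is.null(peaks$nPixels)) peaks$nPixels <- 1L
    if (is.null(peaks$edge)) peaks$edge <- FALSE
    peaks <- peaks[order(-peaks$intensity), .PEAK_COLS, drop = FALSE]
    rownames(peaks) <- NULL
  }
  new("PeakList", peaks = peaks, frameId = as.integer(frameId))
}

#' @describeIn PeakList-class number of peaks.
#' @param x a PeakList.
#' @export
nPeaks <- function(x) nrow(x@peaks)

#' @describeIn PeakList-class the peak table as a data.frame.
#' @export
peakTable <- function(x) x@peaks

setMethod("show", "PeakList", function(object) {
  cat(sprintf("PeakList (frame #%d): %d peaks", object@frameId, nPeaks(object)))
  if (nPeaks(object))
    cat(sprintf(", I in [%.3g, %.3g], max 1/d %.3g 1/A",
                min(object@peaks$intensity), max(object@peaks$intensity),
                max(object@peaks$invD)))
  cat("\n")
})

#' Peak-finder parameters
#'
#' @slot snrMin per-pixel signal-to-noise threshold above the local background.
#' @slot minPix,maxPix allowed connected-component size in pixels.
#' @slot localBgInner,localBgOuter Chebyshev radii (pixels) of the annulus used
#'   for local background/sigma estimation around a candidate component.
#' @slot adcFloor minimum pixel value considered at all.
#' @name PeakFindParams-class
#' @rdname PeakFindParams-class
#' @exportClass PeakFindParams
setClass("PeakFindParams", representation(
  snrMin = "numeric", minPix = "integer", maxPix = "integer",
  localBgInner = "integer", localBgOuter = "integer", adcFloor = "numeric"
))

setValidity("PeakFindParams", function(object) {
  msg <- character()
  if (!(object@minPix >= 1L && object@minPix <= object@maxPix))
    msg <- c(msg, "need 0 < minPix <= maxPix")
  if (!(object@localBgInner < object@localBgOuter))
    msg <- c(msg, "need localBgInner < localBgOuter")
  if (object@snrMin <= 0) msg <- c(msg, "snrMin must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct PeakFindParams
#'
#' Defaults follow common SX practice (SNR 6, components of 2-40 pixels) and
#' are deliberately exposed: real experiments tune them per dataset.
#'
#' @param snrMin SNR threshold (default 6).
#' @param minPix,maxPix component size bounds (default 2, 40).
#' @param localBgInner,localBgOuter annulus radii in pixels (default 3, 6).
#' @param adcFloor minimum considered pixel value (default 1).
#' @return a [PeakFindParams-class].
#' @export
peakFindParams <- function(snrMin = 6, minPix = 2L, maxPix = 40L,
                           localBgInner = 3L, localBgOuter = 6L,
                           adcFloor = 1) {
  new("PeakFindParams", snrMin = snrMin, minPix = as.integer(minPix),
      maxPix = as.integer(maxPix), localBgInner = as.integer(localBgInner),
      localBgOuter = as.integer(localBgOuter), adcFloor = adcFloor)
}

#' Specification of one lossy quantization operator
#'
#' Exactly the parameters of the chosen mode are meaningful:
#' \describe{
#'   \item{uniform}{round to the nearest multiple of \code{step} ADU.}
#'   \item{msb}{round to the nearest value representable with \code{keepBits}
#'     most-significant binary digits (relative-precision quantizer).}
#'   \item{minifloat8}{requantize through the 1/5/2 8-bit float encoding.}
#'   \item{photon}{convert ADU to integer photons via \code{gain}/\code{offset}.}
#' }
#' All modes break ties away from zero so results are bit-reproducible.
#'
#' @slot mode one of \code{"uniform"}, \code{"msb"}, \code{"minifloat8"},
#'   \code{"photon"}.
#' @slot step ADU step (uniform mode).
#' @slot keepBits kept most-significant bits, 1..3 (msb mode).
#' @slot gain ADU per photon, \code{offset} ADU (photon mode).
#' @slot offset ADU offset (photon mode).
#' @name QuantizationSpec-class
#' @rdname QuantizationSpec-class
#' @exportClass QuantizationSpec
setClass("QuantizationSpec", representation(
  mode = "character", step = "numeric", keepBits = "integer",
  gain = "numeric", offset = "numeric"
))

setValidity("QuantizationSpec", function(object) {
  msg <- character()
  if (!object@mode %in% c("uniform", "msb", "minifloat8", "photon"))
    msg <- c(msg, "unknown quantization mode")
  if (object@mode == "uniform" && !(is.finite(object@step) && object@step > 0))
    msg <- c(msg, "uniform mode needs step > 0")
  if (object@mode == "msb" && !object@keepBits %in% 1:3)
    msg <- c(msg, "msb mode needs keepBits in {1, 2, 3}")
  if (object@mode == "photon" && !(is.finite(object@gain) && object@gain > 0))
    msg <- c(msg, "photon mode needs gain > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a QuantizationSpec
#' @param mode quantizer mode (see [QuantizationSpec-class]).
#' @param step uniform step in ADU.
#' @param keepBits kept most-significant bits (1, 2 or 3).
#' @param gain ADU per photon.
#' @param offset ADU offset subtracted before photon conversion.
#' @return a [QuantizationSpec-class].
#' @examples
#' quantizationSpec("msb", keepBits = 2)
#' quantizationSpec("uniform", step = 1024)
#' @export
quantizationSpec <- function(mode, step = NA_real_, keepBits = NA_integer_,
                             gain = NA_real_, offset = 0) {
  new("QuantizationSpec", mode = mode, step = step,
      keepBits = as.integer(keepBits), gain = gain, offset = offset)
}

setMethod("show", "QuantizationSpec", function(object) {
  cat("QuantizationSpec:", formatQuantizationSpec(object), "\n")
})

#' Short text form of a QuantizationSpec (used in reports and file metadata)
#' @param spec a [QuantizationSpec-class].
#' @return a single string such as \code{"msb:2"} or \code{"uniform:1024"}.
#' @export
formatQuantizationSpec <- function(spec) {
  switch(spec@mode,
         uniform = sprintf("uniform:%g", spec@step),
         msb = sprintf("msb:%d", spec@keepBits),
         minifloat8 = "minifloat8",
         photon = sprintf("photon:%g:%g", spec@gain, spec@offset))
}

#' Report of a reduction chain applied to a stack
#'
#' @slot framesIn,framesOut frame counts before and after the chain.
#' @slot chain character vector of applied operator tags, in order.
#' @slot distinctValuesOut number of distinct pixel values after the chain.
#' @slot maxAbsError,maxRelError largest absolute / relative pixel error versus
#'   the input values (0 for lossless chains; relative error over pixels with
#'   nonzero input).
#' @name ReductionReport-class
#' @rdname ReductionReport-class
#' @exportClass ReductionReport
setClass("ReductionReport", representation(
  framesIn = "integer", framesOut = "integer", chain = "character",
  distinctValuesOut = "numeric", maxAbsError = "numeric",
  maxRelError = "numeric"
))

setValidity("ReductionReport", function(object) {
  if (object@framesOut > object@framesIn)
    "framesOut cannot exceed framesIn" else TRUE
})

setMethod("show", "ReductionReport", function(object) {
  cat(sprintf("ReductionReport: %d -> %d frames | chain: %s | %g distinct values | max abs err %g, max rel err %g\n",
              object@framesIn, object@framesOut,
              if (length(object@chain)) paste(object@chain, collapse = " -> ") else "(identity)",
              object@distinctValuesOut, object@maxAbsError, object@maxRelError))
})

#' Lossless codec specification for the stack container
#'
#' Available codecs are those of base R's \code{memCompress}: \code{gzip},
#' \code{bzip2}, \code{xz}, plus \code{none}. The \code{level} slot records the
#' nominal level for reporting; the library default level is what runs
#' (gzip's default corresponds to level 6). An optional byte- or bit-shuffle
#' pre-filter regroups bytes (or bit planes) across elements before
#' compression, which typically helps on photon-count data.
#'
#' @slot name codec name.
#' @slot level nominal compression level (recorded, informational).
#' @slot shuffle one of \code{"none"}, \code{"byte"}, \code{"bit"}.
#' @name CodecSpec-class
#' @rdname CodecSpec-class
#' @exportClass CodecSpec
setClass("CodecSpec", representation(
  name = "character", level = "integer", shuffle = "character"
))

.CODECS <- c("gzip", "bzip2", "xz", "none")

setValidity("CodecSpec", function(object) {
  msg <- character()
  if (!object@name %in% .CODECS)
    msg <- c(msg, paste0("available codecs: ", paste(.CODECS, collapse = ", ")))
  if (!object@shuffle %in% c("none", "byte", "bit"))
    msg <- c(msg, "shuffle must be none, byte or bit")
  if (length(msg)) msg else TRUE
})

#' Construct a CodecSpec
#' @param name codec name: \code{"gzip"}, \code{"bzip2"}, \code{"xz"} or
#'   \code{"none"}.
#' @param level nominal level (informational).
#' @param shuffle pre-filter: \code{"none"}, \code{"byte"} or \code{"bit"}.
#' @return a [CodecSpec-class].
#' @export
codecSpec <- function(name = "gzip", level = 6L, shuffle = "none") {
  new("CodecSpec", name = name, level = as.integer(level), shuffle = shuffle)
}

setMethod("show", "CodecSpec", function(object) {
  cat(sprintf("CodecSpec: %s (level %d, shuffle %s)\n",
              object@name, object@level, object@shuffle))
})

#' Unmerged reflection observations
#'
#' One row per observation of a reflection on some pattern: Miller indices,
#' Friedel sign, intensity, its sigma, the pattern id and the reflection's
#' 1/d. When produced by the simulator, the per-reflection true intensities
#' are carried in the \code{truth} slot for oracle checks.
#'
#' @slot obs data.frame with columns \code{h, k, l} (integer),
#'   \code{friedelSign} (+1/-1), \code{intensity}, \code{sigma} (> 0),
#'   \code{patternId} (integer), \code{invD} (> 0, 1/Angstrom).
#' @slot truth data.frame with columns \code{h, k, l, iTrue} (possibly empty).
#' @name ObservationTable-class
#' @rdname ObservationTable-class
#' @exportClass ObservationTable
setClass("ObservationTable",
         representation(obs = "data.frame", truth = "data.frame"))

.OBS_COLS <- c("h", "k", "l", "friedelSign", "intensity", "sigma",
               "patternId", "invD")

setValidity("ObservationTable", function(object) {
  msg <- character()
  if (!all(.OBS_COLS %in% names(object@obs)))
    msg <- c(msg, paste0("obs must have columns: ",
                         paste(.OBS_COLS, collapse = ", ")))
  else {
    o <- object@obs
    if (nrow(o) < 1L) msg <- c(msg, "at least one observation required")
    else {
      if (any(o$sigma <= 0)) msg <- c(msg, "sigma must be > 0")
      if (any(o$invD <= 0)) msg <- c(msg, "invD must be > 0")
      if (!all(o$friedelSign %in% c(-1L, 1L)))
        msg <- c(msg, "friedelSign must be +1 or -1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ObservationTable
#' @param obs observation data.frame (see [ObservationTable-class]).
#' @param truth optional per-hkl truth data.frame.
#' @return an [ObservationTable-class].
#' @export
observationTable <- function(obs, truth = NULL) {
  if (is.null(truth))
    truth <- data.frame(h = integer(), k = integer(), l = integer(),
                        iTrue = numeric())
  new("ObservationTable", obs = obs, truth = truth)
}

#' @describeIn ObservationTable-class the observation rows as a data.frame.
#' @param x an ObservationTable.
#' @export
observations <- function(x) x@obs

#' @describeIn ObservationTable-class number of observation rows.
#' @export
nObservations <- function(x) nrow(x@obs)

setMethod("show", "ObservationTable", function(object) {
  o <- object@obs
  cat(sprintf("ObservationTable: %d observations, %d unique hkl, %d patterns, 1/d in [%.3g, %.3g]\n",
              nrow(o), nrow(unique(o[, c("h", "k", "l")])),
              length(unique(o$patternId)), min(o$invD), max(o$invD)))
})

#' Merged (per unique reflection) intensities
#'
#' @slot merged data.frame with one row per unique reflection (optionally per
#'   Friedel sign): \code{h, k, l}, \code{friedelSign} (0 when mates were
#'   merged together), \code{intensity} (mean), \code{sigma} (SD of the mean
#'   for multiplicity >= 2, else the propagated input sigma),
#'   \code{multiplicity}, \code{invD}.
#' @name MergedTable-class
#' @rdname MergedTable-class
#' @exportClass MergedTable
setClass("MergedTable", representation(merged = "data.frame"))

setValidity("MergedTable", function(object) {
  need <- c("h", "k", "l", "friedelSign", "intensity", "sigma",
            "multiplicity", "invD")
  if (!all(need %in% names(object@merged)))
    return(paste0("merged must have columns: ", paste(need, collapse = ", ")))
  if (nrow(object@merged) && any(object@merged$multiplicity < 1))
    return("multiplicity must be >= 1")
  TRUE
})

#' @describeIn MergedTable-class the merged rows as a data.frame.
#' @param x a MergedTable.
#' @export
mergedTable <- function(x) x@merged

setMethod("show", "MergedTable", function(object) {
  m <- object@merged
  cat(sprintf("MergedTable: %d unique reflections, mean multiplicity %.2f\n",
              nrow(m), mean(m$multiplicity)))
})

#' Resolution-shell scheme
#'
#' Shell boundaries are equally spaced in (1/d)^3 between \code{1/dMax} and
#' \code{1/dMin}, i.e. equal reciprocal-space volume per shell.
#'
#' @slot nShells shell count.
#' @slot dMin,dMax resolution limits in Angstrom (dMin = high-resolution edge).
#' @slot boundaries vector of nShells + 1 increasing 1/d boundaries.
#' @name ShellScheme-class
#' @rdname ShellScheme-class
#' @exportClass ShellScheme
setClass("ShellScheme", representation(
  nShells = "integer", dMin = "numeric", dMax = "numeric",
  boundaries = "numeric"
))

setValidity("ShellScheme", function(object) {
  msg <- character()
  if (object@dMin >= object@dMax) msg <- c(msg, "need dMin < dMax")
  if (length(object@boundaries) != object@nShells + 1L)
    msg <- c(msg, "boundaries must have nShells + 1 entries")
  if (is.unsorted(object@boundaries, strictly = TRUE))
    msg <- c(msg, "boundaries must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a ShellScheme
#' @param nShells number of shells.
#' @param dMin high-resolution limit in Angstrom.
#' @param dMax low-resolution limit in Angstrom.
#' @return a [ShellScheme-class].
#' @examples
#' shellScheme(10, dMin = 2, dMax = 20)
#' @export
shellScheme <- function(nShells, dMin, dMax) {
  s3 <- seq((1 / dMax)^3, (1 / dMin)^3, length.out = nShells + 1L)
  new("ShellScheme", nShells = as.integer(nShells), dMin = dMin, dMax = dMax,
      boundaries = s3^(1 / 3))
}

#' Assign reflections to resolution shells
#' @param invD vector of 1/d values (1/Angstrom).
#' @param shells a [ShellScheme-class].
#' @return integer shell index per value (NA outside the range; the outermost
#'   boundaries are inclusive).
#' @export
assignShell <- function(invD, shells) {
  idx <- findInterval(invD, shells@boundaries, rightmost.closed = TRUE)
  idx[idx < 1L | idx > shells@nShells] <- NA_integer_
  idx
}

setMethod("show", "ShellScheme", function(object) {
  cat(sprintf("ShellScheme: %d equal-volume shells, %.2f - %.2f A\n",
              object@nShells, object@dMax, object@dMin))
})
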