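## Per-tile robust background statistics: the panel is divided into square
## tiles and each unmasked pixel gets its tile's median and 1.4826*MAD.
## Tiles follow the smooth radial background closely enough for candidate
## screening; final peak statistics use a proper local annulus.
.tileStats <- function(values, mask, tile) {
  nS <- nrow(values); nF <- ncol(values)
  ti <- (seq_len(nS) - 1L) %/% tile
  tj <- (seq_len(nF) - 1L) %/% tile
  tileIdx <- outer(ti, tj * (max(ti) + 1L), "+") + 1L
  v <- values
  v[!mask] <- NA
  med <- tapply(as.vector(v), as.vector(tileIdx), stats::median, na.rm = TRUE)
  sig <- tapply(as.vector(v), as.vector(tileIdx), stats::mad, na.rm = TRUE)
  med[is.na(med)] <- 0; sig[is.na(sig)] <- 0
  list(bg = matrix(med[as.vector(tileIdx)], nS, nF),
       sigma = matrix(sig[as.vector(tileIdx)], nS, nF))
}

## Annulus pixels (Chebyshev distance in (inner, outer]) around a component's
## brightest pixel, excluding masked and candidate pixels.
.annulusValues <- function(values, exclude, mask, row, col, inner, outer) {
  nS <- nrow(values); nF <- ncol(values)
  rows <- max(1L, row - outer):min(nS, row + outer)
  cols <- max(1L, col - outer):min(nF, col + outer)
  dr <- abs(rows - row); dc <- abs(cols - col)
  cheb <- outer(dr, dc, pmax)
  sel <- cheb > inner & cheb <= outer
  block <- values[rows, cols, drop = FALSE]
  ok <- mask[rows, cols, drop = FALSE] & !exclude[rows, cols, drop = FALSE]
  block[sel & ok]
}

#' Find Bragg peaks on a detector frame
#'
#' Local-statistics peak finder in the spirit of the annulus-based finders
#' used in serial crystallography: a pixel is a candidate when its value
#' exceeds the local background by \code{snrMin} local (robust) sigmas and is
#' above \code{adcFloor}; 8-connected candidate components with a size inside
#' \code{[minPix, maxPix]} become peaks. For each component the background
#' and sigma are re-estimated from the surrounding annulus
#' (median and 1.4826 * MAD over unmasked, non-candidate pixels), the
#' intensity is the background-subtracted sum over the component, the
#' position its intensity-weighted centroid, and 1/d follows from the
#' geometry. Components touching the panel border are kept and flagged
#' \code{edge}. The result is deterministic for fixed input.
#'
#' Masked pixels never contribute to candidates, centroids, intensities or
#' background estimates.
#'
#' @param frame a [DetectorFrame-class].
#' @param geometry a [GeometryModel-class] matching the frame shape.
#' @param params a [PeakFindParams-class].
#' @return a [PeakList-class], sorted by descending intensity.
#' @examples
#' geo <- geometryModel(64, 64, 200e-6, 0.08)
#' v <- matrix(10, 64, 64)
#' v[30:34, 40:44] <- v[30:34, 40:44] +
#'   500 * outer(dnorm(-2:2, sd = 1.5), dnorm(-2:2, sd = 1.5)) / dnorm(0, sd = 1.5)^2
#' pk <- findPeaks(detectorFrame(round(v)), geo, peakFindParams())
#' peakTable(pk)
#' @export
findPeaks <- function(frame, geometry, params) {
  validObject(params)
  values <- frame@values
  mask <- frame@mask
  if (!any(mask)) stop("frame mask excludes every pixel")
  if (nrow(values) != geometry@nSlow || ncol(values) != geometry@nFast)
    stop("frame shape does not match geometry")

  tile <- max(2L * params@localBgOuter + 1L, 8L)
  st <- .tileStats(values, mask, tile)
  cand <- mask & values > params@adcFloor &
    (values - st$bg) > params@snrMin * pmax(st$sigma, 1e-9)
  if (!any(cand)) return(peakList(frameId = frame@frameId))

  labels <- EBImage::bwlabel(cand * 1)
  nComp <- max(labels)
  rows <- character(0)
  out <- vector("list", nComp)
  nS <- nrow(values); nF <- ncol(values)
  for (comp in seq_len(nComp)) {
    pix <- which(labels == comp)
    npx <- length(pix)
    if (npx < params@minPix || npx > params@maxPix) next
    pr <- ((pix - 1L) %% nS) + 1L
    pc <- ((pix - 1L) %/% nS) + 1L
    peakPix <- which.max(values[pix])
    ann <- .annulusValues(values, cand, mask, pr[peakPix], pc[peakPix],
                          params@localBgInner, params@localBgOuter)
    if (length(ann) >= 4L) {
      bg <- stats::median(ann)
      sg <- stats::mad(ann)
    } else {
      bg <- st$bg[pix[peakPix]]
      sg <- st$sigma[pix[peakPix]]
    }
    sg <- max(sg, 1e-9)
    sub <- values[pix] - bg
    intensity <- sum(sub)
    if (intensity <= 0) next
    w <- pmax(sub, 0)
    fast <- sum((pc - 1L) * w) / sum(w)
    slow <- sum((pr - 1L) * w) / sum(w)
    out[[comp]] <- data.frame(
      fastPos = fast, slowPos = slow, intensity = intensity,
      snr = intensity / (sg * sqrt(npx)),
      invD = pixelInvD(geometry, fast, slow),
      nPixels = npx,
      edge = any(pr == 1L | pr == nS | pc == 1L | pc == nF))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(peakList(frameId = frame@frameId))
  peakList(do.call(rbind, out), frameId = frame@frameId)
}

#' Classify a frame as a hit
#'
#' A frame is a hit when it carries at least \code{minPeaks} detected Bragg
#' peaks (inclusive comparison).
#'
#' @param peaks a [PeakList-class].
#' @param minPeaks required peak count (>= 1).
#' @return logical.
#' @export
isHit <- function(peaks, minPeaks = 10L) {
  stopifnot(minPeaks >= 1)
  nPeaks(peaks) >= minPeaks
}

#' Per-pattern achievable resolution
#'
#' The highest 1/d among a pattern's peaks, i.e. the resolution out to which
#' this single pattern shows detectable Bragg signal.
#'
#' @param peaks a [PeakList-class].
#' @return max 1/d in 1/Angstrom, or \code{NA_real_} for an empty list (an
#'   empty pattern has no defined resolution; never reported as 0).
#' @export
perPatternResolution <- function(peaks) {
  if (nPeaks(peaks) == 0L) return(NA_real_)
  max(peakTable(peaks)$invD)
}

#' Match detected peaks to ground-truth peaks
#'
#' Greedy nearest-neighbour matching within a pixel tolerance; each truth
#' peak is matched at most once. Used to score recall and false positives of
#' the peak finder against the simulator's truth.
#'
#' @param found,truth [PeakList-class] objects.
#' @param tol match tolerance in pixels (Euclidean).
#' @return list with \code{nMatched}, \code{recall}, \code{falsePositives}
#'   and the per-found match index (\code{NA} = unmatched).
#' @export
matchPeaks <- function(found, truth, tol = 2) {
  ft <- peakTable(found); tt <- peakTable(truth)
  match <- rep(NA_integer_, nrow(ft))
  used <- logical(nrow(tt))
  for (i in seq_len(nrow(ft))) {
    if (!nrow(tt)) break
    d2 <- (tt$fastPos - ft$fastPos[i])^2 + (tt$slowPos - ft$slowPos[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) && d2[j] <= tol^2) { match[i] <- j; used[j] <- TRUE }
  }
  list(nMatched = sum(!is.na(match)),
       recall = if (nrow(tt)) sum(used) / nrow(tt) else NA_real_,
       falsePositives = sum(is.na(match)),
       matchIndex = match)
}
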