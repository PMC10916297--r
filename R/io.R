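#' Compression accounting for one stored payload
#'
#' @slot rawBytes uncompressed payload size: frames x pixels x bytes per
#'   element.
#' @slot storedBytes bytes actually stored after the codec pipeline.
#' @slot ratio \code{rawBytes / storedBytes}.
#' @slot codec the [CodecSpec-class] used.
#' @slot valueKind value kind of the payload.
#' @slot nFrames frame count.
#' @name CompressionReport-class
#' @rdname CompressionReport-class
#' @exportClass CompressionReport
setClass("CompressionReport", representation(
  rawBytes = "numeric", storedBytes = "numeric", ratio = "numeric",
  codec = "CodecSpec", valueKind = "character", nFrames = "integer"
))

setValidity("CompressionReport", function(object) {
  if (!(object@ratio > 0)) return("ratio must be > 0")
  TRUE
})

setMethod("show", "CompressionReport", function(object) {
  cat(sprintf("CompressionReport: %d frames [%s], %s %s/%s: %.0f -> %.0f bytes (CR %.2f)\n",
              object@nFrames, object@valueKind, object@codec@name,
              paste0("lvl", object@codec@level), object@codec@shuffle,
              object@rawBytes, object@storedBytes, object@ratio))
})

## ---- shuffle pre-filters ------------------------------------------------

#' Byte- and bit-shuffle pre-filters
#'
#' Reorders the serialized bytes of fixed-width elements so that equal-order
#' bytes (or bit planes) of all elements are contiguous. On slowly varying
#' integer data the high-order planes become long constant runs, which
#' general-purpose codecs then compress much better. Both transforms are
#' exactly invertible.
#'
#' @param r raw vector whose length is a multiple of \code{elemSize}.
#' @param elemSize element width in bytes.
#' @return the shuffled (or restored) raw vector.
#' @export
byteShuffle <- function(r, elemSize) {
  if (elemSize == 1L) return(r)
  as.vector(t(matrix(r, nrow = elemSize)))
}

#' @rdname byteShuffle
#' @export
byteUnshuffle <- function(r, elemSize) {
  if (elemSize == 1L) return(r)
  as.vector(t(matrix(r, ncol = elemSize)))
}

#' @rdname byteShuffle
#' @export
bitShuffle <- function(r, elemSize) {
  bits <- rawToBits(r)
  packBits(as.vector(t(matrix(bits, nrow = 8L * elemSize))), "raw")
}

#' @rdname byteShuffle
#' @export
bitUnshuffle <- function(r, elemSize) {
  bits <- rawToBits(r)
  packBits(as.vector(t(matrix(bits, ncol = 8L * elemSize))), "raw")
}

.applyShuffle <- function(r, shuffle, elemSize) {
  switch(shuffle, none = r,
         byte = byteShuffle(r, elemSize),
         bit = bitShuffle(r, elemSize))
}

.undoShuffle <- function(r, shuffle, elemSize) {
  switch(shuffle, none = r,
         byte = byteUnshuffle(r, elemSize),
         bit = bitUnshuffle(r, elemSize))
}

## ---- element (de)serialization ------------------------------------------

.dtypeOf <- function(x) {
  if (is.raw(x)) "raw" else if (is.logical(x)) "logical"
  else if (is.integer(x)) "integer" else "double"
}

.elemSize <- function(dtype) switch(dtype, raw = 1L, logical = 1L,
                                    integer = 4L, double = 8L)

.toRaw <- function(x, dtype) {
  switch(dtype,
         raw = as.raw(x),
         logical = as.raw(as.integer(x)),
         integer = writeBin(as.integer(x), raw(), size = 4L, endian = "little"),
         double = writeBin(as.double(x), raw(), size = 8L, endian = "little"))
}

.fromRaw <- function(r, dtype, n) {
  switch(dtype,
         raw = r,
         logical = as.logical(as.integer(r)),
         integer = readBin(r, "integer", n = n, size = 4L, endian = "little"),
         double = readBin(r, "double", n = n, size = 8L, endian = "little"))
}

.compressChunk <- function(r, codec, elemSize) {
  r <- .applyShuffle(r, codec@shuffle, elemSize)
  if (codec@name == "none") r else memCompress(r, type = codec@name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- the SXC1 container --------------------------------------------------
## Layout: magic "SXC1" | int32 header length | header JSON | per dataset,
## per chunk: int32 compressed length + blob. The header lists every dataset
## (name, dtype, dim, codec, chunk sizes) plus free-form metadata, so a
## reader needs nothing but this file.

.writeContainer <- function(path, datasets, meta = list()) {
  con <- file(path, "wb")
  on.exit(close(con))
  header <- list(format = "SXC1", version = 1L, meta = meta,
                 datasets = lapply(names(datasets), function(nm) {
                   d <- datasets[[nm]]
                   list(name = nm, dtype = d$dtype, dim = d$dim,
                        codec = d$codec@name, level = d$codec@level,
                        shuffle = d$codec@shuffle,
                        nChunks = length(d$chunks),
                        chunkElems = d$chunkElems)
                 }))
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  writeBin(charToRaw("SXC1"), con)
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  for (nm in names(datasets)) {
    for (blob in datasets[[nm]]$chunks) {
      writeBin(length(blob), con, size = 4L, endian = "little")
      writeBin(blob, con)
    }
  }
  invisible(path)
}

.readContainer <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 4L)
  if (!identical(rawToChar(magic), "SXC1"))
    stop("not an SXC1 container (expected datasets under magic 'SXC1'): ", path)
  nH <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
  if (!length(nH) || nH <= 0) stop("corrupt container header: ", path)
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", n = nH)),
                               simplifyDataFrame = FALSE)
  datasets <- list()
  for (ds in header$datasets) {
    chunks <- vector("list", ds$nChunks)
    for (i in seq_len(ds$nChunks)) {
      len <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
      if (!length(len)) stop("truncated container (missing chunk header): ", path)
      blob <- readBin(con, "raw", n = len)
      if (length(blob) != len)
        stop("truncated container (chunk shorter than declared): ", path)
      chunks[[i]] <- blob
    }
    n <- prod(unlist(ds$dim))
    dtype <- ds$dtype
    elemSize <- .elemSize(dtype)
    vals <- unlist(lapply(seq_along(chunks), function(i) {
      r <- chunks[[i]]
      if (ds$codec != "none") r <- memDecompress(r, type = ds$codec)
      r <- .undoShuffle(r, ds$shuffle, elemSize)
      .fromRaw(r, dtype, length(r) %/% elemSize)
    }), use.names = FALSE)
    if (length(vals) != n) stop("corrupt dataset ", ds$name, " in ", path)
    dim(vals) <- unlist(ds$dim)
    datasets[[ds$name]] <- vals
  }
  list(meta = header$meta, datasets = datasets)
}

## serialize an array into per-chunk compressed blobs
.makeDataset <- function(x, codec, chunkElems = length(x)) {
  dtype <- .dtypeOf(x)
  elemSize <- .elemSize(dtype)
  v <- as.vector(x)
  starts <- seq(1L, length(v), by = chunkElems)
  chunks <- lapply(starts, function(s) {
    r <- .toRaw(v[s:min(s + chunkElems - 1L, length(v))], dtype)
    .compressChunk(r, codec, elemSize)
  })
  list(dtype = dtype, dim = if (is.null(dim(x))) length(x) else dim(x),
       codec = codec, chunks = chunks, chunkElems = chunkElems)
}

#' Write a frame stack to a chunked, codec-compressed container
#'
#' Frames are stored chunk-per-\code{framesPerChunk} under dataset
#' \code{data}, the shared mask under \code{mask}, and free-form metadata —
#' including the lossy reduction chain applied upstream, so the provenance of
#' lossy steps is never lost — in the header. Compression accounting counts
#' the \code{data} payload only, so the mask and metadata never distort the
#' ratio.
#'
#' @param stack a [FrameStack-class].
#' @param path output file path.
#' @param codec a [CodecSpec-class].
#' @param framesPerChunk frames per compression chunk (default 1, so frames
#'   remain individually addressable during vetoing).
#' @param chain character vector describing the lossy chain already applied
#'   (recorded verbatim in the metadata).
#' @return a [CompressionReport-class] for the \code{data} dataset.
#' @examples
#' sim <- simulateDataset(frameSimConfig(geometry = geometryModel(32, 32, 2e-4, 0.08),
#'                                       nPeaks = 4L, seed = 1), 3)
#' f <- tempfile(fileext = ".sxc")
#' rep <- writeStack(sim$stack, f, codecSpec("gzip"))
#' rep
#' @export
writeStack <- function(stack, path, codec = codecSpec(), framesPerChunk = 1L,
                       chain = character()) {
  validObject(codec)
  d <- dim(stack@values)
  ds <- list(
    data = .makeDataset(stack@values, codec,
                        chunkElems = d[1] * d[2] * framesPerChunk),
    mask = .makeDataset(stack@mask, codecSpec("gzip")),
    frameIds = .makeDataset(stack@frameIds, codecSpec("none")))
  .writeContainer(path, ds,
                  meta = list(valueKind = stack@valueKind,
                              chain = as.list(chain),
                              framesPerChunk = framesPerChunk))
  stored <- sum(vapply(ds$data$chunks, length, numeric(1)))
  raw <- prod(d) * .elemSize(ds$data$dtype)
  new("CompressionReport", rawBytes = raw, storedBytes = stored,
      ratio = raw / stored, codec = codec, valueKind = stack@valueKind,
      nFrames = d[3])
}

#' Read a frame stack written by [writeStack()]
#'
#' @param path container path.
#' @return list with \code{stack} ([FrameStack-class], original value kind
#'   restored) and \code{meta} (including the recorded reduction
#'   \code{chain}). A missing mask dataset is replaced by an all-usable mask
#'   with a warning.
#' @export
readStack <- function(path) {
  cont <- .readContainer(path)
  if (is.null(cont$datasets$data))
    stop("unrecognized layout: expected datasets 'data' (+ optional 'mask', 'frameIds') in ", path)
  values <- cont$datasets$data
  mask <- cont$datasets$mask
  if (is.null(mask)) {
    warning("no mask stored; assuming every pixel usable")
    mask <- matrix(TRUE, dim(values)[1], dim(values)[2])
  }
  ids <- cont$datasets$frameIds %||% (seq_len(dim(values)[3]) - 1L)
  list(stack = frameStack(values, valueKind = cont$meta$valueKind,
                          mask = mask, frameIds = ids),
       meta = cont$meta)
}

#' Write per-frame peak lists in CXI-style padded arrays
#'
#' Stores \code{nPeaks} plus fixed-width arrays \code{peakXPosRaw} (fast),
#' \code{peakYPosRaw} (slow), \code{peakTotalIntensity}, \code{peakSNR} and
#' \code{peakInvD}, each padded to \code{maxPeaks} columns.
#'
#' @param path output path.
#' @param peakLists list of [PeakList-class] objects.
#' @param maxPeaks padded width; must be >= the longest list.
#' @param codec a [CodecSpec-class].
#' @return invisibly, the path.
#' @export
writePeaks <- function(path, peakLists, maxPeaks = NULL,
                       codec = codecSpec()) {
  n <- vapply(peakLists, nPeaks, integer(1))
  if (is.null(maxPeaks)) maxPeaks <- max(n, 1L)
  if (any(n > maxPeaks))
    stop(sprintf("maxPeaks = %d overflowed: longest peak list has %d peaks",
                 maxPeaks, max(n)))
  pad <- function(col) {
    m <- matrix(0, length(peakLists), maxPeaks)
    for (i in seq_along(peakLists)) {
      p <- peakTable(peakLists[[i]])
      if (nrow(p)) m[i, seq_len(nrow(p))] <- p[[col]]
    }
    m
  }
  ds <- list(nPeaks = .makeDataset(as.integer(n), codecSpec("none")),
             frameIds = .makeDataset(
               vapply(peakLists, function(p) p@frameId, integer(1)),
               codecSpec("none")),
             peakXPosRaw = .makeDataset(pad("fastPos"), codec),
             peakYPosRaw = .makeDataset(pad("slowPos"), codec),
             peakTotalIntensity = .makeDataset(pad("intensity"), codec),
             peakSNR = .makeDataset(pad("snr"), codec),
             peakInvD = .makeDataset(pad("invD"), codec))
  .writeContainer(path, ds, meta = list(kind = "cxi_peaks",
                                        maxPeaks = maxPeaks))
  invisible(path)
}

#' Read peak lists written by [writePeaks()]
#' @param path container path.
#' @return list of [PeakList-class] objects.
#' @export
readPeaks <- function(path) {
  cont <- .readContainer(path)
  d <- cont$datasets
  if (is.null(d$nPeaks) || is.null(d$peakXPosRaw))
    stop("unrecognized layout: expected datasets nPeaks/peakXPosRaw/... in ", path)
  lapply(seq_along(d$nPeaks), function(i) {
    ni <- d$nPeaks[i]
    if (ni == 0L) return(peakList(frameId = d$frameIds[i]))
    peakList(data.frame(
      fastPos = d$peakXPosRaw[i, seq_len(ni)],
      slowPos = d$peakYPosRaw[i, seq_len(ni)],
      intensity = d$peakTotalIntensity[i, seq_len(ni)],
      snr = d$peakSNR[i, seq_len(ni)],
      invD = d$peakInvD[i, seq_len(ni)],
      nPixels = 1L, edge = FALSE), frameId = d$frameIds[i])
  })
}

#' Survey lossless codecs on one stack
#'
#' Compresses the identical payload with each codec specification and
#' reports the achieved size and compression ratio. Deterministic codecs
#' give deterministic sizes. Codec specs that fail to run are skipped with a
#' warning.
#'
#' @param stack a [FrameStack-class].
#' @param codecs list of [CodecSpec-class] objects.
#' @param framesPerChunk frames per compression chunk.
#' @return data.frame with columns \code{codec, level, shuffle, rawBytes,
#'   storedBytes, ratio}.
#' @export
codecSurvey <- function(stack, codecs, framesPerChunk = 1L) {
  stopifnot(length(codecs) >= 1L)
  d <- dim(stack@values)
  rows <- lapply(codecs, function(codec) {
    res <- tryCatch({
      ds <- .makeDataset(stack@values, codec,
                         chunkElems = d[1] * d[2] * framesPerChunk)
      stored <- sum(vapply(ds$chunks, length, numeric(1)))
      raw <- prod(d) * .elemSize(ds$dtype)
      data.frame(codec = codec@name, level = codec@level,
                 shuffle = codec@shuffle, rawBytes = raw,
                 storedBytes = stored, ratio = raw / stored)
    }, error = function(e) {
      warning(sprintf("codec %s unavailable, skipped: %s",
                      codec@name, conditionMessage(e)))
      NULL
    })
    res
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}

#' Write / read an observation table as delimited text
#'
#' Tab-separated with a header line; columns exactly the
#' [ObservationTable-class] fields. The hidden truth (when present) goes to
#' a sidecar \code{<path>.truth} file.
#'
#' @param obs an [ObservationTable-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeObservations <- function(obs, path) {
  utils::write.table(observations(obs), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (nrow(obs@truth))
    utils::write.table(obs@truth, paste0(path, ".truth"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeObservations
#' @export
readObservations <- function(path) {
  o <- utils::read.table(path, header = TRUE, sep = "\t")
  tpath <- paste0(path, ".truth")
  truth <- if (file.exists(tpath))
    utils::read.table(tpath, header = TRUE, sep = "\t") else NULL
  observationTable(o, truth = truth)
}
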