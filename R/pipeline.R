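## Canonical operator order for reduction chains; chains declared out of this
## order are honored but flagged, since e.g. quantizing before vetoing can
## change which frames are retained.
.CANONICAL_ORDER <- c("veto", "bin", "photon", "uniform", "msb", "minifloat8")

#' Parse a reduction-chain step tag
#'
#' Tags: \code{"veto"}, \code{"bin:<b>"}, \code{"photon:<gain>[:<offset>]"},
#' \code{"uniform:<step>"}, \code{"msb:<k>"}, \code{"minifloat8"}.
#'
#' @param tag a single step string.
#' @return a list with \code{op} and parameters.
#' @export
parseChainStep <- function(tag) {
  parts <- strsplit(tag, ":", fixed = TRUE)[[1]]
  op <- parts[1]
  switch(op,
         veto = list(op = "veto"),
         bin = list(op = "bin", b = as.integer(parts[2])),
         photon = list(op = "photon", gain = as.numeric(parts[2]),
                       offset = if (length(parts) > 2) as.numeric(parts[3]) else 0),
         uniform = list(op = "uniform", step = as.numeric(parts[2])),
         msb = list(op = "msb", k = as.integer(parts[2])),
         minifloat8 = list(op = "minifloat8"),
         stop("unknown reduction step: ", tag))
}

#' Apply an ordered reduction chain to a frame stack
#'
#' Runs the declared lossy operators in order and accounts for the result:
#' frame counts, distinct output values and the worst-case pixel errors
#' versus the input (computed over frames surviving a veto). A chain
#' declared out of the canonical order veto - bin - photon/uniform -
#' msb/minifloat8 is honored but triggers a warning.
#'
#' @param stack a [FrameStack-class].
#' @param chain character vector of step tags, see [parseChainStep()]; empty
#'   chain is the (lossless) identity.
#' @param geometry a [GeometryModel-class] (needed by \code{veto}).
#' @param peakParams a [PeakFindParams-class] (veto).
#' @param minPeaks hit threshold (veto).
#' @return list with \code{stack} (reduced), \code{report}
#'   ([ReductionReport-class]) and \code{hits} (logical, when a veto ran).
#' @export
runReductionChain <- function(stack, chain = character(),
                              geometry = NULL,
                              peakParams = peakFindParams(),
                              minPeaks = 10L) {
  framesIn <- nFrames(stack)
  ops <- vapply(chain, function(tag) parseChainStep(tag)$op, character(1))
  if (length(ops) > 1L &&
      is.unsorted(match(ops, .CANONICAL_ORDER), strictly = FALSE))
    warning("reduction chain declared out of canonical order (",
            paste(.CANONICAL_ORDER, collapse = " -> "),
            "); applying as declared")
  hits <- NULL
  binFactor <- 1L
  current <- stack
  for (tag in chain) {
    step <- parseChainStep(tag)
    current <- switch(step$op,
      veto = {
        if (is.null(geometry)) stop("veto step needs a geometry")
        v <- vetoNonHits(current, geometry, peakParams, minPeaks)
        hits <- v$hits
        v$stack
      },
      bin = { binFactor <- binFactor * step$b; binStack(current, step$b) },
      photon = aduToPhotons(current, step$gain, step$offset),
      uniform = quantizeUniform(current, step$step),
      msb = msbRound(current, step$k),
      minifloat8 = toMinifloat8(current)$quantized)
  }
  ## error accounting vs the input, on the surviving frames, after undoing
  ## the (lossless, sum-preserving) spatial reduction where possible
  err <- c(abs = 0, rel = 0)
  if (length(chain)) {
    ref <- stack@values[, , if (is.null(hits)) seq_len(framesIn) else hits,
                        drop = FALSE]
    if (binFactor == 1L && identical(dim(ref), dim(current@values))) {
      dv <- abs(as.numeric(current@values) - as.numeric(ref))
      nz <- abs(as.numeric(ref)) > 0
      err <- c(abs = max(dv, 0),
               rel = if (any(nz)) max(dv[nz] / abs(as.numeric(ref))[nz]) else 0)
    } else if (any(ops %in% c("photon", "uniform", "msb", "minifloat8"))) {
      err <- c(abs = NA_real_, rel = NA_real_)  # lossy but not pixel-comparable
    }
  }
  report <- new("ReductionReport", framesIn = framesIn,
                framesOut = nFrames(current),
                chain = as.character(chain),
                distinctValuesOut = length(unique(as.vector(current@values))),
                maxAbsError = unname(err["abs"]),
                maxRelError = unname(err["rel"]))
  list(stack = current, report = report, hits = hits)
}

## ---- configuration ------------------------------------------------------

.frameSimFromList <- function(cfg) {
  geo <- cfg$geometry %||% list()
  geometry <- geometryModel(
    nFast = geo$n_fast %||% 128L, nSlow = geo$n_slow %||% 128L,
    pixelSize = geo$pixel_size %||% 200e-6,
    detectorDistance = geo$detector_distance %||% 0.08,
    beamCenterFast = geo$beam_center_fast %||% ((geo$n_fast %||% 128L) - 1) / 2,
    beamCenterSlow = geo$beam_center_slow %||% ((geo$n_slow %||% 128L) - 1) / 2,
    photonEnergy = geo$photon_energy %||% 12.398)
  frameSimConfig(
    geometry = geometry,
    bgAmplitude = cfg$background_amplitude %||% 4,
    bgFloor = cfg$background_floor %||% 1,
    bgWidth = cfg$background_width %||% 60,
    nPeaks = cfg$n_peaks %||% 25L,
    minPeakSeparation = cfg$min_peak_separation %||% 8,
    peakSigma = cfg$peak_sigma %||% 1.2,
    peakMeanIntensity = cfg$peak_mean_intensity %||% 400,
    wilsonB = cfg$wilson_B %||% 15,
    hitRate = cfg$hit_rate %||% 0.3,
    detectorKind = cfg$detector_kind %||% "counting",
    gain = cfg$gain %||% 73.14,
    offset = cfg$offset %||% 0,
    readoutSigma = cfg$readout_sigma %||% 3,
    seed = cfg$seed %||% stop("config must set a seed"))
}

.obsSimFromList <- function(cfg) {
  obsSimConfig(
    nUniqueHkl = cfg$n_unique_hkl %||% 1000L,
    meanMultiplicity = cfg$mean_multiplicity %||% 8,
    wilsonI0 = cfg$wilson_i0 %||% 1000,
    wilsonB = cfg$wilson_B %||% 15,
    scaleJitterSd = cfg$scale_jitter_sd %||% 0.3,
    noiseSigma0 = cfg$noise_sigma0 %||% 5,
    noiseFrac = cfg$noise_frac %||% 0.05,
    anomalousFraction = cfg$anomalous_fraction %||% 0,
    dMin = cfg$d_min %||% 1.8, dMax = cfg$d_max %||% 20,
    nPatterns = cfg$n_patterns,
    seed = cfg$seed %||% stop("config must set a seed"))
}

.writeProvenance <- function(path, config, extra = list()) {
  prov <- c(list(configHash = unname(tools::md5sum(
                   if (is.character(config) && file.exists(config)) config
                   else { tf <- tempfile(); yaml::write_yaml(config, tf); tf })),
                 timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            extra)
  yaml::write_yaml(prov, path)
  invisible(path)
}

#' Simulate a dataset from a config and write it to disk
#'
#' Writes either a frame stack plus a hit truth table (frame mode) or an
#' observation table (observation mode), with a provenance sidecar
#' (config hash, seed, stage list) sufficient to reproduce the run.
#'
#' @param config a named list (or YAML file path) with keys \code{mode}
#'   (\code{"frames"} or \code{"observations"}), \code{n_frames}, the
#'   simulator fields (names as in [FrameSimConfig-class] /
#'   [ObsSimConfig-class], snake_case), \code{output} and a mandatory
#'   \code{seed}.
#' @return invisibly, a list of written paths and summary counts.
#' @export
runSimulate <- function(config) {
  cfgFile <- NULL
  if (is.character(config)) { cfgFile <- config; config <- yaml::read_yaml(config) }
  mode <- config$mode %||% "frames"
  out <- config$output %||% stop("config must set output")
  if (mode == "frames") {
    sim <- simulateDataset(.frameSimFromList(config),
                           config$n_frames %||% stop("config must set n_frames"))
    rep <- writeStack(sim$stack, out,
                      codec = codecSpec(config$codec %||% "gzip"))
    utils::write.table(sim$truth, paste0(out, ".truth.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    .writeProvenance(paste0(out, ".prov.yaml"), cfgFile %||% config,
                     list(seed = config$seed, stages = list("simulate"),
                          nFrames = nFrames(sim$stack),
                          nHits = sum(sim$truth$isHit)))
    message(sprintf("wrote %d frames (%d hits) to %s (CR %.2f)",
                    nFrames(sim$stack), sum(sim$truth$isHit), out, rep@ratio))
    invisible(list(stack = out, truth = paste0(out, ".truth.tsv"),
                   nFrames = nFrames(sim$stack), nHits = sum(sim$truth$isHit)))
  } else {
    obs <- simulateObservations(.obsSimFromList(config))
    writeObservations(obs, out)
    .writeProvenance(paste0(out, ".prov.yaml"), cfgFile %||% config,
                     list(seed = config$seed, stages = list("simulate"),
                          nObservations = nObservations(obs)))
    message(sprintf("wrote %d observations to %s", nObservations(obs), out))
    invisible(list(observations = out, nObservations = nObservations(obs)))
  }
}

#' Reduce a stored frame stack with a declared chain
#'
#' Reads a stack, applies the chain (see [runReductionChain()]), writes the
#' reduced stack with the chain recorded in its metadata, and reports the
#' per-stage frame counts plus the achieved compression ratio.
#'
#' @param config named list or YAML path: \code{input}, \code{output},
#'   \code{chain} (character vector), optional \code{codec},
#'   \code{geometry} (for veto), \code{peak_params}, \code{min_peaks},
#'   \code{seed}.
#' @return invisibly, a list with the [ReductionReport-class] and
#'   [CompressionReport-class].
#' @export
runReduce <- function(config) {
  cfgFile <- NULL
  if (is.character(config)) { cfgFile <- config; config <- yaml::read_yaml(config) }
  inp <- readStack(config$input %||% stop("config must set input"))
  geometry <- if (!is.null(config$geometry)) {
    g <- config$geometry
    geometryModel(g$n_fast, g$n_slow, g$pixel_size, g$detector_distance,
                  g$beam_center_fast %||% ((g$n_fast - 1) / 2),
                  g$beam_center_slow %||% ((g$n_slow - 1) / 2),
                  g$photon_energy %||% 12.398)
  } else NULL
  pp <- config$peak_params %||% list()
  red <- runReductionChain(inp$stack, config$chain %||% character(),
                           geometry = geometry,
                           peakParams = peakFindParams(
                             snrMin = pp$snr_min %||% 6,
                             minPix = pp$min_pix %||% 2L,
                             maxPix = pp$max_pix %||% 40L,
                             adcFloor = pp$adc_floor %||% 1),
                           minPeaks = config$min_peaks %||% 10L)
  out <- config$output %||% stop("config must set output")
  crep <- writeStack(red$stack, out, codec = codecSpec(config$codec %||% "gzip"),
                     chain = as.character(config$chain %||% character()))
  .writeProvenance(paste0(out, ".prov.yaml"), cfgFile %||% config,
                   list(seed = config$seed,
                        stages = as.list(config$chain %||% character()),
                        framesIn = red$report@framesIn,
                        framesOut = red$report@framesOut))
  message(sprintf("chain [%s]: %d -> %d frames, CR %.2f",
                  paste(config$chain %||% character(), collapse = ", "),
                  red$report@framesIn, red$report@framesOut, crep@ratio))
  invisible(list(reduction = red$report, compression = crep))
}

#' Compute merging metrics for a stored observation table
#'
#' @param config named list or YAML path: \code{input} (observation TSV),
#'   optional \code{n_shells}, \code{d_min}, \code{d_max}, \code{output}
#'   (machine-readable TSV of the per-shell table).
#' @return invisibly, the [mergingMetrics()] result.
#' @export
runMetrics <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  obs <- readObservations(config$input %||% stop("config must set input"))
  o <- observations(obs)
  shells <- shellScheme(config$n_shells %||% 10L,
                        dMin = config$d_min %||% (1 / max(o$invD)),
                        dMax = config$d_max %||% (1 / min(o$invD)))
  met <- mergingMetrics(obs, shells)
  tab <- merge(met$rSplit$byShell,
               met$ccHalf$byShell[, c("shell", "ccHalf")], by = "shell")
  tab$ccStar <- suppressMessages(ccStar(tab$ccHalf))
  fmt <- function(x) ifelse(is.na(x), "n/a", sprintf("%.4f", x))
  cat(sprintf("%5s %10s %10s %6s %8s %8s %8s\n", "shell", "1/d lo", "1/d hi",
              "n", "Rsplit", "CC1/2", "CC*"))
  for (i in seq_len(nrow(tab)))
    cat(sprintf("%5d %10.4f %10.4f %6d %8s %8s %8s\n", tab$shell[i],
                tab$invDLo[i], tab$invDHi[i], tab$n[i], fmt(tab$rSplit[i]),
                fmt(tab$ccHalf[i]), fmt(tab$ccStar[i])))
  cat(sprintf("overall: Rsplit %s, CC1/2 %s, CC* %s, CCano %s (%d common hkl)\n",
              fmt(met$rSplit$overall), fmt(met$ccHalf$overall),
              fmt(met$ccStar), fmt(met$ccAno$overall), met$rSplit$nCommon))
  if (!is.null(config$output))
    utils::write.table(tab, config$output, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  invisible(met)
}

#' Run the full synthetic degradation study
#'
#' Simulates a frame stack and an observation table, applies the ladder of
#' chains raw, bin, bin+msb3, bin+msb2, bin+msb1, and reports for each the
#' stored size / compression ratio (frames) next to the merging metrics
#' (observations with matching intensity quantization). This reproduces, on
#' synthetic data, the characteristic trade-off: compression ratio grows and
#' R_split degrades as fewer significant bits are kept.
#'
#' @param config named list or YAML path; keys: frame-simulator fields under
#'   \code{frames} (plus \code{n_frames}), observation fields under
#'   \code{observations}, optional \code{bin} factor (default 2),
#'   \code{codec}, \code{output}, mandatory \code{seed}.
#' @return the study data.frame (one row per chain): \code{chain,
#'   storedBytes, ratio, rSplit, ccHalf, ccStar, ccAno}.
#' @export
runStudy <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- config$seed %||% stop("config must set a seed")
  fcfg <- config$frames %||% list()
  fcfg$seed <- fcfg$seed %||% seed
  ocfg <- config$observations %||% list()
  ocfg$seed <- ocfg$seed %||% seed
  b <- config$bin %||% 2L
  codec <- codecSpec(config$codec %||% "gzip", shuffle = "byte")

  sim <- simulateDataset(.frameSimFromList(fcfg), fcfg$n_frames %||% 100L)
  obs <- simulateObservations(.obsSimFromList(ocfg))

  frameChains <- list(raw = character(),
                      bin = sprintf("bin:%d", b))
  for (k in 3:1)
    frameChains[[sprintf("bin+msb%d", k)]] <-
      c(sprintf("bin:%d", b), sprintf("msb:%d", k))
  obsChains <- list(raw = list(), bin = list())
  for (k in 3:1)
    obsChains[[sprintf("bin+msb%d", k)]] <-
      list(quantizationSpec("msb", keepBits = k))

  ## CR is always quoted against the original raw payload, so spatial
  ## reduction (binning) contributes to the ratio like in practice
  rawBytes <- prod(dim(sim$stack@values)) *
    .elemSize(.dtypeOf(sim$stack@values))
  sizes <- lapply(names(frameChains), function(nm) {
    red <- runReductionChain(sim$stack, frameChains[[nm]])
    survey <- codecSurvey(red$stack, list(codec))
    data.frame(chain = nm, storedBytes = survey$storedBytes,
               ratio = rawBytes / survey$storedBytes)
  })
  sizes <- do.call(rbind, sizes)
  qual <- qualityVsReduction(obs, obsChains)
  out <- cbind(sizes, qual[match(sizes$chain, qual$chain),
                           c("rSplit", "ccHalf", "ccStar", "ccAno")])
  rownames(out) <- NULL
  if (!is.null(config$output))
    utils::write.table(out, config$output, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  out
}
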