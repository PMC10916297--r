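#' Split observations into half-datasets by pattern
#'
#' Patterns are ranked by their (unique, sorted) pattern id; patterns with
#' even 0-based rank go to half A, odd ranks to half B. The split is a
#' deterministic function of the set of pattern ids, independent of row
#' order, so repeated runs give identical halves. A seeded random split is
#' available for sensitivity checks.
#'
#' @param obs an [ObservationTable-class] with at least 2 patterns.
#' @param random use a seeded random pattern assignment instead of rank
#'   parity.
#' @param seed seed for the random split.
#' @return list of two [ObservationTable-class] objects \code{a} and
#'   \code{b}; every observation lands in exactly one half.
#' @export
splitHalf <- function(obs, random = FALSE, seed = 1L) {
  o <- observations(obs)
  ids <- sort(unique(o$patternId))
  if (length(ids) < 2L)
    stop("split-half statistics need at least 2 patterns")
  if (random) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    inA <- sample(c(TRUE, FALSE), length(ids), replace = TRUE)
    if (all(inA) || all(!inA)) inA[1] <- !inA[1]
  } else {
    inA <- (seq_along(ids) - 1L) %% 2L == 0L
  }
  aIds <- ids[inA]
  sel <- o$patternId %in% aIds
  list(a = observationTable(o[sel, , drop = FALSE], truth = obs@truth),
       b = observationTable(o[!sel, , drop = FALSE], truth = obs@truth))
}

#' Merge unmerged observations per unique reflection
#'
#' Groups observations by Miller index (optionally keeping Friedel mates
#' separate) and reports the mean intensity, its uncertainty (sample SD of
#' the mean for multiplicity >= 2, otherwise the single observation's
#' propagated sigma), the multiplicity and 1/d.
#'
#' @param obs an [ObservationTable-class].
#' @param byFriedel keep the +hkl and -hkl mates separate (needed for
#'   anomalous statistics); default merges them together
#'   (\code{friedelSign = 0} in the output).
#' @return a [MergedTable-class].
#' @export
mergeObservations <- function(obs, byFriedel = FALSE) {
  o <- observations(obs)
  key <- if (byFriedel)
    interaction(o$h, o$k, o$l, o$friedelSign, drop = TRUE)
  else
    interaction(o$h, o$k, o$l, drop = TRUE)
  idx <- split(seq_len(nrow(o)), key)
  rows <- lapply(idx, function(i) {
    I <- o$intensity[i]
    n <- length(I)
    data.frame(h = o$h[i[1]], k = o$k[i[1]], l = o$l[i[1]],
               friedelSign = if (byFriedel) o$friedelSign[i[1]] else 0L,
               intensity = mean(I),
               sigma = if (n >= 2L) stats::sd(I) / sqrt(n)
                       else o$sigma[i],
               multiplicity = n,
               invD = mean(o$invD[i]))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- NULL
  new("MergedTable", merged = m)
}

## Inner join of two merged tables on (h, k, l[, friedelSign]).
.joinMerged <- function(A, B, byFriedel = FALSE) {
  a <- mergedTable(A); b <- mergedTable(B)
  keyCols <- if (byFriedel) c("h", "k", "l", "friedelSign") else c("h", "k", "l")
  ka <- do.call(paste, c(a[keyCols], sep = "/"))
  kb <- do.call(paste, c(b[keyCols], sep = "/"))
  common <- intersect(ka, kb)
  ia <- match(common, ka); ib <- match(common, kb)
  data.frame(h = a$h[ia], k = a$k[ia], l = a$l[ia],
             iA = a$intensity[ia], iB = b$intensity[ib],
             invD = (a$invD[ia] + b$invD[ib]) / 2)
}

#' R_split between two half-dataset merges
#'
#' The standard half-dataset disagreement statistic for merged intensities,
#' \deqn{R_{split} = \frac{1}{\sqrt{2}}
#'   \frac{\sum |I_A - I_B|}{\frac{1}{2}\sum (I_A + I_B)}}
#' computed over reflections present in both halves. The overall value uses
#' all common reflections (not a shell average); per-shell values are
#' reported when a [ShellScheme-class] is given. Reflections present in only
#' one half are excluded and counted.
#'
#' @param A,B [MergedTable-class] halves.
#' @param shells optional [ShellScheme-class].
#' @return list with \code{overall} (\code{NA} when the denominator is 0),
#'   \code{nCommon}, \code{nExcluded} and, with shells, a data.frame
#'   \code{byShell}.
#' @examples
#' # single reflection measured 100 vs 50:
#' # (1/sqrt(2)) * 50 / 75 = 0.4714
#' @export
rSplit <- function(A, B, shells = NULL) {
  j <- .joinMerged(A, B)
  if (nrow(j) < 1L) stop("no common reflections between halves")
  stat <- function(iA, iB) {
    den <- sum(iA + iB) / 2
    if (den == 0) NA_real_ else (1 / sqrt(2)) * sum(abs(iA - iB)) / den
  }
  out <- list(overall = stat(j$iA, j$iB), nCommon = nrow(j),
              nExcluded = nrow(mergedTable(A)) + nrow(mergedTable(B)) - 2L * nrow(j))
  if (!is.null(shells)) {
    sh <- assignShell(j$invD, shells)
    out$byShell <- data.frame(
      shell = seq_len(shells@nShells),
      invDLo = shells@boundaries[-(shells@nShells + 1L)],
      invDHi = shells@boundaries[-1L],
      n = as.vector(table(factor(sh, levels = seq_len(shells@nShells)))),
      rSplit = vapply(seq_len(shells@nShells), function(s) {
        i <- which(sh == s)
        if (!length(i)) NA_real_ else stat(j$iA[i], j$iB[i])
      }, numeric(1)))
  }
  out
}

#' CC1/2 between two half-dataset merges
#'
#' Pearson correlation of the merged mean intensities over reflections common
#' to both halves, overall and (optionally) per resolution shell. Shells with
#' fewer than 3 common reflections are reported as \code{NA}.
#'
#' @param A,B [MergedTable-class] halves.
#' @param shells optional [ShellScheme-class].
#' @return list with \code{overall}, \code{nCommon} and optionally
#'   \code{byShell}.
#' @export
ccHalf <- function(A, B, shells = NULL) {
  j <- .joinMerged(A, B)
  cc <- function(iA, iB) {
    if (length(iA) < 3L || stats::sd(iA) == 0 || stats::sd(iB) == 0)
      return(NA_real_)
    stats::cor(iA, iB)
  }
  out <- list(overall = cc(j$iA, j$iB), nCommon = nrow(j))
  if (!is.null(shells)) {
    sh <- assignShell(j$invD, shells)
    out$byShell <- data.frame(
      shell = seq_len(shells@nShells),
      invDLo = shells@boundaries[-(shells@nShells + 1L)],
      invDHi = shells@boundaries[-1L],
      n = as.vector(table(factor(sh, levels = seq_len(shells@nShells)))),
      ccHalf = vapply(seq_len(shells@nShells), function(s) {
        i <- which(sh == s)
        cc(j$iA[i], j$iB[i])
      }, numeric(1)))
  }
  out
}

#' CC* from CC1/2
#'
#' Analytic extrapolation of the half-dataset correlation to the correlation
#' of the full merged dataset with the (unknown) truth:
#' \eqn{CC^* = \sqrt{2 CC_{1/2} / (1 + CC_{1/2})}}. Defined here for
#' \eqn{CC_{1/2} > 0}; non-positive values return \code{NA} with a message
#' (a half-correlation this low carries no usable signal), and -1 is an
#' error.
#'
#' @param ccHalfValue CC1/2 in (-1, 1].
#' @return CC* or \code{NA_real_}.
#' @examples
#' ccStar(1)    # 1
#' ccStar(0.5)  # sqrt(2/3) = 0.8165
#' @export
ccStar <- function(ccHalfValue) {
  vapply(ccHalfValue, function(c1) {
    if (is.na(c1)) return(NA_real_)
    if (c1 <= -1 || c1 > 1) stop("CC1/2 must lie in (-1, 1]")
    if (c1 <= 0) {
      message("CC1/2 <= 0: CC* undefined, returning NA")
      return(NA_real_)
    }
    sqrt(2 * c1 / (1 + c1))
  }, numeric(1))
}

#' Anomalous correlation between half-datasets
#'
#' Pearson correlation of the Bijvoet differences
#' \eqn{\Delta I_{ano} = I(+) - I(-)} between the two halves, over
#' reflections whose both Friedel mates are present in both halves. A proxy
#' for the strength of the anomalous signal surviving a reduction chain.
#'
#' @param A,B [MergedTable-class] halves merged with
#'   \code{byFriedel = TRUE}.
#' @return list with \code{overall} (\code{NA} when fewer than 3 usable
#'   pairs) and \code{nPairs}.
#' @export
ccAno <- function(A, B) {
  dAno <- function(M) {
    m <- mergedTable(M)
    if (!any(m$friedelSign != 0L))
      stop("ccAno needs halves merged with byFriedel = TRUE")
    key <- paste(m$h, m$k, m$l, sep = "/")
    pl <- m$friedelSign == 1L
    plus <- m[pl, ]; minus <- m[!pl, ]
    common <- intersect(paste(plus$h, plus$k, plus$l, sep = "/"),
                        paste(minus$h, minus$k, minus$l, sep = "/"))
    ip <- match(common, paste(plus$h, plus$k, plus$l, sep = "/"))
    im <- match(common, paste(minus$h, minus$k, minus$l, sep = "/"))
    data.frame(key = common, dI = plus$intensity[ip] - minus$intensity[im])
  }
  da <- dAno(A); db <- dAno(B)
  common <- intersect(da$key, db$key)
  if (length(common) < 3L)
    return(list(overall = NA_real_, nPairs = length(common)))
  x <- da$dI[match(common, da$key)]
  y <- db$dI[match(common, db$key)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(overall = NA_real_, nPairs = length(common)))
  list(overall = stats::cor(x, y), nPairs = length(common))
}

#' Mean I/sigma(I) and completeness per resolution shell
#'
#' Completeness is the fraction of the reference reflection set observed in
#' the merged data, per shell and overall; I/sigma is the mean over observed
#' reflections. Shells with an empty reference are reported \code{NA}.
#'
#' @param merged a [MergedTable-class].
#' @param reference data.frame of theoretically measurable reflections with
#'   columns \code{h, k, l, invD}.
#' @param shells a [ShellScheme-class].
#' @return list with \code{overall} (completeness, meanIOverSigma) and
#'   \code{byShell} data.frame.
#' @export
snrAndCompleteness <- function(merged, reference, shells) {
  m <- mergedTable(merged)
  km <- paste(m$h, m$k, m$l, sep = "/")
  kr <- paste(reference$h, reference$k, reference$l, sep = "/")
  shM <- assignShell(m$invD, shells)
  shR <- assignShell(reference$invD, shells)
  obsRef <- km[km %in% kr]
  byShell <- do.call(rbind, lapply(seq_len(shells@nShells), function(s) {
    refS <- kr[which(shR == s)]
    mS <- which(shM == s)
    data.frame(shell = s,
               invDLo = shells@boundaries[s], invDHi = shells@boundaries[s + 1L],
               nRef = length(refS),
               nObs = length(mS),
               completeness = if (!length(refS)) NA_real_
                              else sum(refS %in% km) / length(refS),
               meanIOverSigma = if (!length(mS)) NA_real_
                                else mean(m$intensity[mS] / m$sigma[mS]))
  }))
  list(overall = list(completeness = sum(kr %in% km) / length(kr),
                      meanIOverSigma = mean(m$intensity / m$sigma)),
       byShell = byShell)
}

#' Merging-quality metrics of an observation table
#'
#' Convenience wrapper: split-half, merge both halves, and report R_split,
#' CC1/2, CC* and (when Friedel mates exist on both halves) CC_ano.
#'
#' @param obs an [ObservationTable-class].
#' @param shells optional [ShellScheme-class] for per-shell output.
#' @return list with \code{rSplit}, \code{ccHalf}, \code{ccStar},
#'   \code{ccAno} and the two halves' merge sizes.
#' @export
mergingMetrics <- function(obs, shells = NULL) {
  halves <- splitHalf(obs)
  A <- mergeObservations(halves$a)
  B <- mergeObservations(halves$b)
  rs <- rSplit(A, B, shells)
  cc <- ccHalf(A, B, shells)
  ano <- tryCatch({
    Af <- mergeObservations(halves$a, byFriedel = TRUE)
    Bf <- mergeObservations(halves$b, byFriedel = TRUE)
    ccAno(Af, Bf)
  }, error = function(e) list(overall = NA_real_, nPairs = 0L))
  list(rSplit = rs, ccHalf = cc,
       ccStar = suppressMessages(ccStar(cc$overall)),
       ccAno = ano,
       nMergedA = nrow(mergedTable(A)), nMergedB = nrow(mergedTable(B)))
}

#' Metric degradation along a list of quantization chains
#'
#' Applies each reduction chain to the observation intensities, re-merges and
#' reports the merging metrics, enabling the quantization-vs-quality study on
#' synthetic data. Chains are lists of [QuantizationSpec-class] (an empty
#' list is the unreduced baseline); intensities are rounded to integers
#' before integer-domain quantizers (msb, minifloat8) when needed.
#'
#' @param obs an [ObservationTable-class].
#' @param chains named list of chains; each chain is a list of
#'   [QuantizationSpec-class] objects applied in order.
#' @param shells optional [ShellScheme-class].
#' @return data.frame with one row per chain: \code{chain, rSplit, ccHalf,
#'   ccStar, ccAno, nCommon}.
#' @export
qualityVsReduction <- function(obs, chains, shells = NULL) {
  stopifnot(length(chains) >= 1L)
  if (is.null(names(chains)) || any(names(chains) == ""))
    names(chains) <- vapply(seq_along(chains), function(i) {
      ch <- chains[[i]]
      if (!length(ch)) "raw"
      else paste(vapply(ch, formatQuantizationSpec, character(1)),
                 collapse = "+")
    }, character(1))
  rows <- lapply(names(chains), function(nm) {
    o <- observations(obs)
    I <- o$intensity
    for (spec in chains[[nm]]) {
      if (spec@mode %in% c("msb", "minifloat8") && any(I != floor(I)))
        I <- .roundHalfAway(I)
      I <- applyQuantizer(I, spec)
    }
    o$intensity <- I
    met <- mergingMetrics(observationTable(o, truth = obs@truth), shells)
    data.frame(chain = nm,
               rSplit = met$rSplit$overall,
               ccHalf = met$ccHalf$overall,
               ccStar = met$ccStar,
               ccAno = met$ccAno$overall,
               nCommon = met$rSplit$nCommon)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
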