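#' Speed-resolved perfusion summary
#'
#' Session means of the three red-cell speed bands (< 1, 1-10, > 10 mm/s)
#' and total perfusion, plus each band's relative contribution in percent.
#' Relative contributions are computed against the SUM OF BAND MEANS (not
#' the total-perfusion channel), so the three shares always sum to exactly
#' 100 whenever any band is nonzero.
#'
#' @param session a \code{\linkS4class{RecordingSession}} with the three
#'   band channels (and \code{BP_TOTAL} for the total mean).
#' @return List of class \code{SpeedResolvedSummary}: \code{meanLow},
#'   \code{meanMid}, \code{meanHigh}, \code{meanTotal}, \code{relLow},
#'   \code{relMid}, \code{relHigh}, and \code{defined} (FALSE when all
#'   bands are zero, in which case the shares are NA and flagged).
#' @export
summarizeSpeedBands <- function(session) {
  lo <- mean(channelValues(session, "BP_LOW"))
  mi <- mean(channelValues(session, "BP_MID"))
  hi <- mean(channelValues(session, "BP_HIGH"))
  tot <- if ("BP_TOTAL" %in% rownames(channelMatrix(session)))
    mean(channelValues(session, "BP_TOTAL")) else lo + mi + hi
  s <- lo + mi + hi
  defined <- s > 0
  rel <- if (defined) 100 * c(lo, mi, hi) / s else rep(NA_real_, 3)
  structure(list(meanLow = lo, meanMid = mi, meanHigh = hi, meanTotal = tot,
                 relLow = rel[1], relMid = rel[2], relHigh = rel[3],
                 defined = defined),
            class = "SpeedResolvedSummary")
}

#' Hemoglobin-oxygenation summary
#'
#' Session means of red-cell fraction, oxygen saturation and the three
#' hemoglobin channels, plus the relative contributions of oxygenized and
#' reduced hemoglobin to total hemoglobin (shares of the sum of the two
#' means, so they sum to exactly 100) and their ratio.
#'
#' @param session a \code{\linkS4class{RecordingSession}} with the
#'   hemoglobin channels.
#' @return List of class \code{OxygenSummary} with means, \code{relOxy},
#'   \code{relRed}, \code{oxyRedRatio}, and \code{defined} (FALSE when
#'   total hemoglobin is zero).
#' @export
oxygenSummary <- function(session) {
  have <- rownames(channelMatrix(session))
  oxy <- mean(channelValues(session, "HB_OXY"))
  red <- mean(channelValues(session, "HB_RED"))
  tot <- if ("HB_TOTAL" %in% have)
    mean(channelValues(session, "HB_TOTAL")) else oxy + red
  s <- oxy + red
  defined <- s > 0
  relOxy <- if (defined) 100 * oxy / s else NA_real_
  relRed <- if (defined) 100 * red / s else NA_real_
  structure(list(
    meanCrbc = if ("CRBC" %in% have)
      mean(channelValues(session, "CRBC")) else NA_real_,
    meanSo2 = if ("SO2" %in% have)
      mean(channelValues(session, "SO2")) else NA_real_,
    meanHbTotal = tot, meanHbOxy = oxy, meanHbRed = red,
    relOxy = relOxy, relRed = relRed,
    oxyRedRatio = if (defined && relRed > 0) relOxy / relRed else NA_real_,
    defined = defined),
    class = "OxygenSummary")
}

#' Microcirculatory blood velocity
#'
#' \code{Mvel = Mbp / C_RBC}: mean perfusion divided by the red-cell
#' tissue fraction. \code{C_RBC} enters as the printed percent value (the
#' instrument's unit), not rescaled to a 0-1 fraction — the choice changes
#' Mvel by a factor 100, so it is fixed and documented here.
#'
#' @param mbp mean perfusion, %RBC.mm/s.
#' @param crbcPercent red-cell tissue fraction, percent (> 0).
#' @return Velocity in mm/s.
#' @examples
#' computeMvel(10, 2)  # 5
#' @export
computeMvel <- function(mbp, crbcPercent) {
  if (crbcPercent <= 0) stop("C_RBC must be positive")
  mbp / crbcPercent
}

#' Vasomotion frequency: oscillations per minute
#'
#' Counts complete perfusion oscillations on the mean-detrended series and
#' scales by 60 / duration. The counter is a robust upward mean-crossing
#' count: the detrended signal is lightly smoothed (moving average over
#' \code{smoothSeconds}) and an oscillation is registered each time it
#' rises above \code{+h} after having been below \code{-h}, with the
#' hysteresis band \code{h = hysteresisFrac * sd(smoothed)}. On a clean
#' sinusoid this equals the plain upward-crossing count; under noise the
#' band suppresses spurious double-crossings near zero.
#'
#' @param bpTotal numeric vector, the total-perfusion series, or a
#'   \code{\linkS4class{RecordingSession}} (its \code{BP_TOTAL} row).
#' @param samplingInterval seconds per sample (taken from the session when
#'   one is supplied).
#' @param smoothSeconds moving-average window, seconds (default 0.25).
#' @param hysteresisFrac hysteresis half-band in units of the smoothed
#'   signal's sd (default 0.5).
#' @return Oscillations per minute.
#' @examples
#' tt <- seq(0, 60 - 0.05, by = 0.05)
#' estimateMfre(sin(2 * pi * 0.5 * tt), 0.05)  # 30
#' @export
estimateMfre <- function(bpTotal, samplingInterval = NULL,
                         smoothSeconds = 0.25, hysteresisFrac = 0.5) {
  if (methods::is(bpTotal, "RecordingSession")) {
    samplingInterval <- samplingInterval %||% samplingInterval(bpTotal)
    bpTotal <- channelValues(bpTotal, "BP_TOTAL")
  }
  if (is.null(samplingInterval))
    stop("samplingInterval required when passing a bare vector")
  n <- length(bpTotal)
  if (n < 4) stop("insufficient duration: need at least 4 samples")
  x <- bpTotal - mean(bpTotal)
  win <- max(1L, round(smoothSeconds / samplingInterval))
  if (win > 1L) {
    x <- stats::filter(x, rep(1 / win, win), sides = 2)
    x <- x[!is.na(x)]
  }
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(0)
  h <- hysteresisFrac * s
  armed <- TRUE  # start ready to count the first rise
  count <- 0L
  for (v in x) {
    if (armed && v > h) { count <- count + 1L; armed <- FALSE }
    else if (!armed && v < -h) armed <- TRUE
  }
  duration <- n * samplingInterval
  count * 60 / duration
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Microvascular resistance index
#'
#' \code{IMR = Mbp / (Mvel * Mfre * S)}: mean perfusion over the product
#' of velocity, vasomotion frequency, and the microvessel diameter
#' constant S. The default S is 150 um expressed as 0.15 mm so that Mvel
#' (mm/s) and S share a length unit; pass \code{sUnit = "um"} to supply S
#' in micrometres directly. The composite index is reported unitless.
#'
#' @param mbp mean perfusion.
#' @param mvel velocity, mm/s (> 0).
#' @param mfre oscillations per minute (> 0).
#' @param sConstant microvessel diameter (default 0.15).
#' @param sUnit \code{"mm"} (default) or \code{"um"}; with \code{"um"} the
#'   value is converted to mm before use.
#' @return The resistance index.
#' @examples
#' computeImr(10, 5, 10, 0.15)  # 1.3333
#' @export
computeImr <- function(mbp, mvel, mfre, sConstant = 0.15,
                       sUnit = c("mm", "um")) {
  sUnit <- match.arg(sUnit)
  if (sUnit == "um") sConstant <- sConstant / 1000
  if (mvel <= 0 || mfre <= 0 || sConstant <= 0)
    stop("mvel, mfre and sConstant must all be positive")
  mbp / (mvel * mfre * sConstant)
}

#' Session-level hemodynamic indices
#'
#' Chains the scalar index formulas over session means: \code{Mbp} is the
#' time-mean of total perfusion, \code{Mvel = Mbp / mean(C_RBC)},
#' \code{Mfre} from \code{\link{estimateMfre}} on the total-perfusion
#' series, and \code{IMR = Mbp / (Mvel * Mfre * S)}.
#'
#' @param session a \code{\linkS4class{RecordingSession}} with
#'   \code{BP_TOTAL} and \code{CRBC}.
#' @param sConstant,sUnit passed to \code{\link{computeImr}}.
#' @param ... passed to \code{\link{estimateMfre}}.
#' @return List of class \code{HemodynamicIndices}: \code{mbp},
#'   \code{mvel}, \code{mfre}, \code{sConstant} (in mm), \code{imr}.
#' @export
sessionIndices <- function(session, sConstant = 0.15, sUnit = c("mm", "um"),
                           ...) {
  sUnit <- match.arg(sUnit)
  sMm <- if (sUnit == "um") sConstant / 1000 else sConstant
  mbp <- mean(channelValues(session, "BP_TOTAL"))
  mvel <- computeMvel(mbp, mean(channelValues(session, "CRBC")))
  mfre <- estimateMfre(session, ...)
  imr <- if (mvel > 0 && mfre > 0) mbp / (mvel * mfre * sMm) else NA_real_
  structure(list(mbp = mbp, mvel = mvel, mfre = mfre, sConstant = sMm,
                 imr = imr),
            class = "HemodynamicIndices")
}

#' Per-subject metric table for a cohort
#'
#' One row per session: group, subject, speed-band summary, oxygenation
#' summary and hemodynamic indices — the table behind group-level
#' descriptive comparisons and the bubble-chart payload.
#'
#' @param sessions list of \code{RecordingSession}s.
#' @param ... passed to \code{\link{sessionIndices}}.
#' @return data.frame with one row per subject.
#' @export
cohortMetrics <- function(sessions, ...) {
  do.call(rbind, lapply(sessions, function(s) {
    sb <- summarizeSpeedBands(s)
    ox <- oxygenSummary(s)
    hi <- sessionIndices(s, ...)
    data.frame(subjectId = subjectId(s), group = groupLabel(s),
               meanTotal = sb$meanTotal, meanLow = sb$meanLow,
               meanMid = sb$meanMid, meanHigh = sb$meanHigh,
               relLow = sb$relLow, relMid = sb$relMid, relHigh = sb$relHigh,
               meanCrbc = ox$meanCrbc, meanSo2 = ox$meanSo2,
               meanHbTotal = ox$meanHbTotal, meanHbOxy = ox$meanHbOxy,
               meanHbRed = ox$meanHbRed, relOxy = ox$relOxy,
               relRed = ox$relRed, oxyRedRatio = ox$oxyRedRatio,
               mbp = hi$mbp, mvel = hi$mvel, mfre = hi$mfre, imr = hi$imr,
               stringsAsFactors = FALSE)
  }))
}
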