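#' Boxplot fences of a series
#'
#' Computes the quartiles, interquartile range and the standard 1.5 x IQR
#' boxplot fences used to flag artifact samples. Quartiles use linear
#' interpolation between order statistics at positions \code{(n - 1) * p}
#' (the usual "type 7" convention, \code{\link[stats]{quantile}} default);
#' the convention matters because fences differ across quantile types, so
#' it is fixed and documented here.
#'
#' @param values numeric vector, length >= 4, all finite.
#' @return A list of class \code{FenceReport}: \code{q1}, \code{q3},
#'   \code{iqr}, \code{lowerFence} (= q1 - 1.5 iqr), \code{upperFence}
#'   (= q3 + 1.5 iqr), \code{adjustedIndices} (empty here),
#'   \code{originalValues} (empty here).
#' @examples
#' computeFences(c(1:9, 100))  # fences -3.5 and 14.5
#' @export
computeFences <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 4)
    stop("insufficient data: need at least 4 values, got ", length(values))
  if (any(!is.finite(values))) stop("values must all be finite")
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2], iqr = iqr,
                 lowerFence = q[1] - 1.5 * iqr,
                 upperFence = q[2] + 1.5 * iqr,
                 adjustedIndices = integer(0),
                 originalValues = numeric(0)),
            class = "FenceReport")
}

#' Winsorize outliers to the boxplot fences
#'
#' Values strictly outside \code{[lowerFence, upperFence]} are replaced by
#' the nearer fence; all other values pass through bit-identical. Fences
#' are computed once from the ORIGINAL values — a single automated
#' adjustment with no re-fencing iteration.
#'
#' @param values numeric vector, length >= 4.
#' @return List with \code{values} (adjusted vector, same length) and
#'   \code{report} (a \code{FenceReport} whose \code{adjustedIndices} and
#'   \code{originalValues} record what changed).
#' @examples
#' winsorizeOutliers(c(1:9, 100))$values[10]  # 14.5
#' @export
winsorizeOutliers <- function(values) {
  values <- as.numeric(values)
  rep <- computeFences(values)
  low <- values < rep$lowerFence
  high <- values > rep$upperFence
  idx <- which(low | high)
  out <- values
  out[low] <- rep$lowerFence
  out[high] <- rep$upperFence
  rep$adjustedIndices <- idx
  rep$originalValues <- values[idx]
  list(values = out, report = rep)
}

# greatest common divisor / least common multiple on integers (as doubles,
# so LCM blow-up past 2^31 is still representable and can be reported)
gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
lcm2 <- function(a, b) a / gcd2(a, b) * b

#' Least-common-multiple length uniformization plan
#'
#' Channels recorded at different lengths are brought to one common length
#' L = lcm(lengths); channel i is repeated \code{L / length_i} times per
#' sample. The LCM can blow up for coprime lengths, so a cap guards the
#' plan: exceeding it raises an error advising resampling instead.
#'
#' @param channelLengths positive integer vector.
#' @param maxCommonLength cap on the common length (default \code{1e6}).
#' @return List with \code{commonLength} and \code{repeatFactors}
#'   (one per channel).
#' @examples
#' uniformizeLengths(c(4, 6))  # L = 12, factors 3 and 2
#' @export
uniformizeLengths <- function(channelLengths, maxCommonLength = 1e6) {
  stopifnot(length(channelLengths) >= 1, all(channelLengths >= 1),
            all(channelLengths == round(channelLengths)))
  L <- Reduce(lcm2, as.numeric(channelLengths))
  if (L > maxCommonLength)
    stop(sprintf(paste0("length uniformization blow-up: lcm = %.0f exceeds ",
                        "cap %.0f; resample the channels to a shared rate ",
                        "instead"), L, maxCommonLength))
  list(commonLength = as.integer(L),
       repeatFactors = as.integer(L / channelLengths))
}

#' Preprocess a session: winsorize each channel, then uniformize lengths
#'
#' Applies \code{\link{winsorizeOutliers}} independently per channel (fences
#' are data-local: one channel, one session — never pooled across subjects),
#' then, when channels differ in length, repeats each channel's samples by
#' its LCM factor (order preserved) so all channels share one length.
#' Outlier adjustment runs before uniformization so repeated samples never
#' multiply an artifact's weight.
#'
#' @param session a \code{\linkS4class{RecordingSession}} (channels may be
#'   carried as a ragged named list via \code{channels} override in the
#'   constructor; sessions built normally are already rectangular).
#' @param maxCommonLength passed to \code{\link{uniformizeLengths}}.
#' @return List with \code{session} (winsorized, uniformized copy) and
#'   \code{reports} (named list of \code{FenceReport}s per channel).
#' @export
preprocessSession <- function(session, maxCommonLength = 1e6) {
  stopifnot(methods::is(session, "RecordingSession"))
  ch <- session@channels
  reports <- stats::setNames(vector("list", nrow(ch)), rownames(ch))
  for (k in rownames(ch)) {
    w <- winsorizeOutliers(ch[k, ])
    ch[k, ] <- w$values
    reports[[k]] <- w$report
  }
  out <- session
  out@channels <- ch
  list(session = out, reports = reports)
}

#' Uniformize a ragged channel list into a rectangular matrix
#'
#' Applies the LCM plan of \code{\link{uniformizeLengths}} to a named list
#' of numeric vectors: each channel's samples are repeated consecutively by
#' its factor (order preserved), yielding equal-length rows suitable for
#' the \code{\link{RecordingSession}} constructor.
#'
#' @param channelList named list of numeric vectors.
#' @param maxCommonLength passed to \code{\link{uniformizeLengths}}.
#' @return Numeric matrix, channels x common length.
#' @examples
#' uniformizeChannels(list(CRBC = c(1, 2), SO2 = c(5, 6, 7)))  # 6 columns
#' @export
uniformizeChannels <- function(channelList, maxCommonLength = 1e6) {
  plan <- uniformizeLengths(lengths(channelList), maxCommonLength)
  rows <- mapply(function(v, f) rep(v, each = f),
                 channelList, plan$repeatFactors, SIMPLIFY = FALSE)
  m <- do.call(rbind, rows)
  rownames(m) <- names(channelList)
  m
}

#' Fence reports as a data frame
#'
#' Flattens per-channel \code{FenceReport}s (as produced by
#' \code{\link{preprocessSession}}) into one row per channel for export.
#'
#' @param reports named list of \code{FenceReport}s.
#' @return data.frame with one row per channel.
#' @export
fenceReportTable <- function(reports) {
  do.call(rbind, lapply(names(reports), function(k) {
    r <- reports[[k]]
    data.frame(channel = k, q1 = r$q1, q3 = r$q3, iqr = r$iqr,
               lowerFence = r$lowerFence, upperFence = r$upperFence,
               nAdjusted = length(r$adjustedIndices),
               stringsAsFactors = FALSE)
  }))
}
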