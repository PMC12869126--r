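#' Dimensionless normalization methods
#'
#' Four standard transforms used to place heterogeneous microcirculatory
#' channels (percentages, micromolar concentrations, perfusion units) on a
#' common dimensionless scale before joint visualization:
#' \describe{
#'   \item{Z-score}{\code{x' = (x - mean(x)) / sigma}, with POPULATION
#'     standard deviation (divisor n). Output has mean 0 and population
#'     sd 1.}
#'   \item{min-max}{\code{x' = (x - min) / (max - min)}; output lies in
#'     [0, 1] with the endpoints mapped exactly to 0 and 1.}
#'   \item{L2}{\code{x'_i = x_i / ||x||} with \code{||x||} the Euclidean
#'     norm; the output vector has unit norm.}
#'   \item{median scaling}{\code{x' = x / Me} with \code{Me} the median
#'     (midpoint of the central order statistics for even n); the output
#'     has median 1.}
#' }
#' Degenerate inputs (constant series for Z-score/min-max, an all-zero
#' vector for L2, zero median for median scaling) raise a condition of
#' class \code{microcohere_degenerate} rather than returning NaN;
#' \code{\link{compareMethods}} converts these into "inapplicable" flags.
#'
#' @param values numeric vector (length >= 2 for zscore/minmax).
#' @return A list of class \code{NormalizationResult} with \code{method},
#'   \code{transformed} and \code{parameters} (the fitted quantities:
#'   mean/sd, min/max, norm, or median).
#' @examples
#' normalizeZscore(c(1, 2, 3))$transformed     # -1.2247, 0, 1.2247
#' normalizeMinmax(c(2, 4, 6))$transformed     # 0, 0.5, 1
#' normalizeL2(c(3, 4))$transformed            # 0.6, 0.8
#' normalizeMedian(c(2, 4, 8))$transformed     # 0.5, 1, 2
#' @name normalization
NULL

degenerate <- function(msg) {
  stop(structure(class = c("microcohere_degenerate", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

normResult <- function(method, transformed, parameters) {
  structure(list(method = method, transformed = transformed,
                 parameters = parameters), class = "NormalizationResult")
}

#' @rdname normalization
#' @export
normalizeZscore <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  m <- mean(values)
  s <- sqrt(mean((values - m)^2))  # population sd, divisor n
  if (s == 0) degenerate("constant input: Z-score undefined (sd = 0)")
  normResult("zscore", (values - m) / s, list(mean = m, sd = s))
}

#' @rdname normalization
#' @export
normalizeMinmax <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2) stop("need at least 2 values")
  lo <- min(values); hi <- max(values)
  if (hi == lo) degenerate("constant input: min-max undefined (max = min)")
  normResult("minmax", (values - lo) / (hi - lo), list(min = lo, max = hi))
}

#' @rdname normalization
#' @export
normalizeL2 <- function(values) {
  values <- as.numeric(values)
  nrm <- sqrt(sum(values^2))
  if (nrm == 0) degenerate("all-zero vector: L2 normalization undefined")
  normResult("l2", values / nrm, list(norm = nrm))
}

#' @rdname normalization
#' @export
normalizeMedian <- function(values) {
  values <- as.numeric(values)
  me <- stats::median(values)
  if (me == 0) degenerate("zero median: median scaling undefined")
  normResult("median", values / me, list(median = me))
}

#' Apply a normalization method by name
#'
#' @param values numeric vector.
#' @param method one of \code{"zscore"}, \code{"minmax"}, \code{"l2"},
#'   \code{"median"}.
#' @return A \code{NormalizationResult} (see \code{\link{normalization}}).
#' @export
normalizeValues <- function(values,
                            method = c("zscore", "minmax", "l2", "median")) {
  method <- match.arg(method)
  switch(method,
         zscore = normalizeZscore(values),
         minmax = normalizeMinmax(values),
         l2 = normalizeL2(values),
         median = normalizeMedian(values))
}

#' Compare the four normalization methods across channels
#'
#' Applies all four transforms to every channel and summarizes each
#' transformed series as a boxplot five-number record (whisker min, Q1,
#' median, Q3, whisker max), the convergence/dispersion view used to pick
#' the method whose outputs share one fixed bounded interval across
#' channels of wildly different scales. Channels degenerate under a method
#' are marked inapplicable for it, never fatal.
#'
#' The recommendation rule: min-max is recommended whenever every channel
#' normalizes under it without a degenerate error — it is the only method
#' with a fixed bounded output interval ([0, 1]) regardless of channel
#' units, which is what a common multichannel frame requires.
#'
#' @param channels named list of numeric vectors (>= 2 channels, each with
#'   >= 4 samples), or a \code{\linkS4class{RecordingSession}} (its channel
#'   rows are used), or a list of sessions (channels pooled by
#'   concatenation over the session timeline).
#' @return A list of class \code{MethodComparison}: \code{summary} (a
#'   data.frame with method, channel, applicable flag and the five-number
#'   summary) and \code{recommendedMethod}.
#' @export
compareMethods <- function(channels) {
  channels <- asChannelList(channels)
  if (length(channels) < 2) stop("need at least 2 channels")
  if (any(lengths(channels) < 4)) stop("each channel needs >= 4 samples")
  methodsAll <- c("zscore", "minmax", "l2", "median")
  rows <- list()
  minmaxOK <- TRUE
  for (m in methodsAll) {
    for (k in names(channels)) {
      res <- tryCatch(normalizeValues(channels[[k]], m),
                      microcohere_degenerate = function(e) NULL)
      if (is.null(res)) {
        if (m == "minmax") minmaxOK <- FALSE
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, channel = k, applicable = FALSE,
          whiskerMin = NA_real_, q1 = NA_real_, median = NA_real_,
          q3 = NA_real_, whiskerMax = NA_real_, stringsAsFactors = FALSE)
      } else {
        v <- res$transformed
        q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, channel = k, applicable = TRUE,
          whiskerMin = min(v), q1 = q[1], median = q[2], q3 = q[3],
          whiskerMax = max(v), stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(summary = do.call(rbind, rows),
                 recommendedMethod = if (minmaxOK) "minmax" else NA_character_),
            class = "MethodComparison")
}

# Coerce session(s) or a named list into a named list of numeric vectors.
asChannelList <- function(x) {
  if (methods::is(x, "RecordingSession")) {
    m <- channelMatrix(x)
    return(stats::setNames(lapply(rownames(m), function(k) m[k, ]),
                           rownames(m)))
  }
  if (is.list(x) && length(x) > 0 && methods::is(x[[1]], "RecordingSession")) {
    kinds <- Reduce(intersect, lapply(x, function(s) rownames(channelMatrix(s))))
    return(stats::setNames(lapply(kinds, function(k)
      unlist(lapply(x, channelValues, kind = k), use.names = FALSE)), kinds))
  }
  if (is.list(x) && !is.null(names(x))) return(lapply(x, as.numeric))
  stop("expected a named channel list, a RecordingSession, or a list of sessions")
}
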