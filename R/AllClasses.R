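#' Channel kinds of the combined LDF/DRS instrument
#'
#' The ten synchronized channels recorded by an enhanced perfusion and
#' oxygen saturation probe: red-blood-cell tissue fraction (\code{CRBC}, %),
#' oxygen saturation (\code{SO2}, %), total / oxygenized / reduced
#' hemoglobin (\code{HB_TOTAL}, \code{HB_OXY}, \code{HB_RED}, uM),
#' speed-resolved perfusion in three red-cell speed bands
#' (\code{BP_LOW} < 1 mm/s, \code{BP_MID} 1-10 mm/s, \code{BP_HIGH}
#' > 10 mm/s, %RBC.mm/s), total perfusion (\code{BP_TOTAL}, %RBC.mm/s)
#' and conventional laser-Doppler perfusion (\code{BP_CONV}, PU).
#'
#' @return \code{channelKinds()} returns the ten channel names in canonical
#'   order; \code{channelUnits()} returns a named character vector mapping
#'   each kind to its unit.
#' @examples
#' channelKinds()
#' channelUnits()["HB_TOTAL"]
#' @export
channelKinds <- function() {
  c("CRBC", "SO2", "HB_TOTAL", "HB_OXY", "HB_RED",
    "BP_LOW", "BP_MID", "BP_HIGH", "BP_TOTAL", "BP_CONV")
}

#' @rdname channelKinds
#' @export
channelUnits <- function() {
  c(CRBC = "%", SO2 = "%",
    HB_TOTAL = "uM", HB_OXY = "uM", HB_RED = "uM",
    BP_LOW = "%RBC.mm/s", BP_MID = "%RBC.mm/s", BP_HIGH = "%RBC.mm/s",
    BP_TOTAL = "%RBC.mm/s", BP_CONV = "PU")
}

#' Experimental group labels
#'
#' The six cohort arms of the disease/treatment design: healthy control,
#' type 2 diabetes mellitus (T2DM), and insulin- or liraglutide-treated
#' T2DM at one and two weeks.
#'
#' @return Character vector of the six group labels.
#' @examples
#' groupLabels()
#' @export
groupLabels <- function() {
  c("control", "t2dm", "insulin_1w", "insulin_2w",
    "liraglutide_1w", "liraglutide_2w")
}

#' RecordingSession: one subject's synchronized multichannel recording
#'
#' The pipeline's atomic data object. All channels share one implicit time
#' grid (index times \code{samplingInterval}); there are no per-channel
#' timestamps. The channel matrix holds one row per channel kind and one
#' column per sample.
#'
#' Structural validity (known channel names, a numeric matrix, a positive
#' sampling interval, a known group) is enforced by the class validity
#' method. Value-level physiological invariants (ranges, hemoglobin and
#' perfusion conservation, SO2 consistency) are checked by
#' \code{\link{validateSession}}, deliberately kept separate so that
#' sessions carrying instrument artifacts remain representable.
#'
#' @slot subjectId character scalar identifier.
#' @slot group one of \code{\link{groupLabels}}.
#' @slot channels numeric matrix, channels x time, rownames in
#'   \code{\link{channelKinds}}.
#' @slot samplingInterval sampling interval in seconds (> 0).
#' @slot tolerance relative tolerance used by conservation checks.
#' @aliases RecordingSession-class
#' @exportClass RecordingSession
setClass("RecordingSession",
  representation(
    subjectId = "character",
    group = "character",
    channels = "matrix",
    samplingInterval = "numeric",
    tolerance = "numeric"
  ),
  prototype(
    subjectId = "subject",
    group = "control",
    channels = matrix(numeric(0), nrow = 0, ncol = 0),
    samplingInterval = 0.1,
    tolerance = 1e-6
  )
)

setValidity("RecordingSession", function(object) {
  msgs <- character(0)
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msgs <- c(msgs, "subjectId must be a single non-NA string")
  if (length(object@group) != 1L || !(object@group %in% groupLabels()))
    msgs <- c(msgs, sprintf("group must be one of: %s",
                            paste(groupLabels(), collapse = ", ")))
  ch <- object@channels
  if (!is.numeric(ch))
    msgs <- c(msgs, "channels must be a numeric matrix")
  if (nrow(ch) > 0) {
    if (is.null(rownames(ch)) || !all(rownames(ch) %in% channelKinds()))
      msgs <- c(msgs, "channel rownames must be drawn from channelKinds()")
    if (anyDuplicated(rownames(ch)))
      msgs <- c(msgs, "duplicate channel names")
  }
  if (length(object@samplingInterval) != 1L ||
      !is.finite(object@samplingInterval) || object@samplingInterval <= 0)
    msgs <- c(msgs, "samplingInterval must be a single positive number")
  if (length(object@tolerance) != 1L || !is.finite(object@tolerance) ||
      object@tolerance < 0)
    msgs <- c(msgs, "tolerance must be a single nonnegative number")
  if (length(msgs)) msgs else TRUE
})

#' Construct a RecordingSession
#'
#' @param subjectId subject identifier.
#' @param group one of \code{\link{groupLabels}}.
#' @param channels numeric matrix (channels x time) with rownames in
#'   \code{\link{channelKinds}}, or a named list of equal-length numeric
#'   vectors which is bound into such a matrix.
#' @param samplingInterval sampling interval in seconds.
#' @param tolerance relative tolerance for conservation checks
#'   (default \code{1e-6}, suitable for synthetic data; raise it for
#'   noisy instrument exports).
#' @return A \code{\linkS4class{RecordingSession}} object.
#' @examples
#' s <- RecordingSession("m1", "control",
#'        list(CRBC = c(1, 1.1), SO2 = c(70, 71)), samplingInterval = 0.1)
#' nSamples(s)
#' @export
RecordingSession <- function(subjectId, group, channels,
                             samplingInterval = 0.1, tolerance = 1e-6) {
  if (is.list(channels)) {
    lens <- lengths(channels)
    if (length(unique(lens)) > 1L)
      stop("all channels must share one length (synchrony), got: ",
           paste(lens, collapse = ", "))
    channels <- do.call(rbind, lapply(channels, as.numeric))
    rownames(channels) <- names(lens)
  }
  methods::new("RecordingSession", subjectId = as.character(subjectId),
               group = as.character(group), channels = channels,
               samplingInterval = samplingInterval, tolerance = tolerance)
}

#' @rdname RecordingSession
#' @param x,object a \code{RecordingSession}.
#' @export
subjectId <- function(x) x@subjectId

#' @rdname RecordingSession
#' @export
groupLabel <- function(x) x@group

#' @rdname RecordingSession
#' @export
samplingInterval <- function(x) x@samplingInterval

#' @rdname RecordingSession
#' @export
channelMatrix <- function(x) x@channels

#' @rdname RecordingSession
#' @param kind a channel kind (see \code{\link{channelKinds}}).
#' @export
channelValues <- function(x, kind) {
  kind <- match.arg(kind, channelKinds())
  if (!kind %in% rownames(x@channels))
    stop("session has no channel ", kind)
  as.numeric(x@channels[kind, ])
}

#' @rdname RecordingSession
#' @export
nSamples <- function(x) ncol(x@channels)

#' @rdname RecordingSession
#' @export
sessionDuration <- function(x) ncol(x@channels) * x@samplingInterval

setMethod("show", "RecordingSession", function(object) {
  cat(sprintf("RecordingSession '%s' [%s]\n", object@subjectId, object@group))
  cat(sprintf("  %d channel(s) x %d samples @ %g s (%.1f s)\n",
              nrow(object@channels), ncol(object@channels),
              object@samplingInterval, sessionDuration(object)))
  cat("  channels:", paste(rownames(object@channels), collapse = ", "), "\n")
})

#' CoherenceMatrix: joint counts of binned perfusion and oxygen saturation
#'
#' A 10 x 10 (by default) contingency table counting synchronous time
#' points whose total perfusion and SO2 values fall in each pair of
#' intervals; the engine behind chord-diagram and association heat-map
#' payloads.
#'
#' @slot bpEdges ascending numeric bin edges for perfusion (length k+1).
#' @slot so2Edges ascending numeric bin edges for SO2 (length k+1).
#' @slot counts nonnegative integer matrix (perfusion bins x SO2 bins).
#' @slot group group label the counts were pooled over.
#' @slot nPairs total number of paired samples (= sum of counts).
#' @aliases CoherenceMatrix-class
#' @exportClass CoherenceMatrix
setClass("CoherenceMatrix",
  representation(
    bpEdges = "numeric",
    so2Edges = "numeric",
    counts = "matrix",
    group = "character",
    nPairs = "integer"
  )
)

setValidity("CoherenceMatrix", function(object) {
  msgs <- character(0)
  if (any(diff(object@bpEdges) <= 0) || any(diff(object@so2Edges) <= 0))
    msgs <- c(msgs, "bin edges must be strictly increasing")
  if (nrow(object@counts) != length(object@bpEdges) - 1L ||
      ncol(object@counts) != length(object@so2Edges) - 1L)
    msgs <- c(msgs, "counts dimensions must match the bin edges")
  if (any(object@counts < 0) || any(object@counts != round(object@counts)))
    msgs <- c(msgs, "counts must be nonnegative integers")
  if (sum(object@counts) != object@nPairs)
    msgs <- c(msgs, "sum(counts) must equal nPairs")
  if (length(msgs)) msgs else TRUE
})

#' @rdname CoherenceMatrix-class
#' @param x a \code{CoherenceMatrix}.
#' @export
coherenceCounts <- function(x) x@counts

#' @rdname CoherenceMatrix-class
#' @export
coherenceEdges <- function(x) list(bp = x@bpEdges, so2 = x@so2Edges)

#' @rdname CoherenceMatrix-class
#' @export
nPairs <- function(x) x@nPairs

setMethod("show", "CoherenceMatrix", function(object) {
  cat(sprintf("CoherenceMatrix [%s]: %d x %d bins, %d pairs\n",
              object@group, nrow(object@counts), ncol(object@counts),
              object@nPairs))
  cat(sprintf("  BP range [%g, %g], SO2 range [%g, %g]\n",
              min(object@bpEdges), max(object@bpEdges),
              min(object@so2Edges), max(object@so2Edges)))
})
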