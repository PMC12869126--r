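#' Equal-width bin edges over a value range
#'
#' Edges span [min, max] of the data (or an explicit override); ten
#' intervals by default, matching the chord-diagram convention of ten
#' intervals per half arc. Binning is half-open \code{[a, b)} with the
#' RIGHTMOST interval closed so the maximum is never lost.
#'
#' @param values numeric vector (ignored when \code{rangeOverride} given).
#' @param k number of intervals (>= 2; default 10).
#' @param rangeOverride optional c(min, max) to bin against a pooled range.
#' @return Numeric vector of k + 1 strictly increasing edges.
#' @examples
#' makeBins(c(0, 100))  # 0, 10, ..., 100
#' @export
makeBins <- function(values, k = 10, rangeOverride = NULL) {
  stopifnot(k >= 2)
  rng <- if (!is.null(rangeOverride)) as.numeric(rangeOverride)
         else range(as.numeric(values))
  if (diff(rng) <= 0)
    stop("degenerate range: max must exceed min (supply rangeOverride)")
  seq(rng[1], rng[2], length.out = k + 1)
}

# interval index under the half-open-left / closed-last rule; values
# outside the edges clamp to the end intervals (pooled-range use)
binIndex <- function(x, edges) {
  k <- length(edges) - 1L
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), k)
}

#' Joint histogram of synchronized perfusion and SO2
#'
#' Counts time points by the pair (perfusion interval, SO2 interval) —
#' the engine behind the association heat map and the chord diagram.
#' Count conservation holds by construction: the counts sum to the series
#' length.
#'
#' @param bp,so2 equal-length numeric vectors of synchronized samples, or
#'   a single \code{\linkS4class{RecordingSession}} passed as \code{bp}
#'   (its \code{BP_TOTAL} and \code{SO2} rows are used).
#' @param bpEdges,so2Edges bin edges from \code{\link{makeBins}}.
#' @param group group label carried on the result.
#' @return A \code{\linkS4class{CoherenceMatrix}}.
#' @export
jointHistogram <- function(bp, so2 = NULL, bpEdges, so2Edges,
                           group = "control") {
  if (methods::is(bp, "RecordingSession")) {
    group <- groupLabel(bp)
    so2 <- channelValues(bp, "SO2")
    bp <- channelValues(bp, "BP_TOTAL")
  }
  if (length(bp) != length(so2))
    stop("bp and so2 must have equal length (synchrony)")
  kb <- length(bpEdges) - 1L
  ks <- length(so2Edges) - 1L
  i <- binIndex(bp, bpEdges)
  j <- binIndex(so2, so2Edges)
  counts <- matrix(0L, kb, ks)
  tab <- table(factor(i, levels = seq_len(kb)), factor(j, levels = seq_len(ks)))
  counts[] <- as.integer(tab)
  methods::new("CoherenceMatrix", bpEdges = as.numeric(bpEdges),
               so2Edges = as.numeric(so2Edges), counts = counts,
               group = group, nPairs = length(bp))
}

#' Per-group coherence matrices on a pooled bin range
#'
#' Bin ranges are pooled across ALL groups before the per-group histograms
#' so that matrices are comparable group to group on shared intervals;
#' per-group ranges are available via \code{range = "per-group"}.
#'
#' @param sessions list of \code{RecordingSession}s.
#' @param k intervals per axis (default 10).
#' @param range \code{"pooled"} (default) or \code{"per-group"}.
#' @return Named list of \code{\linkS4class{CoherenceMatrix}} per group
#'   present in the cohort.
#' @export
groupCoherence <- function(sessions, k = 10, range = c("pooled", "per-group")) {
  range <- match.arg(range)
  groups <- unique(vapply(sessions, groupLabel, character(1)))
  allBp <- unlist(lapply(sessions, channelValues, kind = "BP_TOTAL"))
  allSo2 <- unlist(lapply(sessions, channelValues, kind = "SO2"))
  out <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    gs <- Filter(function(s) groupLabel(s) == g, sessions)
    bp <- unlist(lapply(gs, channelValues, kind = "BP_TOTAL"))
    so2 <- unlist(lapply(gs, channelValues, kind = "SO2"))
    if (range == "pooled") {
      be <- makeBins(allBp, k); se <- makeBins(allSo2, k)
    } else {
      be <- makeBins(bp, k); se <- makeBins(so2, k)
    }
    out[[g]] <- jointHistogram(bp, so2, be, se, group = g)
  }
  out
}

#' Chord-diagram payload from a coherence matrix
#'
#' Twenty arcs (one per interval per side) whose widths are the marginal
#' proportions, and one chord per nonzero joint cell whose width is the
#' joint proportion. Per-side arc widths and chord widths each sum to 1.
#' Raw counts are retained on every record so a consumer preferring
#' count-width chords can rescale.
#'
#' @param matrix a \code{\linkS4class{CoherenceMatrix}} with
#'   \code{nPairs > 0}.
#' @return List of class \code{ChordPayload}: \code{arcs} (data.frame:
#'   side, interval, label, width, count) and \code{chords} (data.frame:
#'   bpInterval, so2Interval, width, count), plus \code{group} and
#'   \code{nPairs}.
#' @export
chordPayload <- function(matrix) {
  stopifnot(methods::is(matrix, "CoherenceMatrix"))
  n <- nPairs(matrix)
  if (n == 0) stop("empty matrix: no pairs to lay out")
  cnt <- coherenceCounts(matrix)
  ed <- coherenceEdges(matrix)
  lab <- function(e, i) sprintf("[%.3g, %.3g%s", e[i], e[i + 1],
                                if (i == length(e) - 1) "]" else ")")
  kb <- nrow(cnt); ks <- ncol(cnt)
  arcs <- rbind(
    data.frame(side = "BP", interval = seq_len(kb),
               label = vapply(seq_len(kb), function(i) lab(ed$bp, i), ""),
               width = rowSums(cnt) / n, count = rowSums(cnt),
               stringsAsFactors = FALSE),
    data.frame(side = "SO2", interval = seq_len(ks),
               label = vapply(seq_len(ks), function(i) lab(ed$so2, i), ""),
               width = colSums(cnt) / n, count = colSums(cnt),
               stringsAsFactors = FALSE))
  nz <- which(cnt > 0, arr.ind = TRUE)
  chords <- data.frame(bpInterval = nz[, 1], so2Interval = nz[, 2],
                       width = cnt[nz] / n, count = cnt[nz])
  chords <- chords[order(chords$bpInterval, chords$so2Interval), ,
                   drop = FALSE]
  rownames(chords) <- NULL
  structure(list(arcs = arcs, chords = chords, group = matrix@group,
                 nPairs = n),
            class = "ChordPayload")
}

#' Filter a chord payload to selected intervals
#'
#' The interval-conditioned sub-diagrams (one perfusion interval's chords,
#' say) are derivable from the full payload by filtering; chord widths are
#' kept on the original all-pairs scale so filtered views remain
#' comparable.
#'
#' @param payload a \code{ChordPayload}.
#' @param bpIntervals,so2Intervals integer interval indices to keep
#'   (default: all).
#' @return A \code{ChordPayload} with the filtered chords.
#' @export
filterChords <- function(payload, bpIntervals = NULL, so2Intervals = NULL) {
  stopifnot(inherits(payload, "ChordPayload"))
  ch <- payload$chords
  if (!is.null(bpIntervals)) ch <- ch[ch$bpInterval %in% bpIntervals, ]
  if (!is.null(so2Intervals)) ch <- ch[ch$so2Interval %in% so2Intervals, ]
  payload$chords <- ch
  payload
}

#' Relevance-thresholded channel correlation report
#'
#' Pools all subjects' synchronized samples within a group (concatenation
#' over subjects), computes the Pearson correlation for every channel
#' pair, a two-sided p-value from the t statistic
#' \code{t = r * sqrt((n - 2) / (1 - r^2))}, and a relevance flag:
#' relevant iff \code{p < pThreshold} AND \code{|r| > rThreshold}
#' (defaults 0.05 and 0.4). No multiple-testing correction is applied —
#' the flag is a screening rule, not an inference procedure. Channels are
#' ordered by average-linkage hierarchical clustering on the distance
#' \code{1 - |r|}.
#'
#' @param sessions list of \code{RecordingSession}s (pooled; pass a single
#'   group's sessions for a per-group report).
#' @param group optional label: keep only sessions of this group.
#' @param rThreshold,pThreshold relevance thresholds.
#' @param linkage clustering linkage (default \code{"average"}).
#' @return List of class \code{CorrelationReport}: \code{r}, \code{p},
#'   \code{relevant} (channel x channel matrices), \code{n} (pooled sample
#'   count), \code{dendrogramOrder} (channel permutation), \code{group}.
#'   Pairs involving a constant channel carry NA r/p and a FALSE flag.
#' @export
correlateChannels <- function(sessions, group = NULL, rThreshold = 0.4,
                              pThreshold = 0.05, linkage = "average") {
  if (methods::is(sessions, "RecordingSession")) sessions <- list(sessions)
  if (!is.null(group))
    sessions <- Filter(function(s) groupLabel(s) == group, sessions)
  if (length(sessions) == 0) stop("no sessions for the requested group")
  chl <- asChannelList(sessions)
  n <- length(chl[[1]])
  if (n < 3) stop("need at least 3 pooled time points")
  kinds <- names(chl)
  X <- do.call(cbind, chl)
  constant <- apply(X, 2, function(v) stats::sd(v) == 0)
  r <- suppressWarnings(stats::cor(X))
  diag(r) <- 1
  r[constant, ] <- NA; r[, constant] <- NA
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  diag(p) <- 0
  relevant <- !is.na(r) & !is.na(p) & p < pThreshold & abs(r) > rThreshold
  diag(relevant) <- FALSE

  ord <- seq_along(kinds)
  ok <- !constant
  if (sum(ok) >= 2) {
    d <- stats::as.dist(1 - abs(r[ok, ok, drop = FALSE]))
    hc <- stats::hclust(d, method = linkage)
    ord <- c(which(ok)[hc$order], which(!ok))
  }
  structure(list(r = r, p = p, relevant = relevant, n = n,
                 dendrogramOrder = kinds[ord],
                 group = group %||% "pooled",
                 rThreshold = rThreshold, pThreshold = pThreshold),
            class = "CorrelationReport")
}
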