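#' Write a cohort to a wide CSV
#'
#' Canonical on-disk format: one row per (subject, time index), columns
#' \code{subject_id}, \code{group}, \code{time} (seconds) and one column
#' per channel kind present.
#'
#' @param sessions list of \code{RecordingSession}s (or a single one).
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSessionsCsv <- function(sessions, path) {
  if (methods::is(sessions, "RecordingSession")) sessions <- list(sessions)
  frames <- lapply(sessions, function(s) {
    m <- channelMatrix(s)
    df <- data.frame(subject_id = subjectId(s), group = groupLabel(s),
                     time = (seq_len(ncol(m)) - 1) * samplingInterval(s),
                     stringsAsFactors = FALSE)
    for (k in rownames(m)) df[[k]] <- m[k, ]
    df
  })
  kinds <- unique(unlist(lapply(frames, names)))
  frames <- lapply(frames, function(df) {
    for (k in setdiff(kinds, names(df))) df[[k]] <- NA_real_
    df[kinds]
  })
  utils::write.csv(do.call(rbind, frames), path, row.names = FALSE)
  invisible(path)
}

#' Read sessions from a wide CSV
#'
#' Reads the format written by \code{\link{writeSessionsCsv}}. A schema
#' mapping renames nonstandard column headers to the canonical names
#' (e.g. \code{c("C_RBC (%)" = "CRBC")}). Every session is validated in
#' lax mode; violations are reported via \code{warning} with counts, never
#' fatally. Unknown channel columns and malformed numeric cells raise
#' errors naming the offending column (and row).
#'
#' @param path CSV path.
#' @param schema optional named character vector: names are file column
#'   headers, values are canonical names (\code{subject_id}, \code{group},
#'   \code{time}, or a \code{\link{channelKinds}} entry).
#' @param tolerance conservation tolerance for the constructed sessions.
#' @return List of \code{RecordingSession}s.
#' @export
readSessionsCsv <- function(path, schema = NULL, tolerance = 1e-6) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (!is.null(schema)) {
    hit <- names(raw) %in% names(schema)
    names(raw)[hit] <- schema[names(raw)[hit]]
  }
  meta <- c("subject_id", "group", "time")
  for (m in setdiff(meta, names(raw)))
    stop("schema error: missing required column '", m, "'")
  chCols <- setdiff(names(raw), meta)
  unknown <- setdiff(chCols, channelKinds())
  if (length(unknown))
    stop("schema error: unknown channel column(s): ",
         paste(unknown, collapse = ", "))
  for (k in c("time", chCols)) {
    v <- suppressWarnings(as.numeric(raw[[k]]))
    bad <- which(is.na(v) & !is.na(raw[[k]]) & nzchar(raw[[k]]))
    if (length(bad))
      stop(sprintf("unparseable number in column '%s', row %d: '%s'",
                   k, bad[1], raw[[k]][bad[1]]))
    raw[[k]] <- v
  }
  sessions <- lapply(split(raw, raw$subject_id), function(df) {
    df <- df[order(df$time), , drop = FALSE]
    dt <- if (nrow(df) > 1) stats::median(diff(df$time)) else 0.1
    keep <- chCols[vapply(chCols, function(k) !all(is.na(df[[k]])), TRUE)]
    m <- t(as.matrix(df[keep]))
    dimnames(m) <- list(keep, NULL)
    RecordingSession(df$subject_id[1], df$group[1], m,
                     samplingInterval = dt, tolerance = tolerance)
  })
  sessions <- unname(sessions)
  nViol <- sum(vapply(sessions, function(s) nrow(validateSession(s)), 0L))
  if (nViol > 0)
    warning(sprintf("read %d session(s) with %d validation violation(s)",
                    length(sessions), nViol))
  sessions
}

#' Export per-group 3D surface frames
#'
#' One JSON frame per group: sample indices along the time axis, channel
#' labels along the variable axis, and the normalized values as the
#' height matrix (variable x time) — the payload a 3D surface viewer
#' renders. Subjects within a group are concatenated along the time axis.
#' A channel degenerate under the chosen normalization is dropped from the
#' frame with a warning.
#'
#' @param sessions list of \code{RecordingSession}s.
#' @param method normalization method name (default \code{"minmax"}).
#' @param dir output directory (created if needed).
#' @return Named character vector of written file paths per group.
#' @export
exportSurfaceJson <- function(sessions, method = "minmax", dir = ".") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  groups <- unique(vapply(sessions, groupLabel, character(1)))
  paths <- stats::setNames(character(length(groups)), groups)
  for (g in groups) {
    gs <- Filter(function(s) groupLabel(s) == g, sessions)
    chl <- asChannelList(gs)
    z <- list(); keep <- character(0)
    for (k in names(chl)) {
      res <- tryCatch(normalizeValues(chl[[k]], method),
                      microcohere_degenerate = function(e) NULL)
      if (is.null(res)) {
        warning(sprintf("channel %s degenerate under %s in group %s; dropped",
                        k, method, g))
      } else {
        z[[k]] <- res$transformed
        keep <- c(keep, k)
      }
    }
    zmat <- do.call(rbind, z)
    frame <- list(group = g, normalization = method,
                  axis_time = seq_len(ncol(zmat)) - 1L,
                  axis_variable = keep,
                  z_values = zmat)
    paths[g] <- file.path(dir, sprintf("surface_%s.json", g))
    jsonlite::write_json(frame, paths[g], digits = NA, auto_unbox = TRUE,
                         matrix = "rowmajor")
  }
  paths
}

#' Export a bubble-chart payload from a metric table
#'
#' One bubble per (group, metric): the group-mean value and a bubble size
#' obtained by mapping values linearly onto \code{sizeRange} within each
#' metric (so sizes are comparable across groups, and order-preserving).
#' All-equal values map to the midpoint size. Colors are keyed by group
#' label only; no rendering is performed.
#'
#' @param metricTable data.frame from \code{\link{cohortMetrics}}.
#' @param path output JSON path.
#' @param metrics metric column names to export (default: all numeric).
#' @param sizeRange c(min, max) bubble sizes.
#' @return The payload (data.frame), invisibly; JSON written to
#'   \code{path}.
#' @export
exportBubblePayload <- function(metricTable, path,
                                metrics = NULL, sizeRange = c(10, 60)) {
  if (nrow(metricTable) == 0) stop("empty metric table")
  if (is.null(metrics))
    metrics <- setdiff(names(metricTable)[vapply(metricTable, is.numeric, TRUE)],
                       c("time"))
  rows <- list()
  for (m in metrics) {
    agg <- tapply(metricTable[[m]], metricTable$group, mean, na.rm = TRUE)
    vals <- as.numeric(agg)
    rng <- range(vals, na.rm = TRUE)
    size <- if (diff(rng) == 0) rep(mean(sizeRange), length(vals))
            else sizeRange[1] + (vals - rng[1]) / diff(rng) * diff(sizeRange)
    rows[[m]] <- data.frame(group = names(agg), metric = m, value = vals,
                            size = size, stringsAsFactors = FALSE)
  }
  payload <- do.call(rbind, rows)
  rownames(payload) <- NULL
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(payload)
}

#' Export a chord payload as JSON
#'
#' Schema: named arcs (side, interval, label, width, count) plus weighted
#' links (bpInterval, so2Interval, width, count), with the group and pair
#' count — consumable by any chord renderer.
#'
#' @param payload a \code{ChordPayload}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
exportChordJson <- function(payload, path) {
  stopifnot(inherits(payload, "ChordPayload"))
  jsonlite::write_json(list(group = payload$group, nPairs = payload$nPairs,
                            arcs = payload$arcs, links = payload$chords),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Export a coherence matrix as JSON
#'
#' @param mat a \code{\linkS4class{CoherenceMatrix}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
exportCoherenceJson <- function(mat, path) {
  stopifnot(methods::is(mat, "CoherenceMatrix"))
  jsonlite::write_json(list(group = mat@group, nPairs = nPairs(mat),
                            bp_edges = mat@bpEdges, so2_edges = mat@so2Edges,
                            counts = coherenceCounts(mat)),
                       path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
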