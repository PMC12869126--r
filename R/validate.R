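#' Validate a RecordingSession against the instrument's channel semantics
#'
#' Checks the physiological invariants of a synchronized recording:
#' \itemize{
#'   \item all channels share one length (synchrony);
#'   \item \code{CRBC} and \code{SO2} lie in [0, 100];
#'   \item all perfusion and hemoglobin channels are nonnegative;
#'   \item hemoglobin conservation:
#'     \code{|HB_TOTAL - (HB_OXY + HB_RED)| <= tol * HB_TOTAL} elementwise;
#'   \item perfusion conservation:
#'     \code{|BP_TOTAL - (BP_LOW + BP_MID + BP_HIGH)| <= tol * BP_TOTAL};
#'   \item SO2 consistency: \code{|SO2 - 100 * HB_OXY / HB_TOTAL|} within an
#'     absolute tolerance wherever \code{HB_TOTAL > 0}.
#' }
#' Relative tolerances carry an absolute floor of \code{1e-9} so that
#' zero-valued samples do not force spurious violations.
#'
#' A missing mandatory channel for a derived check is reported as a
#' structural violation (\code{rule == "missing_channel"}), distinct from
#' value violations. The function is pure: two calls on the same session
#' return identical reports.
#'
#' @param session a \code{\linkS4class{RecordingSession}}.
#' @param strict if \code{TRUE}, stop at the first violation; otherwise
#'   return the full report.
#' @param requireAll require the complete ten-channel set (default
#'   \code{FALSE}: conservation checks are only run when their inputs are
#'   present).
#' @return A data.frame with columns \code{channel}, \code{index},
#'   \code{rule}, \code{value}; zero rows iff the session is valid.
#' @examples
#' cfg <- syntheticConfig(nSamples = 100, seed = 1)
#' s <- generateSession(cfg, "control", "m1")
#' nrow(validateSession(s))  # 0
#' @export
validateSession <- function(session, strict = FALSE, requireAll = FALSE) {
  stopifnot(methods::is(session, "RecordingSession"))
  ch <- session@channels
  if (nrow(ch) < 1L) stop("session has no channels")
  tol <- session@tolerance
  floorTol <- 1e-9
  rows <- list()
  emit <- function(channel, index, rule, value) {
    v <- data.frame(channel = channel, index = index, rule = rule,
                    value = value, stringsAsFactors = FALSE)
    if (strict && nrow(v) > 0)
      stop(sprintf("validation failed: %s at index %d of %s (value %g)",
                   v$rule[1], v$index[1], v$channel[1], v$value[1]))
    rows[[length(rows) + 1L]] <<- v
  }
  have <- rownames(ch)
  if (requireAll) {
    for (k in setdiff(channelKinds(), have))
      emit(k, NA_integer_, "missing_channel", NA_real_)
  }

  for (k in intersect(c("CRBC", "SO2"), have)) {
    bad <- which(ch[k, ] < 0 | ch[k, ] > 100)
    if (length(bad)) emit(k, bad, "range_0_100", ch[k, bad])
  }
  nonneg <- c("HB_TOTAL", "HB_OXY", "HB_RED",
              "BP_LOW", "BP_MID", "BP_HIGH", "BP_TOTAL", "BP_CONV")
  for (k in intersect(nonneg, have)) {
    bad <- which(ch[k, ] < 0)
    if (length(bad)) emit(k, bad, "nonnegative", ch[k, bad])
  }
  for (k in have) {
    bad <- which(!is.finite(ch[k, ]))
    if (length(bad)) emit(k, bad, "finite", ch[k, bad])
  }

  hbNeed <- c("HB_TOTAL", "HB_OXY", "HB_RED")
  if (all(hbNeed %in% have)) {
    resid <- abs(ch["HB_TOTAL", ] - (ch["HB_OXY", ] + ch["HB_RED", ]))
    bad <- which(resid > pmax(tol * abs(ch["HB_TOTAL", ]), floorTol))
    if (length(bad)) emit("HB_TOTAL", bad, "hb_conservation", resid[bad])
  } else if (any(hbNeed %in% have) && !requireAll) {
    for (k in setdiff(hbNeed, have))
      emit(k, NA_integer_, "missing_channel", NA_real_)
  }

  bpNeed <- c("BP_TOTAL", "BP_LOW", "BP_MID", "BP_HIGH")
  if (all(bpNeed %in% have)) {
    resid <- abs(ch["BP_TOTAL", ] -
                   (ch["BP_LOW", ] + ch["BP_MID", ] + ch["BP_HIGH", ]))
    bad <- which(resid > pmax(tol * abs(ch["BP_TOTAL", ]), floorTol))
    if (length(bad)) emit("BP_TOTAL", bad, "bp_conservation", resid[bad])
  } else if (any(bpNeed %in% have) && !requireAll) {
    for (k in setdiff(bpNeed, have))
      emit(k, NA_integer_, "missing_channel", NA_real_)
  }

  so2Need <- c("SO2", "HB_OXY", "HB_TOTAL")
  if (all(so2Need %in% have)) {
    pos <- ch["HB_TOTAL", ] > 0
    expect <- 100 * ch["HB_OXY", pos] / ch["HB_TOTAL", pos]
    resid <- abs(ch["SO2", pos] - expect)
    absTol <- pmax(100 * tol, floorTol)
    bad <- which(resid > absTol)
    if (length(bad)) emit("SO2", which(pos)[bad], "so2_consistency", resid[bad])
  }

  if (length(rows) == 0L)
    return(data.frame(channel = character(0), index = integer(0),
                      rule = character(0), value = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
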