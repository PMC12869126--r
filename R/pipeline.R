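#' Default pipeline configuration
#'
#' A small simulate-driven demo configuration: 3 subjects per group at 600
#' samples each, min-max normalization, pooled 10-bin coherence.
#'
#' @param seed master seed.
#' @return Config list accepted by \code{\link{runPipeline}}.
#' @export
defaultPipelineConfig <- function(seed = 1L) {
  list(
    simulate = list(nSamples = 600L, nPerGroup = 3L, seed = as.integer(seed)),
    normalization = "minmax",
    sConstant = 0.15,
    sUnit = "mm",
    bins = 10L,
    range = "pooled",
    stages = c("preprocess", "normalize", "metrics", "coherence", "export")
  )
}

readPipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  base <- defaultPipelineConfig()
  for (k in names(base)) if (is.null(config[[k]])) config[[k]] <- base[[k]]
  if (!config$normalization %in% c("zscore", "minmax", "l2", "median"))
    stop("config error: unknown normalization '", config$normalization, "'")
  if (!config$range %in% c("pooled", "per-group"))
    stop("config error: range must be 'pooled' or 'per-group'")
  if (is.null(config$input) && is.null(config$simulate))
    stop("config error: need either an 'input' CSV or a 'simulate' block")
  config
}

configHash <- function(config) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(yaml::as.yaml(config[order(names(config))]), tf)
  unname(tools::md5sum(tf))
}

pipelineLog <- function(...) message("[microcohere] ", sprintf(...))

#' Run the full analysis pipeline
#'
#' Executes simulate (or read) -> validate -> preprocess -> normalize ->
#' metrics -> coherence -> export in order, writing every artifact under
#' \code{outDir} together with a manifest (config hash, seed, package
#' version, file list). The pipeline is a pure function of (config, seed):
#' re-running with an identical config reproduces every artifact byte for
#' byte. Per-stage counts (sessions, outliers adjusted, degenerate
#' channels) are logged to stderr.
#'
#' @param config a config list (see \code{\link{defaultPipelineConfig}})
#'   or the path of a YAML file holding one. A \code{simulate} block
#'   (\code{nSamples}, \code{nPerGroup}, \code{seed}, plus any
#'   \code{\link{syntheticConfig}} override) generates the cohort; an
#'   \code{input} path reads one from CSV instead.
#' @param outDir artifact directory (created if needed).
#' @return Invisibly, a list with \code{sessions}, \code{metrics},
#'   \code{correlations}, \code{manifest} and \code{outDir}.
#' @export
runPipeline <- function(config, outDir = "microcohere_out") {
  config <- readPipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  keep <- function(p) { written <<- c(written, basename(p)); p }

  # --- acquire sessions ---------------------------------------------------
  if (!is.null(config$input)) {
    pipelineLog("reading sessions from %s", config$input)
    sessions <- readSessionsCsv(config$input)
  } else {
    sim <- config$simulate
    scArgs <- sim[setdiff(names(sim), "nPerGroup")]
    sc <- do.call(syntheticConfig, scArgs)
    sessions <- generateCohort(sc, nPerGroup = sim$nPerGroup %||% 3L)
    pipelineLog("simulated %d sessions (%d per group, %d samples)",
                length(sessions), sim$nPerGroup %||% 3L, sc$nSamples)
  }

  # --- validate -----------------------------------------------------------
  reports <- lapply(sessions, validateSession)
  nViol <- sum(vapply(reports, nrow, 0L))
  pipelineLog("validated %d sessions: %d violation(s)", length(sessions), nViol)
  viol <- do.call(rbind, Map(function(s, r) {
    if (nrow(r)) cbind(subject_id = subjectId(s), r) else NULL
  }, sessions, reports))
  if (is.null(viol))
    viol <- data.frame(subject_id = character(0), channel = character(0),
                       index = integer(0), rule = character(0),
                       value = numeric(0))
  utils::write.csv(viol, keep(file.path(outDir, "validation.csv")),
                   row.names = FALSE)

  # --- preprocess ---------------------------------------------------------
  fenceTables <- list()
  if ("preprocess" %in% config$stages) {
    pre <- lapply(sessions, preprocessSession)
    sessions <- lapply(pre, `[[`, "session")
    nAdj <- sum(vapply(pre, function(p)
      sum(vapply(p$reports, function(r) length(r$adjustedIndices), 0L)), 0L))
    pipelineLog("preprocess: %d outlier sample(s) adjusted", nAdj)
    fenceTables <- lapply(pre, function(p) fenceReportTable(p$reports))
    names(fenceTables) <- vapply(sessions, subjectId, character(1))
    jsonlite::write_json(fenceTables,
                         keep(file.path(outDir, "fence_reports.json")),
                         digits = NA, dataframe = "rows")
  }
  writeSessionsCsv(sessions, keep(file.path(outDir, "sessions.csv")))

  # --- normalize ----------------------------------------------------------
  if ("normalize" %in% config$stages) {
    cmp <- compareMethods(sessions)
    nDeg <- sum(!cmp$summary$applicable)
    pipelineLog("normalize: compared 4 methods, %d degenerate channel-method pair(s); recommended %s",
                nDeg, cmp$recommendedMethod)
    utils::write.csv(cmp$summary,
                     keep(file.path(outDir, "method_comparison.csv")),
                     row.names = FALSE)
  }

  # --- metrics ------------------------------------------------------------
  metrics <- NULL
  if ("metrics" %in% config$stages) {
    metrics <- cohortMetrics(sessions, sConstant = config$sConstant,
                             sUnit = config$sUnit)
    pipelineLog("metrics: %d subject rows", nrow(metrics))
    utils::write.csv(metrics, keep(file.path(outDir, "metrics.csv")),
                     row.names = FALSE)
  }

  # --- coherence ----------------------------------------------------------
  correlations <- list()
  if ("coherence" %in% config$stages) {
    mats <- groupCoherence(sessions, k = config$bins, range = config$range)
    for (g in names(mats)) {
      exportCoherenceJson(mats[[g]],
                          keep(file.path(outDir, sprintf("coherence_%s.json", g))))
      exportChordJson(chordPayload(mats[[g]]),
                      keep(file.path(outDir, sprintf("chord_%s.json", g))))
    }
    for (g in unique(vapply(sessions, groupLabel, character(1)))) {
      rep <- correlateChannels(sessions, group = g)
      correlations[[g]] <- rep
      utils::write.csv(as.data.frame(rep$r),
                       keep(file.path(outDir, sprintf("correlation_%s.csv", g))))
      utils::write.csv(as.data.frame(rep$relevant),
                       keep(file.path(outDir, sprintf("relevance_%s.csv", g))))
    }
    pipelineLog("coherence: %d group matrices, correlations on %d channels",
                length(mats), nrow(correlations[[1]]$r))
  }

  # --- export -------------------------------------------------------------
  if ("export" %in% config$stages) {
    sp <- exportSurfaceJson(sessions, method = config$normalization,
                            dir = outDir)
    for (p in sp) keep(p)
    if (!is.null(metrics))
      exportBubblePayload(metrics, keep(file.path(outDir, "bubbles.json")))
    pipelineLog("export: surfaces (%s) and bubble payload written",
                config$normalization)
  }

  # --- manifest -----------------------------------------------------------
  manifest <- list(
    package = "microcohere",
    version = as.character(utils::packageVersion("microcohere")),
    config = config,
    config_hash = configHash(config),
    seed = config$simulate$seed %||% NA_integer_,
    artifacts = sort(unique(written))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, pretty = TRUE)
  pipelineLog("done: %d artifacts in %s", length(manifest$artifacts), outDir)
  invisible(list(sessions = sessions, metrics = metrics,
                 correlations = correlations, manifest = manifest,
                 outDir = outDir))
}
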