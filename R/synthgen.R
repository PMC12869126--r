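#' Group effect profile for the synthetic cohort generator
#'
#' Encodes how one experimental arm deviates from the healthy-control
#' baseline: multiplicative effects on the three speed-resolved perfusion
#' bands, an additive shift of oxygen saturation (percentage points), and
#' multiplicative effects on red-cell tissue fraction and total hemoglobin,
#' plus the arm's vasomotion frequency in cycles per minute.
#'
#' @param perfusionMultipliers positive numeric, named \code{low}/\code{mid}/
#'   \code{high}.
#' @param so2Shift percentage-point shift of baseline SO2.
#' @param crbcMultiplier,hbMultiplier positive multipliers.
#' @param vasomotionFreq vasomotion rate, cycles per minute (>= 0).
#' @return A list of class \code{GroupEffectProfile}.
#' @export
groupEffectProfile <- function(perfusionMultipliers = c(low = 1, mid = 1, high = 1),
                               so2Shift = 0, crbcMultiplier = 1,
                               hbMultiplier = 1, vasomotionFreq = 15) {
  pm <- perfusionMultipliers
  stopifnot(all(c("low", "mid", "high") %in% names(pm)),
            all(pm > 0), crbcMultiplier > 0, hbMultiplier > 0,
            vasomotionFreq >= 0)
  structure(list(perfusionMultipliers = pm[c("low", "mid", "high")],
                 so2Shift = so2Shift, crbcMultiplier = crbcMultiplier,
                 hbMultiplier = hbMultiplier,
                 vasomotionFreq = vasomotionFreq),
            class = "GroupEffectProfile")
}

#' Default per-group effect profiles
#'
#' The control profile is all-ones / zero-shift with a 15 cycles/min
#' vasomotion rate. The T2DM profile carries the disease signature the
#' analysis is designed to detect: reduced perfusion in every speed band,
#' most strongly in the high-speed band (multiplier 0.6), oxygen
#' saturation shifted down 10 percentage points, reduced red-cell fraction
#' and hemoglobin (0.85), and slowed vasomotion (0.7 x control). Insulin
#' and liraglutide arms interpolate toward control with week-2 closer than
#' week-1, emulating partial treatment recovery.
#'
#' @return Named list mapping each of \code{\link{groupLabels}} to a
#'   \code{\link{groupEffectProfile}}.
#' @export
defaultGroupProfiles <- function() {
  list(
    control = groupEffectProfile(),
    t2dm = groupEffectProfile(c(low = 0.9, mid = 0.75, high = 0.6),
                              so2Shift = -10, crbcMultiplier = 0.85,
                              hbMultiplier = 0.85, vasomotionFreq = 10.5),
    insulin_1w = groupEffectProfile(c(low = 0.92, mid = 0.82, high = 0.72),
                                    so2Shift = -7, crbcMultiplier = 0.90,
                                    hbMultiplier = 0.90, vasomotionFreq = 12),
    insulin_2w = groupEffectProfile(c(low = 0.95, mid = 0.88, high = 0.80),
                                    so2Shift = -5, crbcMultiplier = 0.93,
                                    hbMultiplier = 0.93, vasomotionFreq = 13),
    liraglutide_1w = groupEffectProfile(c(low = 0.94, mid = 0.86, high = 0.78),
                                        so2Shift = -5, crbcMultiplier = 0.92,
                                        hbMultiplier = 0.92, vasomotionFreq = 12.5),
    liraglutide_2w = groupEffectProfile(c(low = 0.97, mid = 0.93, high = 0.90),
                                        so2Shift = -2, crbcMultiplier = 0.96,
                                        hbMultiplier = 0.96, vasomotionFreq = 14)
  )
}

#' Configuration of the synthetic cohort generator
#'
#' Baselines are control-arm channel means in instrument units; noise
#' standard deviations are per-sample Gaussian. \code{targetCorrelation}
#' is the Pearson correlation induced between oxygenized hemoglobin and
#' low-speed perfusion through a shared latent Gaussian driver (closed-form
#' mixing weight \code{w = r / sqrt(1 - r^2)}, giving
#' \code{r = w / sqrt(w^2 + 1)} for unit-variance components).
#' \code{vasomotionAmplitude} is the peak amplitude (%RBC.mm/s) of the
#' sinusoidal vasomotion carried by total perfusion.
#'
#' @param nSamples samples per session (> 0).
#' @param samplingInterval seconds per sample (default 0.1 s = 10 Hz).
#' @param baselines named numeric: \code{crbc} (%), \code{so2} (%),
#'   \code{hbTotal} (uM), \code{bpLow}, \code{bpMid}, \code{bpHigh}
#'   (%RBC.mm/s), \code{bpConv} (PU).
#' @param noiseSds named numeric (>= 0): \code{crbc}, \code{hbOxy},
#'   \code{hbRed}, \code{bpLow}, \code{bpMid}, \code{bpHigh}, \code{bpConv}.
#' @param targetCorrelation in (-1, 1).
#' @param vasomotionAmplitude peak sinusoid amplitude, %RBC.mm/s.
#' @param groupProfiles named list of \code{\link{groupEffectProfile}}s
#'   covering every \code{\link{groupLabels}} entry.
#' @param seed master integer seed.
#' @return A list of class \code{SyntheticConfig}.
#' @examples
#' cfg <- syntheticConfig(nSamples = 500, seed = 42)
#' s <- generateSession(cfg, "t2dm", "m1")
#' @export
syntheticConfig <- function(nSamples = 2000,
                            samplingInterval = 0.1,
                            baselines = c(crbc = 1.5, so2 = 70, hbTotal = 60,
                                          bpLow = 0.25, bpMid = 0.6,
                                          bpHigh = 0.35, bpConv = 120),
                            noiseSds = c(crbc = 0.08, hbOxy = 2, hbRed = 1,
                                         bpLow = 0.02, bpMid = 0.04,
                                         bpHigh = 0.03, bpConv = 6),
                            targetCorrelation = 0.5,
                            vasomotionAmplitude = 0.15,
                            groupProfiles = defaultGroupProfiles(),
                            seed = 1L) {
  stopifnot(nSamples >= 1, samplingInterval > 0,
            all(noiseSds >= 0),
            abs(targetCorrelation) < 1,
            vasomotionAmplitude >= 0)
  need <- c("crbc", "so2", "hbTotal", "bpLow", "bpMid", "bpHigh", "bpConv")
  stopifnot(all(need %in% names(baselines)))
  stopifnot(all(c("crbc", "hbOxy", "hbRed", "bpLow", "bpMid", "bpHigh",
                  "bpConv") %in% names(noiseSds)))
  if (baselines["crbc"] < 0 || baselines["crbc"] > 100 ||
      baselines["so2"] < 0 || baselines["so2"] > 100)
    stop("crbc and so2 baselines must lie in [0, 100]")
  if (any(baselines[c("hbTotal", "bpLow", "bpMid", "bpHigh", "bpConv")] < 0))
    stop("hemoglobin and perfusion baselines must be nonnegative")
  stopifnot(all(groupLabels() %in% names(groupProfiles)))
  structure(list(nSamples = as.integer(nSamples),
                 samplingInterval = samplingInterval,
                 baselines = baselines, noiseSds = noiseSds,
                 targetCorrelation = targetCorrelation,
                 vasomotionAmplitude = vasomotionAmplitude,
                 groupProfiles = groupProfiles,
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# Run expr under a fixed RNG seed without disturbing the caller's stream.
withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, envir = env)
          else if (exists(".Random.seed", envir = env, inherits = FALSE))
            rm(".Random.seed", envir = env))
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}

#' Generate one synthetic RecordingSession
#'
#' Constructs the full ten-channel set with the structural relations the
#' validator enforces built in exactly: \code{HB_TOTAL = HB_OXY + HB_RED},
#' \code{SO2 = 100 * HB_OXY / HB_TOTAL}, \code{BP_TOTAL} = sum of the three
#' speed bands. The vasomotion sinusoid (group frequency, configured
#' amplitude) is carried by the mid- and high-speed bands in proportion to
#' their baselines — vasomotion is arteriolar in origin, so the slow
#' capillary band is left as pure baseline-plus-noise; total perfusion
#' therefore oscillates at the full amplitude. The Pearson correlation
#' between \code{HB_OXY} and \code{BP_LOW} is induced by a shared latent
#' standard-Gaussian driver: the low-band noise is the driver itself and
#' the oxygenized-hemoglobin noise mixes it with weight
#' \code{w = r / sqrt(1 - r^2)}, normalized back to unit variance.
#'
#' Generated \code{CRBC} values are clipped into [0, 100] and hemoglobin
#' channels at 0 after noise addition; clipping events are reported via
#' \code{message()}.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param group one of \code{\link{groupLabels}}.
#' @param subjectId subject identifier.
#' @param seed integer seed for this session (default: the config's master
#'   seed).
#' @return A valid \code{\linkS4class{RecordingSession}}.
#' @export
generateSession <- function(config, group, subjectId,
                            seed = config$seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  group <- match.arg(group, groupLabels())
  prof <- config$groupProfiles[[group]]
  n <- config$nSamples
  if (n < 1) stop("nSamples must be positive")
  bl <- config$baselines
  sds <- config$noiseSds
  r <- config$targetCorrelation
  w <- r / sqrt(1 - r^2)

  withSeed(seed, {
    tt <- (seq_len(n) - 1) * config$samplingInterval
    pm <- prof$perfusionMultipliers

    # shared latent driver: BP_LOW noise IS the driver
    L <- stats::rnorm(n)
    e1 <- stats::rnorm(n)
    oxyNoiseU <- if (w == 0) e1 else (w * L + e1) / sqrt(w^2 + 1)

    bpLow <- bl[["bpLow"]] * pm[["low"]] + sds[["bpLow"]] * L

    # vasomotion in mid+high bands, split by adjusted baseline share
    midB <- bl[["bpMid"]] * pm[["mid"]]
    highB <- bl[["bpHigh"]] * pm[["high"]]
    fHz <- prof$vasomotionFreq / 60
    osc <- config$vasomotionAmplitude * sin(2 * pi * fHz * tt)
    shareMid <- if (midB + highB > 0) midB / (midB + highB) else 0.5
    bpMid <- midB + shareMid * osc + sds[["bpMid"]] * stats::rnorm(n)
    bpHigh <- highB + (1 - shareMid) * osc + sds[["bpHigh"]] * stats::rnorm(n)

    clip0 <- function(x) pmax(x, 0)
    nClip <- sum(bpLow < 0) + sum(bpMid < 0) + sum(bpHigh < 0)
    bpLow <- clip0(bpLow); bpMid <- clip0(bpMid); bpHigh <- clip0(bpHigh)
    bpTotal <- bpLow + bpMid + bpHigh

    # hemoglobin: oxy fraction from shifted SO2 baseline
    f <- min(max((bl[["so2"]] + prof$so2Shift) / 100, 0.01), 0.99)
    hbT <- bl[["hbTotal"]] * prof$hbMultiplier
    hbOxy <- hbT * f + sds[["hbOxy"]] * oxyNoiseU
    hbRed <- hbT * (1 - f) + sds[["hbRed"]] * stats::rnorm(n)
    nClip <- nClip + sum(hbOxy < 0) + sum(hbRed < 0)
    hbOxy <- clip0(hbOxy); hbRed <- clip0(hbRed)
    hbTotal <- hbOxy + hbRed
    so2 <- ifelse(hbTotal > 0, 100 * hbOxy / hbTotal, 0)

    crbc <- bl[["crbc"]] * prof$crbcMultiplier + sds[["crbc"]] * stats::rnorm(n)
    nClip <- nClip + sum(crbc < 0 | crbc > 100)
    crbc <- pmin(pmax(crbc, 0), 100)

    convMult <- sum(bl[c("bpLow", "bpMid", "bpHigh")] * pm) /
      sum(bl[c("bpLow", "bpMid", "bpHigh")])
    bpConv <- clip0(bl[["bpConv"]] * convMult +
                      sds[["bpConv"]] * stats::rnorm(n))

    if (nClip > 0)
      message(sprintf("generateSession(%s): clipped %d sample(s) into range",
                      subjectId, nClip))

    ch <- rbind(CRBC = crbc, SO2 = so2, HB_TOTAL = hbTotal, HB_OXY = hbOxy,
                HB_RED = hbRed, BP_LOW = bpLow, BP_MID = bpMid,
                BP_HIGH = bpHigh, BP_TOTAL = bpTotal, BP_CONV = bpConv)
    RecordingSession(subjectId, group, ch,
                     samplingInterval = config$samplingInterval)
  })
}

#' Generate a full six-group cohort
#'
#' Per-subject seeds are derived deterministically from the config's master
#' seed, so two cohorts from the same config are identical.
#'
#' @param config a \code{\link{syntheticConfig}}.
#' @param nPerGroup subjects per group (>= 1); the reference design uses 9.
#' @return List of \code{6 * nPerGroup} \code{RecordingSession}s with
#'   unique subject ids.
#' @export
generateCohort <- function(config, nPerGroup = 9) {
  stopifnot(inherits(config, "SyntheticConfig"), nPerGroup >= 1)
  groups <- groupLabels()
  out <- vector("list", length(groups) * nPerGroup)
  k <- 0L
  for (gi in seq_along(groups)) {
    for (i in seq_len(nPerGroup)) {
      k <- k + 1L
      sid <- sprintf("%s_%02d", groups[gi], i)
      sseed <- (as.numeric(config$seed) + 7919 * gi + 104729 * i) %%
        .Machine$integer.max
      out[[k]] <- generateSession(config, groups[gi], sid, seed = sseed)
    }
  }
  out
}

#' Inject instrument-like artifacts into a session
#'
#' Displaces \code{floor(rate * n)} randomly chosen samples per targeted
#' channel by \code{+/- magnitudeSd} channel standard deviations.
#' Derived-channel consistency (hemoglobin / perfusion conservation) is
#' deliberately NOT repaired: artifacts are non-physiological glitches and
#' should be detectable by the validator and the fence-based preprocessor.
#'
#' @param session a \code{\linkS4class{RecordingSession}}.
#' @param rate fraction of samples to corrupt, in [0, 1].
#' @param magnitudeSd displacement magnitude in channel-sd units (> 0).
#' @param seed integer seed.
#' @param channels channel kinds to corrupt (default \code{"BP_TOTAL"}).
#' @return List with \code{session} (corrupted copy) and \code{injected}
#'   (named list of sorted injected indices per channel).
#' @export
injectArtifacts <- function(session, rate, magnitudeSd = 8, seed = 1L,
                            channels = "BP_TOTAL") {
  stopifnot(methods::is(session, "RecordingSession"))
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  stopifnot(magnitudeSd > 0)
  channels <- match.arg(channels, channelKinds(), several.ok = TRUE)
  n <- nSamples(session)
  nInject <- floor(rate * n)
  ch <- session@channels
  injected <- stats::setNames(vector("list", length(channels)), channels)
  withSeed(seed, {
    for (k in channels) {
      if (!k %in% rownames(ch)) stop("session has no channel ", k)
      if (nInject == 0L) { injected[[k]] <- integer(0); next }
      idx <- sort(sample.int(n, nInject))
      s <- stats::sd(ch[k, ])
      if (s == 0) s <- max(abs(ch[k, ]), 1)  # constant channel fallback scale
      sign <- sample(c(-1, 1), nInject, replace = TRUE)
      ch[k, idx] <- ch[k, idx] + sign * magnitudeSd * s
      injected[[k]] <- idx
    }
  })
  out <- session
  out@channels <- ch
  list(session = out, injected = injected)
}
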