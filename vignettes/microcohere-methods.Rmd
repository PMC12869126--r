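---
title: "Models and numerical choices in microcohere"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and numerical choices in microcohere}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcohere)
```

## The measurement and the data object

Combined laser Doppler flowmetry (LDF) and diffuse reflectance
spectroscopy (DRS) probes report, from one tissue volume roughly 1 mm
deep, a synchronized set of ten channels: red-blood-cell tissue fraction
`CRBC` (%), oxygen saturation `SO2` (%), total / oxygenized / reduced
hemoglobin (uM), perfusion resolved into three red-cell speed bands
(< 1, 1-10, > 10 mm/s, in %RBC.mm/s), their total, and conventional
laser-Doppler perfusion (PU). `microcohere` models one subject's
recording as a `RecordingSession`: a channels x time matrix on a single
implicit time grid (index times `samplingInterval`). There are no
per-channel timestamps because acquisition is synchronous; channels that
arrive at unequal lengths are brought to a common length before a
session is formed (see preprocessing).

Structural validity (known channels, positive sampling interval, a known
group label) lives in the S4 validity method; the physiological
invariants live in `validateSession()`:

* `HB_TOTAL = HB_OXY + HB_RED` and `BP_TOTAL = BP_LOW + BP_MID + BP_HIGH`,
  elementwise, to a relative tolerance (default `1e-6`) with an absolute
  floor of `1e-9` so zero-valued samples cannot trip the check;
* `SO2 = 100 * HB_OXY / HB_TOTAL` wherever total hemoglobin is positive;
* `CRBC` and `SO2` in [0, 100]; perfusion and hemoglobin nonnegative.

The two layers are deliberately separate: instrument glitches violate the
physiological invariants, and the whole point of preprocessing is that
such sessions must be representable, validated in "lax" mode (full
report) rather than rejected at construction. `strict = TRUE` turns the
first violation into an error.

## The synthetic cohort generator

No public recordings from this instrument exist, so the generator is a
first-class module, not a test fixture: it defines the statistical
conditions under which every downstream claim is tested.

Per sample, each free channel is baseline + Gaussian noise, with three
structural features layered on:

1. **Conservation by construction.** `HB_TOTAL`, `SO2` and `BP_TOTAL`
   are derived exactly from their constituents, so generated sessions
   satisfy the validator identically (artifact injection then breaks
   them on purpose).
2. **Vasomotion.** Total perfusion carries a sinusoid at the group's
   vasomotion frequency (control default 15 cycles/min) with peak
   amplitude `vasomotionAmplitude` (default 0.15 %RBC.mm/s, about 12% of
   baseline total perfusion). The sinusoid is injected into the mid- and
   high-speed bands in proportion to their baselines and not into the
   low band: vasomotion originates in arteriolar tone, which modulates
   faster-moving flow, and keeping the low band free of a deterministic
   component means the engineered low-band correlation (next point) is
   not diluted. The band sum still carries the full amplitude, which is
   what the frequency estimator sees.
3. **Hemodynamic-oxygen coupling.** The Pearson correlation between
   `HB_OXY` and `BP_LOW` is induced through a shared latent
   standard-Gaussian driver. The low-band noise *is* the driver; the
   oxygenized-hemoglobin noise mixes it with weight
   `w = r / sqrt(1 - r^2)`, renormalized to unit variance, so that the
   induced correlation is `w / sqrt(w^2 + 1) = r` in expectation. This
   keeps temporal structure intact (no post-hoc reordering) and has a
   closed form that tests verify independently. The default target is
   `r = 0.5`.

Group effects are a profile per arm: multiplicative effects on the three
perfusion bands, `CRBC` and hemoglobin; an additive shift of the SO2
baseline (implemented by shifting the oxygenized fraction of total
hemoglobin, so conservation is preserved); and the arm's vasomotion
frequency. The T2DM defaults encode the disease signature the analysis
is designed to detect — high-band multiplier 0.6 (with 0.75 mid and 0.9
low, so the *share* of high-speed perfusion falls while the low-speed
share rises), SO2 shift -10 points, `CRBC` and hemoglobin 0.85, and
vasomotion at 0.7 x control (10.5 cycles/min). Treatment arms
interpolate toward control with week 2 closer than week 1, emulating
partial recovery; these interpolated values, the control baselines
(`CRBC` 1.5%, SO2 70%, total Hb 60 uM, bands 0.25/0.6/0.35 %RBC.mm/s,
conventional perfusion 120 PU) and the noise scales (roughly 5% of each
baseline) are package choices pitched at realistic instrument output,
fixed once and documented here. The sampling rate defaults to 10 Hz — a
free configuration parameter, since the hardware rate is not dictated by
anything downstream.

What the generator does **not** emulate: 1/f drift and slow baseline
wander, respiratory/cardiac harmonics, heteroscedastic noise,
autocorrelated noise within channels, and any biophysics of oxygen
transport. Passing tests therefore demonstrate correct *mechanics*
(formulas, conservation, recovery of engineered structure), not
robustness to every artifact class of real recordings.

Per-subject seeds derive deterministically from the master seed, so a
cohort is a pure function of its configuration. `CRBC`/`SO2` are clipped
into [0, 100] and hemoglobin at 0 after noise addition; clipping events
are reported via `message()` (with default settings they essentially
never occur — baselines sit many standard deviations from the bounds).

## Preprocessing: fences and length uniformization

Outliers are handled by the boxplot rule: Q1 and Q3 establish
`IQR = Q3 - Q1`, and values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` are
*winsorized* — replaced by the nearer fence, never deleted, so sample
counts are stable. Three conventions are fixed because they change the
answer:

* **Quartile convention.** Linear interpolation between order statistics
  at positions `(n - 1) p` ("type 7", the `quantile()` default). Fences
  differ across the nine textbook quantile types; one is named so results
  are reproducible.
* **Single pass.** Fences are computed once from the original values.
  Winsorization is not iterated to a fixed point; re-fencing the adjusted
  data can flag new points (the adjusted distribution is tighter), and
  the contract is a single automated adjustment. The property suite
  checks that when a second pass finds nothing new, it is the identity.
* **Locality.** Fences are per channel, per session — never pooled
  across subjects — because an outlier is defined relative to its own
  recording's central tendency.

Channels of unequal lengths are uniformized to the least common multiple
of the lengths, each sample repeated `L / length_i` times in order —
integer repetition being the only scheme consistent with an LCM target.
A cap (default `1e6`) guards against coprime-length blow-up
(`lcm(7, 11, 13) = 1001` already exceeds a cap of 500) and the error
advises resampling instead. Outlier adjustment runs *before*
uniformization, so a repeated sample can never multiply an artifact's
weight; the order is configurable in the pipeline but this default is
the contract.

## Normalization and method selection

Four dimensionless transforms place channels spanning four orders of
magnitude (fractions of a percent to hundreds of PU) on a common scale:

| method | transform | fitted parameters | output contract |
|---|---|---|---|
| Z-score | `(x - mean) / sd` | mean, **population** sd | mean 0, sd 1 |
| min-max | `(x - min) / (max - min)` | min, max | exactly [0, 1] |
| L2 | `x / ||x||` | Euclidean norm | unit norm |
| median | `x / median` | median | median 1 |

The population standard deviation (divisor `n`) is used for the Z-score:
the transform describes the realized series, not an estimate of a wider
population; the sample-sd variant is the other defensible reading and
the choice is surfaced here because outputs differ by `sqrt(n/(n-1))`.
The median uses the midpoint convention for even lengths. Median scaling
only scales — it does not center — and is implemented exactly so.

Normalization is applied per channel over the session timeline, not per
time point across channels: the object being made comparable is the
channel's trajectory. Degenerate inputs (constant series, all-zero
vector, zero median) raise a typed condition (`microcohere_degenerate`)
rather than returning NaN; `compareMethods()` converts these to
"inapplicable" flags per channel-method pair.

`compareMethods()` reproduces the convergence/dispersion comparison:
boxplot five-number summaries of every channel under every method.
Min-max is recommended whenever all channels survive it, because it is
the only transform with a *fixed bounded* output interval regardless of
input units — Z-scores are unbounded, L2 outputs shrink with series
length, and median scaling has no fixed range. A shared bounded interval
is precisely what a common multichannel frame needs.

## Hemodynamic and oxygenation metrics

Speed-band shares are computed against the sum of the three band means
(not the `BP_TOTAL` channel) so the three shares always total exactly
100; likewise the oxygenized/reduced hemoglobin shares. With all-zero
bands the shares are undefined and flagged rather than silently zero.

The scalar indices chain over session means:

* `Mbp` — time-mean of total perfusion (%RBC.mm/s). Total rather than
  conventional perfusion is used because it shares units with the bands
  and the velocity formula; the choice is configurable.
* `Mvel = Mbp / C_RBC` (mm/s), with `C_RBC` entered as the printed
  percent value, matching the instrument's unit for that symbol — not
  rescaled to a 0-1 fraction, which would change `Mvel` by 100 x.
* `Mfre` — vasomotion oscillations per minute (below).
* `IMR = Mbp / (Mvel x Mfre x S)`, with `S` the microvessel diameter
  constant, 150 um stored as 0.15 mm so `Mvel` and `S` share a length
  unit; `sUnit = "um"` accepts the bare micrometre figure. The composite
  is reported unitless with the S unit logged. Note the algebraic
  consequence of the chaining: `IMR = C_RBC / (Mfre x S)`, so IMR is
  invariant to rescaling perfusion — the tests assert this homogeneity
  property explicitly.

**Counting oscillations.** `estimateMfre()` reads "oscillations per
minute" literally: count complete cycles, scale by 60/duration. The
numerical guard rails are (a) mean-detrending, (b) a short
moving-average smoother (default 0.25 s), and (c) a hysteresis band of
half-width `0.5 x sd(signal)`: an oscillation is registered when the
signal rises above `+h` having previously been below `-h`. On a clean
sinusoid this equals the plain upward mean-crossing count (the tests
check 0.5 Hz at 20 Hz sampling over 60 s gives 30/min, and agreement
within 5% with an independent periodogram-peak estimate); under noise
the band suppresses the spurious double-crossings that plain
zero-crossing counting produces near the mean. A constant series returns
0. The estimator quantizes to whole cycles per recording, so short
recordings carry +/- `60/duration` resolution.

## Coherence analytics

The perfusion-SO2 joint distribution is summarized on a 10 x 10 grid
(ten intervals per variable, matching the ten arcs per half-chord-
diagram). Binning is equal-width, half-open `[a, b)` with the last
interval closed so the maximum is never lost. Bin ranges are pooled
across all groups by default so per-group matrices are comparable on
shared intervals; per-group ranges are a flag away. The chord payload
normalizes row/column marginals to arc widths and joint cells to chord
widths (each summing to 1), omits zero chords, and retains raw counts on
every record so a consumer preferring count-scaled widths can rescale;
interval-conditioned sub-diagrams are a filter over the payload, not
bespoke graphics.

Channel-pair screening pools all subjects' synchronized samples within a
group (concatenation — matching per-group analyses with large pooled n),
computes Pearson r, a two-sided p from `t = r sqrt((n-2)/(1-r^2))`, and
flags a pair *relevant* iff `p < 0.05` and `|r| > 0.4`. No
multiple-testing correction is applied: the flag is a screening rule on
45 pairs, not a family of confirmatory tests, and consumers needing
error control should apply it downstream. Channel ordering comes from
average-linkage hierarchical clustering on `1 - |r|` (the linkage is
configurable; average linkage is the least shape-committal default for a
similarity-derived distance). Constant channels yield NA correlations,
flagged not fatal.

## Pipeline, determinism and problem sizes

`runPipeline()` chains simulate (or read) - validate - preprocess -
normalize - metrics - coherence - export, writing CSV/JSON artifacts
plus a manifest carrying the config hash (MD5 of the canonicalized
YAML), master seed, package version and artifact list. Nothing
timestamped enters any artifact, so a rerun from the same config is
byte-identical — the determinism tests compare MD5 sums file by file.

Default problem sizes are chosen so the demo configuration (3 subjects
per group at 600 samples) completes in about a second and the reference
design (9 per group at 2000 samples, the cohort size used by the
recovery checks and the acceptance script) in a few seconds on one CPU.
Statistical checks in the test suite use: 2000 samples for correlation
recovery (+/- 0.1 at r = 0.5), 5000 for mean convergence (3 standard
errors), 1000 random trials for the normalization contracts, and 500
random series against the brute-force fence oracle.

## Known limitations

* The generator's white-noise model understates real recordings'
  autocorrelation; correlation p-values on real data will be
  anti-conservative in the same way the original screening rule is.
* `estimateMfre` assumes one dominant oscillation; mixed vasomotion
  bands (endothelial + neurogenic + myogenic) would need a spectral
  decomposition, out of scope here.
* LCM uniformization is faithful to its specification but statistically
  crude (repeated samples are not new information); for real multi-rate
  data, resampling is the better tool and the blow-up error says so.
* Group comparisons are descriptive (means per arm); formal inference
  between arms is deliberately not provided.

## Worked example

```{r example, eval = FALSE}
cfg <- defaultPipelineConfig(seed = 1)
res <- runPipeline(cfg, outDir = "demo_out")
aggregate(cbind(relHigh, meanSo2, mfre, imr) ~ group, res$metrics, mean)
```
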