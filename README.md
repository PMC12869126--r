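# microcohere

Analysis of synchronized multichannel microcirculatory recordings — the
kind produced by combined laser Doppler flowmetry (perfusion) and diffuse
reflectance spectroscopy (hemoglobin oxygenation) probes — for
researchers studying microvascular function in disease models such as
type 2 diabetes and its treatment.

A recording is ten synchronized channels from one tissue volume:
red-blood-cell tissue fraction C_RBC (%), oxygen saturation SO2 (%),
total/oxygenized/reduced hemoglobin (µM), perfusion resolved into three
red-cell speed bands (< 1, 1–10, > 10 mm/s; %RBC·mm/s), total perfusion,
and conventional laser-Doppler perfusion (PU). The package provides the
full analysis chain:

- **Preprocessing** — boxplot-fence outlier winsorization
  (values outside [Q1 − 1.5·IQR, Q3 + 1.5·IQR] adjusted to the nearer
  fence) and least-common-multiple length uniformization;
- **Normalization** — Z-score, min–max, L2 and median scaling, with a
  convergence/dispersion comparison across channels
  (min–max is recommended when applicable: it alone has a fixed bounded
  output interval across heterogeneous units);
- **Metrics** — speed-resolved perfusion shares, oxygenized/reduced
  hemoglobin fractions, and the scalar indices

  ```
  Mvel = Mbp / C_RBC                 (microcirculatory velocity, mm/s)
  IMR  = Mbp / (Mvel · Mfre · S)     (microvascular resistance index)
  ```

  with Mbp the mean total perfusion, Mfre the vasomotion rate
  (oscillations/min, counted by a robust mean-crossing method) and
  S = 150 µm (0.15 mm) the microvessel diameter constant;
- **Coherence** — 10 × 10 joint-bin matrices of perfusion × SO2,
  chord-diagram payloads (arc widths = marginal proportions, chord
  widths = joint proportions), and channel-pair Pearson screening with
  the relevance rule p < 0.05 and |r| > 0.4, ordered by average-linkage
  clustering on 1 − |r|;
- **Synthetic cohorts** — a seeded generator emulating the instrument's
  channel set with exact hemoglobin/perfusion conservation, group effect
  profiles (six arms: control, T2DM, insulin/liraglutide at 1 and 2
  weeks), vasomotion oscillations, a tunable HB_OXY~BP_LOW coupling, and
  artifact injection — so the whole pipeline is testable without
  hardware.

## Worked example

```r
library(microcohere)
res <- runPipeline(defaultPipelineConfig(seed = 1), outDir = "demo_out")
aggregate(cbind(relHigh, meanSo2, mfre, imr) ~ group, res$metrics, mean)
```

```
           group relHigh meanSo2  mfre    imr
1        control   29.07   70.01 15.00 0.6670
2     insulin_1w   25.82   62.97 12.33 0.7306
3     insulin_2w   26.78   65.05 13.00 0.7154
4 liraglutide_1w   26.79   64.96 13.00 0.7074
5 liraglutide_2w   28.27   68.00 14.00 0.6869
6           t2dm   23.75   59.96 11.00 0.7709
```

Reading the table: the simulated T2DM arm shows the disease signature
the pipeline is built to quantify — a smaller share of high-speed
perfusion (`relHigh`, 23.8% vs 29.1% in control), lower oxygen
saturation (`meanSo2`), slower vasomotion (`mfre`, cycles/min) and a
higher resistance index (`imr`); treated arms sit between the two, with
week-2 arms closer to control. The engineered coupling between
oxygenized hemoglobin and low-speed perfusion is recovered and flagged
by the relevance rule:

```r
rep <- res$correlations[["control"]]
rep$r["HB_OXY", "BP_LOW"]         # 0.526  (target 0.5)
rep$relevant["HB_OXY", "BP_LOW"]  # TRUE   (p < 0.05 and |r| > 0.4)
```

`demo_out/` holds every artifact as CSV/JSON (per-subject metrics, fence
reports, method comparison, coherence matrices, chord and surface
payloads, bubble-chart payload) plus a manifest with the config hash and
seed; a rerun from the same config is byte-identical.

A thin command-line wrapper covers the same stages:

```sh
exec/microcohere simulate --out cohort.csv --n-per-group 3 --seed 1
exec/microcohere metrics --input cohort.csv --out out --s-constant 0.15 --s-unit mm
exec/microcohere run --config config.yaml --out out
```

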