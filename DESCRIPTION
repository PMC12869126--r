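Package: microcohere
Title: Microcirculatory Perfusion-Oxygenation Coherence Framework
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for synchronized multichannel microcirculatory recordings
    from combined laser Doppler flowmetry and diffuse reflectance
    spectroscopy: boxplot-fence outlier winsorization and least-common-
    multiple length uniformization, four dimensionless normalization methods
    (Z-score, min-max, L2, median scaling) with a convergence/dispersion
    comparison, speed-resolved perfusion and hemoglobin-oxygenation
    summaries, vasomotion frequency and a microvascular resistance index,
    and perfusion-oxygen coherence analytics (joint-bin heat matrices,
    chord-diagram payloads, relevance-thresholded correlation clustering).
    A seeded synthetic cohort generator emulates the instrument's channel
    set, including hemoglobin conservation and group-level effects, so the
    whole pipeline is testable without hardware.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, jsonlite, yaml, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
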