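Package: ligaseflux
Title: Degron-Reporter Kinetics and Ubiquitin-Ligase Activity Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying ubiquitin-ligase activity from
    fluorescent degron reporters in time-lapse microscopy and luminescent
    plate assays. Covers synthetic ground-truth generation (single-cell
    reporter traces obeying a synthesis-degradation balance, rendered
    nuclear image series, 1536-well screening plates), illumination-bias
    correction and nuclear quantification, synthesis-rate estimation under
    neddylation inhibition, activity inference as synthesis minus the
    reporter derivative, cycloheximide-chase half-life fitting, mitosis
    alignment, percent-activity normalization with hit calling,
    four-parameter logistic dose-response fitting, and single-cell
    activity-versus-protein statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    scales,
    generics,
    stats,
    EBImage,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
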