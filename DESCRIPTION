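Package: srbench
Title: Passive Sampling Inference and Diagnostic-Ratio Benchmarking for
    Hydrophobic Organic Contaminants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers freely dissolved concentrations of hydrophobic organic
    contaminants from silicone-rubber passive sampler deployments and screens
    monitoring networks with the hexachlorobenzene/pentachlorobenzene (HCB/PeCB)
    diagnostic concentration ratio. Covers performance-reference-compound (PRC)
    dissipation kinetics fitted by nonlinear least squares, sampling-rate and
    degree-of-equilibrium estimation, temperature-dependent Henry's law constants
    and air-water fugacity ratios, three-phase (dissolved/DOC/SPM) partitioning
    checks, interquartile-range outlier limits for concentration ratios,
    through-origin regression, and benchmarking of target compounds (e.g. PCB
    congeners) against the near-constant background HCB/PeCB ratio. A synthetic
    multi-site scenario generator emulates deployment data so the full pipeline
    is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    ggplot2
Config/testthat/edition: 3
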