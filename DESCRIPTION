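Package: achnet
Title: Acetylcholine-Modulated Dynamics and Plasticity in Scale-Free Spiking Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates networks of conductance-based neurons whose M-type
    potassium current (g_Ks) is used as an inverse proxy for acetylcholine
    level, switching cells between Type I and Type II excitability. Directed
    scale-free topologies with tunable hub in-degree bias are built with a
    multi-pass preferential-attachment growth process, coupled by
    double-exponential conductance synapses with an asymmetric
    spike-timing-dependent plasticity rule, and integrated with a compiled
    fourth-order Runge-Kutta scheme. Analysis tools include mean phase
    coherence, zero-lag cross-correlation of Gaussian-smoothed spike trains,
    average-minimal-distance (AMD) asymmetry scores, region-resolved synaptic
    reorganization, firing-rate statistics, and local-field-potential spectra,
    plus protocol drivers for conductance/noise sweeps, excitatory-inhibitory
    comparisons, hub removal, and wake-sleep-wake plasticity experiments.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Config/testthat/parallel: false
RoxygenNote: 7.3.3
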