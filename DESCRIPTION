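Package: ymazepop
Title: Behavioral and Neural Population Analysis for Virtual-Reality Y-Maze Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for virtual-reality Y-maze
    decision tasks and simultaneously imaged cortical populations. Provides a
    behavioral task simulator (simple, delay, switching and run-to-target
    variants with performance-triggered rule switches and bias correction), a
    synthetic population-activity generator with transient spatial tuning,
    configurable trial-type selectivity and a shared latent noise source,
    fluorescence normalization (neuropil-corrected running-percentile dF/F),
    spatial binning, high-performance trial selection, per-bin auROC
    trial-type selectivity with permutation significance, cross-validated
    linear-SVM population decoding with neuron subsampling, pairwise noise
    correlations and their disruption by trial shuffling, choice decoding
    from running kinematics, and hierarchical bootstrap estimation and
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
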