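Package: pcsm
Title: Probabilistic Cognitive State Modeling for Task fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers recurring latent brain states from trial-aligned task-fMRI
    BOLD signals and derives emergent cognitive-processing metrics from their
    posterior structure. The pipeline estimates per-trial BOLD amplitudes with
    finite-impulse-response (FIR) deconvolution, decodes latent states with a
    constrained Gaussian-mixture hidden Markov model (trial-segmented
    sequences, template alignment, frozen covariances), computes per-timepoint
    decoding diagnostics (response probability, temporal reliability,
    Mahalanobis model discrepancy), and derives serial-parallel processing
    deviation via the Poisson-binomial distribution, cognitive demand,
    leaky-integrator resource level, and a serial-bottleneck scalar.
    Data-driven decision thresholds are estimated by Gaussian-mixture density
    intersections, boundary-corrected kernel-density valleys, subject-level
    quartile bootstraps, and adaptive posterior-FDR node selection. A
    generative stop-signal-task simulator with known ground truth supports
    recovery evaluation and cross-validated model-order selection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    mclust,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
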