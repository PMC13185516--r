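# pcsm — Probabilistic Cognitive State Modeling for task fMRI

Task fMRI analyses usually reduce trial-evoked activity to static contrasts,
discarding how cognition unfolds within a trial. `pcsm` is for researchers
who want trial-resolved, individual-specific estimates of *cognitive
processing dynamics*: which latent brain state the system occupies at each
post-stimulus delay, whether processing is serial or parallel, how cognitive
demand fluctuates, how control resources accumulate and deplete, and how
severe the serial bottleneck is.

## The model

Per-trial BOLD amplitudes are estimated with finite-impulse-response (FIR)
deconvolution, `β̂ = (X'X)⁻¹X'Y`, over 5 delay bins (0–8 s at TR = 2 s); no
hemodynamic shape is assumed. The K × N amplitude series (K = trials ×
delays, N nodes) is decoded by a Gaussian-mixture hidden Markov model with
C = 3 latent states and M = 2 mixtures per state,

    P(y_t | C_t = c) = Σ_m π_{c,m} · N(y_t; μ_{c,m}, Σ_{c,m}),

fitted by Baum–Welch with per-trial sequence segmentation, aligned across
subjects to a global template, with subject covariances frozen at the global
fit for numerical stability. From the filtered posteriors π_{t,c} the
package derives:

- diagnostics: response probability `P_t = Σ_c π_{t,c} a_{c,resp}`, temporal
  reliability `ρ_t = 1 − TV(π_t, π_{t−1})`, Mahalanobis model discrepancy,
  and frame/trial quality flags;
- node response posteriors `B_{t,n}` and the Poisson-binomial
  serial–parallel index `D^SP_t = (2/N) E|K_t − N/2|`;
- cognitive demand, a leaky-integrator resource level with data-driven
  half-life, and a per-subject serial-bottleneck scalar;
- data-driven thresholds for every metric (Gaussian-mixture density
  intersections with separation gating, boundary-corrected KDE valleys,
  subject-level quartile bootstraps, adaptive posterior-FDR node selection).

A generative stop-signal-task simulator (132 trials, 60% go / 40% stop,
three transition regimes × four noise levels, 200 nodes) provides known
ground truth for recovery validation; see the methods vignette
(`vignettes/pcsm-methods.Rmd`) for the model, assumptions and design
choices.

## Worked example

```r
library(pcsm)
study <- run_pcsm_study(n_subjects = 24, seed = 7)
print(study)
#> PCSM study: 24 subjects, 200 nodes, seed 7
#>   state recovery accuracy: 0.9939
#>   thresholds: rho 0.984 | P 0.077 | D_maha 0.503 | D_SP ( 0.929 , 0.974 )
#>   demand high tau: 0.594 | resource high tau: 0.68 | bottleneck negative mass: 75 %
round(study$recovery_states$overall$recall, 3)
#> 0.998 0.992 0.992
```

The accuracy line says that 99.4% of all timepoints across the 24 simulated
subjects were decoded into the correct ground-truth state after template
alignment, with every state recovered at ≥ 99.2% — the regime in which the
downstream metrics are trustworthy. The threshold line reports the
data-driven decision boundaries estimated from this cohort's pooled metric
distributions: e.g. timepoints with reliability ρ below 0.984 are unstable
decodes, and subjects' serial–parallel values at or above the upper D^SP
boundary are classified serial. `study$fdr` tabulates adaptive-FDR node
selection across α ∈ [0.10, 0.30] (realized error is conservative, node
counts grow monotonically with α).

Individual stages are available as plain functions — `simulate_subject()`,
`build_fir_design()`, `estimate_fir()`, `fit_global()`, `fit_subject()`,
`align_to_template()`, `infer_posteriors()`, `response_probability()`,
`serial_parallel_deviation()`, `cognitive_demand()`, `resource_level()`,
`serial_bottleneck()`, `gmm_intersection_threshold()`, … — and a thin
command-line wrapper lives at `inst/cli/pcsm.R`
(`Rscript inst/cli/pcsm.R run --out out --n-subjects 48 --seed 1`).

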