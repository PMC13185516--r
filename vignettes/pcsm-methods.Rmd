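---
title: "Probabilistic cognitive state modeling: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probabilistic cognitive state modeling: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package models

`pcsm` decodes recurring latent brain states from trial-aligned task-fMRI
BOLD and derives interpretable cognitive-processing metrics from the
posterior structure of that decoding. The pipeline has four layers:

1. **FIR deconvolution.** Evoked responses are estimated nonparametrically
   at discrete post-stimulus delays (default 5 bins spanning 0–8 s at
   TR = 2 s), via ordinary least squares
   $\hat\beta = (X'X)^{-1}X'Y$ on a stick design with one indicator column
   per (trial, delay). No hemodynamic shape is assumed; the post-8 s
   undershoot is deliberately excluded because it carries more physiological
   noise than task signal. The K × N matrix of amplitudes
   (K = trials × delays, N nodes) is the observation sequence of everything
   downstream.
2. **A constrained Gaussian-mixture HMM.** Each latent state
   $c \in \{1,2,3\}$ emits from a two-component diagonal Gaussian mixture,
   $P(y_t \mid C_t = c) = \sum_m \pi_{c,m}\,\mathcal N(y_t; \mu_{c,m},
   \Sigma_{c,m})$, intended to capture responding versus non-responding
   signal regimes within a state. Three adaptations make subject-level
   estimates stable and comparable: per-trial sequence segmentation (each
   trial's delay-bin run is an independent sequence; transitions never
   bridge inter-trial gaps), alignment of every subject to a global
   template, and freezing subject covariances at the values of a global
   concatenated fit while start probabilities, transitions, mixture weights
   and means adapt per subject.
3. **Diagnostics.** Per timepoint: the response probability
   $P_t = \sum_c \pi_{t,c}\, a_{c,\mathrm{resp}}$; the temporal reliability
   $\rho_t = 1 - \tfrac12\sum_c |\pi_{t,c} - \pi_{t-1,c}|$ (one minus total
   variation between consecutive filtered posteriors); and a Mahalanobis
   model discrepancy
   $(y_t-\hat y_t)'\Sigma^{-1}(y_t-\hat y_t)$ against the
   posterior-weighted prediction, with a shrinkage-regularized spatial
   covariance. Frames failing all three criteria are flagged; a trial with
   at least 3 of its 5 bins flagged is recommended for removal.
4. **Emergent metrics.** The node response posterior
   $B_{t,n} = \sum_c \pi_{t,c}\,\gamma_{t,c,\mathrm{resp}}(n)$ feeds a
   Poisson-binomial model of the responding-node count, whose normalized
   expected deviation from N/2 is the serial–parallel index
   $D^{SP}_t = \tfrac2N \mathbb E\,|K_t - N/2|$. Demand combines changes in
   processing-mode potential, posterior entropy and Jensen–Shannon
   divergence with a synergy term; resource level integrates demand through
   a leaky integrator whose half-life is derived from the median dwell time
   in processing modes; and the serial bottleneck multiplies mean
   serial-episode length by the mean post-exit demand cost.

Thresholds for all of these are estimated from the data, never fixed a
priori: two- (or three-) component Gaussian-mixture density intersections
with separation gating, boundary-corrected KDE valley selection as the
fallback, subject-level quartile bootstraps for unimodal metrics, and an
adaptive posterior-FDR rule for node selection.

## The generative simulator

The simulator is first-class code, not a fixture: it produces the study
conditions under which everything else is validated. Per subject it
generates a stop-signal task of 132 trials (60% go / 40% stop, at least 50
stop trials), uniform reaction times in 0.35–0.65 s, stop-signal delays in
0.10–0.40 s and a fixed SSRT of 0.25 s (a stop succeeds when the latent go
response would have finished after SSD + SSRT). Each trial carries a
first-order Markov chain over three states across the 5 delay bins, with a
stay probability set by the transition regime (low transition: 0.90,
medium: 0.70, high: 0.50) and trial-type-conditioned initial distributions
(stop trials favor the high-salience state, go trials the low-positive
state). Node amplitudes are drawn once per subject and state — state 1 high
positive U(0.8, 1.2), state 2 low positive U(0.2, 0.5), state 3 mixed
U(−0.8, 0.8) — and observations add Gaussian noise with level-dependent sd
{0.5, 1.0, 1.5, 2.0} (multiples of the state-1 amplitude midpoint), after
which each node is z-scored. These noise values put the per-node effect
size between adjacent states at roughly 1.3 (low noise) down to 0.33 (very
high), so that the between-state mean distance exceeds the within-state
spread at low noise while per-timepoint decoding stays probabilistic; much
smaller noise makes every posterior one-hot and every derived metric
degenerate.

What the simulator deliberately does **not** emulate: hemodynamic
convolution or raw 4D volumes (amplitudes live directly in FIR space),
delay-dependent amplitude modulation within a trial, physiological noise
spectra, scanner drift, and spatially correlated noise. Passing tests
therefore demonstrate identifiability and internal consistency under the
stated generative model — not performance on real fMRI.

## Numerical and design choices

* **Initialization of the global fit.** EM is initialized from a clustering
  of timepoints by their mean amplitude across nodes: trial-evoked states
  differ foremost in overall intensity, and averaging over N nodes
  suppresses node noise by $\sqrt N$. This structured solution is retained
  whenever it is sound; k-means and random restarts are consulted by final
  log-likelihood only if it degenerates (an unvisited state or non-finite
  likelihood). A free likelihood race over restarts is deliberately
  avoided: with subject-specific spatial patterns the pooled likelihood of
  this (necessarily misspecified) model can prefer solutions whose states
  absorb between-subject heterogeneity, which decode individual subjects
  poorly even though they score higher on the concatenated data.
* **Template alignment.** Within each state the mixture with the larger
  mean absolute amplitude is the responding one and is stored last. States
  are matched to the template by the exact-search permutation minimizing
  the squared distance between subject and template mixture-weighted state
  means. The salience score (standardized mean amplitude + standardized
  responding weight) is computed and reported, and breaks exact ties; it is
  not used as the primary matching key because the responding-mixture
  weight is not identified when a state's emissions are effectively
  unimodal — its noise can then exceed the salience gap between states and
  scramble the match, while the state-mean distance uses the same
  information plus the full spatial pattern.
* **Posterior convention.** Filtered posteriors
  $P(C_t = c \mid y_{0:t})$ are the default everywhere; smoothed
  (forward–backward) posteriors are available by flag. $\rho_1 = 1$ by
  convention. The optional reliability smoother is an EMA with half-life
  equal to the delay-bin count, off by default.
* **EM hygiene.** Variance floor 1e−6; convergence at 1e−4 change in
  per-observation log-likelihood; scaled forward–backward with per-row
  shifting so 200-node log densities never underflow; Viterbi in log space;
  all seeds explicit.
* **Discrepancy normalization.** The raw Mahalanobis quadratic form is
  unbounded; the bounded series used for thresholding is the per-subject
  empirical-CDF rank transform (rank − ½)/K, uniform on [0, 1] by
  construction. The raw series is retained alongside.
* **Demand details.** $U$ is the per-subject min–max normalization of
  $D^{SP}$; the Jensen–Shannon series is centered at its median over steps;
  deltas at the first timepoint are 0; the raw demand series is
  median/MAD-standardized (Gaussian consistency constant 1.4826) before the
  tanh squash. A constant series maps to zeros rather than NaN.
* **Resource gain.** The printed form of the integrator gain is read as
  $\alpha = \sqrt{(1-(1-\lambda)^2)/\operatorname{Var}(L)}$, the unique
  choice for which the stationary variance of
  $R_t = (1-\lambda)R_{t-1} + \alpha L_t$ equals one (verified by
  simulation in the test suite).
* **Bottleneck squashing across a cohort.** The raw bottleneck
  (persistence × exit cost) is non-negative and strongly right-skewed, with
  most subjects near zero and a long tail of persistent bottlenecks. The
  cohort squash is therefore tanh of the values centered at the cohort
  **mean** with a MAD-based spread: mean-centering places the ordinary bulk
  below zero and isolates the upper tail, whereas median-centering would
  pin exactly half the cohort below zero regardless of the tail structure.
  Single subjects fall back to tanh of the raw value.
* **Threshold gates.** Mixture intersections require component separation
  $d = |m_2-m_1|/\sqrt{(s_1^2+s_2^2)/2} \ge 1$. A separation-passing
  intersection whose minor component carries ≤ 20% of the density is a
  tail threshold: it is retained for the reliability metric (whose mass
  concentrates near 1) but triggers the KDE fallback for the response
  probability, mirroring the per-metric decision paths of the study this
  implements. KDE valleys use a 512-bin histogram with reflection at both
  support boundaries, Gaussian smoothing at the Silverman bandwidth, and a
  sensitivity sweep over {0.5×, 1×, 2×} bandwidth and {256, 512, 1024}
  bins. Default search windows: response probability (0.02, 0.60), the
  lower serial–parallel boundary (0.45, 0.58), the upper (0.55, 0.70),
  bottleneck tail valleys (0.05, 0.60) and (0.60, 0.99). Degenerate
  univariate mixture fits (spike-heavy samples) are refit under mclust's
  conjugate prior.
* **Adaptive FDR.** Nodes are sorted by descending posterior $B$ and the
  largest prefix with mean posterior error $\overline{1-B} \le \alpha$ is
  retained, so the realized error is conservative by construction;
  Benjamini–Hochberg on $1-B$ is available as an alternate mode.
* **Label correspondence for recovery evaluation.** Subjects share the
  template's label space; the single template-to-generative-labels
  correspondence is resolved once, globally, by maximizing pooled
  prediction–truth agreement over the 3! permutations. No per-subject
  re-matching is performed.

## Problem sizes

The default study (`run_pcsm_study()`) simulates 120 subjects balanced over
the 3 × 4 regime-by-noise grid at the full 132 trials × 5 bins × 200 nodes
and completes in about two minutes on one CPU; the test suite exercises the
same pipeline at 108 subjects plus many small synthetic cases. The original
study ran 15,000 subjects; cohort size mainly tightens the threshold
estimates, not the recovery rates.

## Known limitations

* Under this generator each state's emission distribution is a single
  Gaussian, so the two-mixture split within a state is not identified as
  respond/non-respond; EM settles on a bulk-plus-outlier split with a small
  responding weight. Node posteriors $B$ then concentrate near 0, the
  pooled serial–parallel index sits near its ceiling, and the thresholds of
  the metrics downstream of $B$ (the serial–parallel pair, the FDR error
  level, demand/resource/bottleneck cut points) land away from the values
  reported for richer data. State and transition **recovery** — the
  validation target of the simulation — is unaffected, as are the
  reliability and engagement threshold mechanics. On real trial-evoked
  data, where respond/non-respond structure exists within states, the
  mixture split is meaningful.
* The bounded discrepancy normalization is a design choice (rank ECDF); the
  mapping used to produce the reported 0.741 flagging threshold is not
  derivable from its description, and our uniform-by-construction series
  yields an intersection near 0.5 instead.
* Frozen covariances inherit any structure error of the global fit; the
  package mitigates this with the structured initialization described
  above, but pathological cohorts could still freeze unsuitable variances.
* Model-order selection criteria (the ΔLL > 2, 2 × SE, 70%-of-folds and
  mixture-gain ≥ max(5, 2 × SE) rules) are encoded verbatim; they are
  calibrated for per-observation log-likelihoods of ~200-node data and may
  be conservative for much smaller N.
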