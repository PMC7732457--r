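---
title: "Normative connectome modeling and single-subject anomaly fingerprinting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative connectome modeling and single-subject anomaly fingerprinting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normconn)
```

## The problem

Group-level case–control statistics cannot tell a clinician which of *this*
patient's brain connections are abnormal. The normative-modeling alternative
is to estimate, for every pair of brain regions ("edge"), the distribution of
connectivity strength in a healthy reference cohort, and then score an
individual patient edge by edge against that distribution. `normconn`
implements this workflow for paired structural (diffusion-tractography
streamline counts) and functional (resting-state BOLD correlation)
connectomes over a 379-region atlas: 180 cortical parcels per hemisphere plus
19 subcortical structures (9 per hemisphere and the brain stem).

## The model

For each modality the control cohort of matrices $C_1,\dots,C_N$ is mapped to
a per-edge representation $x_e$:

* **Structural.** Streamline counts are heavy-tailed and non-negative, so
  edges are represented as $\log(1 + \text{count})$. On this scale a
  multiplicative loss of fibers becomes an additive shift, and zero counts
  remain finite. A raw-count option is retained
  (`representation = "raw_count"`).
* **Functional.** Correlation matrices live on the SPD manifold, and
  element-wise statistics ignore their geometry. Each subject matrix is
  shrunk toward the identity, $(1-\lambda)C + \lambda I$ with
  $\lambda = 10^{-3}$ (finite, motion-censored runs can be rank-deficient);
  the cohort's affine-invariant (Karcher) geometric mean $\bar C$ is computed
  by the standard fixed-point iteration; and each subject is embedded in the
  tangent space at $\bar C$:
  $T_i = \log\!\big(\bar C^{-1/2} C_i \bar C^{-1/2}\big)$.
  The whitening makes coefficients comparable across subjects and scanners;
  the embedding is exactly invertible (`tangent_invert()`), which the test
  suite verifies to $10^{-8}$.

Per edge, the normative moments are the sample mean $\mu_e$ and sample
standard deviation $\sigma_e$ (denominator $N-1$). Individual subjects are
scored as $z_e = (x_e - \mu_e)/\sigma_e$ and an edge is flagged anomalous
when $|z_e| > k$ with $k = 3$ by default. The boundary is strict:
$|z_e| = k$ exactly is normal. This is an arbitrary but fixed convention,
chosen so that the flag set shrinks monotonically as $k$ grows.

**Variance exclusion.** Before detection, the one-third of edges with the
highest between-subject variance in the control cohort is excluded
(`exclusion_fraction = 1/3`), the rationale being that highly variable edges
in healthy subjects are prone to false discovery. Exactly
$\lfloor f \cdot n_\text{edges} \rfloor$ edges are excluded, ties broken by
ascending edge index so the mask is reproducible. Variance is ranked on the
detection representation itself (tangent coefficients for functional,
log-counts for structural) — the representation the z-scores are computed on
is the one whose stability matters. Edges with $\sigma_e = 0$ are marked
*degenerate* and never flagged (a 0/0 z-score has no meaning). No
multiple-testing correction is applied beyond the exclusion step; that is
the procedure's stated false-discovery mitigation.

Edges are the $n(n-1)/2$ unordered off-diagonal pairs (71,631 for $n=379$)
in column-major upper-triangle order; the full square functional matrix has
$n^2 = 143{,}641$ entries for the default atlas, which is how
`fc_from_timeseries()` counts them.

## Fingerprint summaries

Detection produces one status per retained edge
(`normal` / `anomaly_low` / `anomaly_high`), which three summaries aggregate:

* **Burden table** (`burden_table()`): per region, every flagged
  (subject, edge) pair increments both endpoint regions once; the region's
  *total potential* is its retained-edge count times the number of subjects,
  and the burden percentage is anomalies over that total. This counting rule
  is the only one consistent with a total potential of
  retained × subjects, and it reproduces reference burden rows exactly
  (see `burden_arithmetic()`). Percentages are displayed half-up to 2
  decimals; full precision is kept internally and used for sorting.
* **Edge-frequency table** (`edge_frequency_table()`): per edge, the number
  of subjects flagged, annotated with each endpoint's network affiliation
  and a deterministic edge classification — hemisphere relation
  (left / right / bilateral / midline-involved) and anatomical relationship
  decided in a fixed priority order: corticobasal (any basal-ganglia or
  accumbens endpoint) before corticothalamic before corticohippocampal
  before other subcortical classes, then interhemispheric, then intralobar
  (shared lobe), then long-range. Subcortical classes outrank the hemisphere
  test so that corticobasal edges are labelled corticobasal on either side.
  "Long range" is operationalized as same hemisphere, different lobe.
* **Network submatrices** (`network_submatrix()`): the status matrix
  restricted to one network's members, with excluded and normal edges
  distinguishable from anomalies. The diagonal is reported as `excluded`
  (self-edges are never assessed), so an all-excluded network renders
  uniformly as the background state.

Structural burden and frequency default to low-side anomalies only (the
phenomenon of interest is fiber *loss*); functional summaries default to
both directions. Both are configurable.

## The synthetic cohort generator

Imaging cohorts cannot ship with a package, so `sim_config()` +
`simulate_controls()` / `simulate_patients()` generate cohorts with a known
normative structure. Defaults are fixed at the emulated study design:
**41 controls and 21 patients**, 379 regions.

* **Structural**: each edge has a fixed population log-mean drawn uniformly
  from `sc_log_mean_range = c(0, 6)` — roughly 300k streamlines per brain
  spread over 71,631 edges with a heavy right tail and many near-zero
  edges — and subjects scatter log-normally around it with
  `sc_log_sd = 0.25`, then round to integer counts (zeros permitted).
* **Functional**: one population correlation matrix with
  `fc_base_rank = 10` latent factors plus heteroscedastic noise; each
  subject's covariance is a Wishart draw with `fc_sample_df = 5 n` degrees
  of freedom, converted to correlation. The shared-factor structure makes
  between-subject variance genuinely heterogeneous across edges, which the
  exclusion step ranks.
* **Effects** are planted *after* sampling, so the ground-truth table lists
  exactly the modified (subject, edge) pairs: planted structural edges are
  multiplied by `sc_multiplier = 0.3` (fewer fibers), planted functional
  edges shifted by `fc_shift_sigmas = 4` sampling standard deviations
  (approximated as $(1-\rho^2)/\sqrt{df}$). Identity parameters
  (multiplier 1, shift 0) reproduce the un-planted patient draw bit for bit
  — controls and patients share one code path up to injection.

**Planted-edge selection.** An effect planted on an edge that the variance
mask excludes is unobservable by construction (excluded edges are never
scored), and a 70% fiber loss on a 1-streamline edge is invisible.
`choose_planted_edges()` therefore samples planted edges among the retained,
non-degenerate edges whose normative mean lies above the retained median —
the regime where the emulated phenomenon (loss of substantial fiber
bundles) lives. This is a design choice of the generator, stated here once.

What the generator does *not* emulate: spatial autocorrelation of edges,
age/sex covariates, scanner batch effects beyond what tangent whitening
absorbs, motion artifacts, and atrophy-driven registration error. Passing
recovery tests on synthetic cohorts therefore demonstrates correctness of
the estimator and detection machinery, not clinical validity on real data.

## Numerical choices

* Geometric mean: fixed-point iteration, tolerance $10^{-8}$ on the
  Frobenius norm of the mean tangent update, maximum 50 iterations,
  initialized at the arithmetic mean; non-convergence is an error that
  reports the last residual. A log-Euclidean mean is available
  (`mean_type = "log_euclidean"`).
* All matrix logarithms/exponentials/square roots go through symmetric
  eigendecompositions, with symmetrization after every reconstruction.
* Before embedding, functional matrices are shrunk and their eigenvalues
  floored at $\lambda$; planted perturbations of a correlation matrix can
  leave it numerically indefinite, and the floor keeps the matrix
  logarithms defined without materially moving the large eigenvalues.
* Matrices are symmetrized by averaging on read; asymmetry beyond $10^{-6}$
  in files (or $10^{-8}$ in constructed matrices) is an error, not silently
  repaired.
* Display rounding of percentages is half-up (base `round()` is
  half-to-even, which disagrees with the convention burden tables print).
* Per-region retained-edge counts are bounded by $n-1$ by construction.

## Problem sizes used by the tests and acceptance script

Correctness tests run on toy atlases (3–25 regions) against brute-force
oracles. The statistical calibration checks use: a 450-region null reference
(101,025 edges, one Gaussian draw per edge) for the $2\Phi(-3)$ flag-rate
check; 20 independent 100-region cohorts of 41 controls and 21 patients
with 10 planted structural edges at multiplier 0.3 for sensitivity
(expected ≈ 0.97, required ≥ 0.9) and false-positive rate (expected
≈ 0.009, required ≤ 0.01), reported as medians; and an 8-parcel × 500-voxel
synthetic grid for parcellation recovery (agreement ≈ 0.98, required
≥ 0.85, with zero centroid-radius violations). These sizes keep the
end-to-end statistical checks well-powered while remaining quick on a single
CPU.

## The parcellation module

The voxel-assignment classifier (`train_parcellation_model()` /
`assign_voxels()`) reproduces the connectivity-fingerprint idea in
simplified, synthetic form: each voxel's feature vector counts its
streamline terminations per atlas target, a gradient-boosted tree ensemble
(xgboost; depth 4, 60 rounds, learning rate 0.3, single thread for
determinism) classifies voxels, and candidate parcels are restricted to
those whose training centroid lies within a radius of the voxel. The radius
default is twice the mean within-parcel distance of training voxels to
their centroid, logged at fit time; voxels with no candidate in range stay
unassigned rather than being forced into a distant parcel. No volumetric
image I/O or registration is attempted — the module's contract is the
classification-with-centroid-constraint procedure itself.

## Known limitations

* The bundled atlas metadata's lobe and network assignments are package
  configuration: anatomically reasonable, but not a published lookup, and
  overridable via `load_atlas()`.
* With 41 controls, z-scores have mild $t$-tail inflation relative to the
  Gaussian $2\Phi(-3)$ rate; the false-positive calibration above reflects
  this (≈ 0.005 under the null at $n=41$), and it is inherent to plug-in
  normative moments, not a defect of the implementation.
* Patient cohorts are never included in reference fitting; the package does
  not regress out age or sex (the emulated design matches cohorts by age
  instead).
* Structural and functional subject subsets may differ (per-modality
  cohorts are supported); no cross-modality coupling is modeled.
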