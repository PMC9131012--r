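---
title: "Microstate dynamics and microstate-specific connectivity: methods"
author: "microdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstate dynamics and microstate-specific connectivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdyn)
```

## The model

Resting-state EEG topographies do not drift continuously: the scalp
voltage map stays quasi-stable for tens of milliseconds and then switches
abruptly to another configuration. These epochs — *microstates* — are the
unit of analysis here. `microdyn` implements the full chain from raw
multichannel EEG to microstate statistics:

1. **Segmentation.** The global field power (GFP) — the per-sample
   population standard deviation across channels — marks moments of high
   topographic signal-to-noise at its local maxima. Maps at filtered GFP
   peaks are clustered by a *polarity-invariant modified k-means*: a map
   belongs to the template with the largest absolute spatial correlation,
   and a template is the dominant eigenvector of its cluster's map
   covariance. Polarity is a gauge freedom — the dipolar generators of a
   map reverse sign within each oscillation cycle — so every comparison
   uses `|corr|` and any template row may be negated freely.
2. **Model order.** The number of clusters is chosen by the
   Krzanowski–Lai (KL) criterion on the within-cluster dispersion curve
   `W(k)`: `DIFF(k) = (k-1)^(2/p) W(k-1) - k^(2/p) W(k)`,
   `KL(k) = |DIFF(k)/DIFF(k+1)|`, with `p` the channel count. KL curves
   are computed per recording, normalised by their own maximum (the
   magnitude of KL varies wildly across recordings; the location of its
   peak is what carries information), averaged, and maximised over
   interior `k`. Ties break to the smaller `k` (parsimony).
3. **Template hierarchy.** Recording-specific templates (best of many
   random restarts by global explained variance, GEV) are re-clustered
   into group templates with equal per-participant contribution, and the
   two groups' templates are pooled and re-clustered once more into
   *common* templates, so that downstream group comparisons cannot be
   driven by systematic template differences. Templates are labelled by
   an exact best assignment (absolute-correlation-maximising matching)
   against a reference set.
4. **Back-fitting and smoothing.** The common templates are fitted back
   to *every* sample of the 1–20 Hz band-passed, average-referenced
   recording. Segments shorter than 30 ms are iteratively relabelled to
   the next most likely class until none remain (see *Numerical choices*
   for the exact algorithm and its termination guarantee).
5. **Parameters.** Per class: GEV (%), mean duration (ms), occurrence
   (1/s), coverage (%), mean interval (ms), mean GFP (µV); plus the
   k × k spatial-correlation matrix `SC[X, Y]` (mean `|corr|` of template
   X with maps labelled Y — not symmetric) and the transition matrix
   `TP` reported as observed minus expected probability.
6. **Microstate-wise connectivity.** The *same* recording follows a
   second, parallel signal path: spherical-spline surface Laplacian
   (current source density, mitigating volume conduction), 8–12 Hz
   band-pass, Hilbert phase, 10% edge discard per segment side. For each
   class the valid samples carrying that label are gathered and the
   phase-locking value
   `PLV(i, j) = |mean(exp(1i * (phi_j - phi_i)))|`
   is computed for every channel pair. Labels come from the 1–20 Hz
   path; phases from the alpha path — never a re-filter of one by the
   other.
7. **Statistics.** Edge-wise tests are corrected by a *signed*
   network-based statistic: edges with parametric `p < p_thr` are split
   by statistic sign, connected components are found per sign on the
   electrode graph, and each observed component's size (sum of its
   statistic values) is referred to the permutation null of the largest
   same-sign component: `p = (2 * #{|S_null| > |s_obs|} + 1) / (N + 1)`,
   clamped at 1. Scalar parameters use two-sided permutation tests
   (label shuffles, sign flips, or score shuffles), Holm correction, and
   BCa bootstrap confidence intervals.
8. **Classification.** A nested leave-one-out SVM (standardise → PCA at
   95% variance → SVM, all fitted inside each training fold; inner
   leave-one-out grid search) pools held-out decision scores into one
   ROC/AUC.

## Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| microstate band | 1–20 | Hz | microstates are broadband but alpha-dominated; 1–20 Hz keeps the classical range |
| GFP peak discard | bottom 15% | — | low-GFP maps carry unreliable topographies |
| GFP outlier guard | mean + 3 SD | — | removes artifact-driven peaks (see below) |
| k range | 2–10 | — | brackets every published optimum |
| restarts | 100 | — | best-of-restarts GEV is effectively converged |
| smoothing minimum | 30 | ms | shorter segments are not interpretable as states |
| connectivity band | 8–12 | Hz | Hilbert phase needs a narrow band; alpha generates microstates |
| edge discard | 10% per side of each segment | — | Hilbert/filter edge effects |
| Laplacian | m = 4, 50 Legendre terms, λ = 1e-5 | — | standard spherical-spline CSD convention |
| PLV minimum samples | 250 (1 s at 250 Hz) | — | below this the class matrix is flagged unreliable |
| NBS `p_thr` | 0.001–0.05 | — | edge-forming threshold; component inference corrects family-wise error |
| permutations | 2000 (NBS), 100000 (scalar) | — | p-value floors 1/2001 and 1e-5 |
| SVM grids | C ∈ 10^(-2..2), γ ∈ 10^(-3..1) | — | unspecified upstream; logged in output |

One deliberate re-reading: the GFP outlier rule is sometimes stated as
"peaks greater than three times the standard deviation". GFP is a
non-negative quantity with a large mean, so a threshold at `3·SD` *from
zero* would sit below the typical peak height and discard the bulk of
genuine peaks (~84% on synthetic alpha-riding EEG). The rule is an
outlier guard; `microdyn` implements it as `mean(GFP) + 3·SD(GFP)` over
all samples, configurable via `sd_multiple`.

## The synthetic generator

`generate_microstate_eeg()` plants everything downstream stages must
recover. Defaults are the reference eyes-closed resting-state setting:
59 channels at 250 Hz (a synthetic Fibonacci-lattice hemisphere montage,
not an anatomical cap), five states, gamma dwell times with shape 4 and
scale 25 ms (mean 100 ms — the canonical quasi-stable duration; gamma
rather than geometric because empirical dwell distributions are
unimodal with a mode away from zero), a 10 Hz carrier with a small
random-walk frequency jitter, and SNR 2 (state-signal RMS over noise
RMS — resting alpha rides well above the broadband floor, and 2 is a
conservative desk value).

Templates are dipolar fields: the cosine between each electrode position
and a random dipole axis, average-referenced and normalised. Axes are
drawn in a whitened metric so that the correlation between two maps
equals the plain cosine between their sampled directions — on a
hemisphere-only montage the raw metric is anisotropic and would make
honest separation constraints unreachable. When a requested separation
corresponds to line packings random sampling cannot find (five lines
pairwise ≥ 60° in 3-D), a randomly rotated icosahedral axis frame
(pairwise `|cos| = 1/sqrt(5)`) is used instead.

Phase coupling is a shared random-walk carrier plus independent
per-channel von Mises jitters, giving the closed-form pair PLV
`(I1(κ)/I0(κ))²`. Cohort simulations raise κ by `effect` on all channels
incident to a planted edge set during one designated state; with
`effect = 0` the groups are exchangeable by construction, which is what
the family-wise-error simulations exploit.

What the generator does **not** emulate: 1/f background spectra, spatially
correlated noise, eye/muscle artifacts, non-stationary state
repertoires, or volume-conduction leakage of independent sources.
Passing recovery tests on this generator therefore demonstrates
*internal consistency* of the pipeline — templates in, templates out —
not robustness to every pathology of real recordings.

## Numerical choices

* **Segments.** Artifact-free runs are stored 1-based with inclusive
  `start` and exclusive `end`; all per-segment processing (filtering,
  Hilbert, labelling) never crosses a boundary.
* **Filters.** 4th-order Butterworth applied forward–backward
  (`signal::filtfilt`), per segment. Any zero-phase realisation meeting
  the pass/stop behaviour would do; IIR keeps edge regions short.
* **k-means details.** Template update is the dominant eigenvector of
  the cluster covariance (warm-started power iteration), *not* the mean
  of sign-aligned maps — this makes polarity invariance exact. Empty
  clusters are re-seeded from the worst-explained map. Dispersion is
  `W(k) = Σ (2 - 2|corr|)` over sign-aligned unit maps. Restarts consume
  one seeded RNG stream; recording lists are canonicalised by name
  before group clustering so input order cannot change results.
* **Smoothing termination.** Iterative relabelling of short segments can
  oscillate. Phase 1 is made monotone: when a short run is rejected,
  its samples *permanently* exclude that class and move to the best
  remaining one — each sample can reject at most k−1 classes, so the
  loop terminates. Phase 2 merges any leftover short runs into their
  longer neighbour, shortest first. Smoothing is idempotent and the
  ≥ 30 ms postcondition is property-tested on random sequences.
* **Truncation.** The first and last run of every segment are flagged
  truncated and excluded from *all* per-class parameters; coverage is
  renormalised over the remaining samples (one consistent denominator;
  coverage sums to 100% exactly). Intervals never span artifact gaps.
  Expected transition probability uses destination run-count shares
  among classes other than the source.
* **Ties.** argmax ties in back-fitting and smoothing go to the lowest
  class index; assignment ties in template ordering go to the earlier
  reference column; KL ties go to the smaller k.
* **Zero-variance samples** inherit the previous sample's label (first
  valid label for a flat prefix) and contribute zero correlation.
* **p-value conventions.** NBS components use the printed formula with
  the sign-matched null and `abs` comparison, clamped at 1 (the formula
  can exceed 1 for small components). Scalar tests use
  `p = (2·min(tail counts) + 1)/(N + 1)` with strict inequalities —
  this makes null p-values uniform on their attainable grid and
  reproduces the 1/(N+1) floor. Permutation spaces smaller than the
  requested count are enumerated exactly.
* **Pooled LOOCV scores.** Each held-out decision score is centred by
  the mean decision score of its training fold. Without this, pooled
  leave-one-out scores carry a systematic class offset (the training
  fold always lacks one member of the held-out class), which drags the
  null AUC well below 0.5; centring restores chance-level behaviour and
  leaves separable data at AUC 1.
* **Feature selection happens outside the cross-validation loop** (it
  mirrors the select-then-classify workflow it models). The pipeline
  records this provenance and flags the resulting AUC as potentially
  optimistic rather than silently reporting it.

## Problem sizes used in validation

The recovery suite runs twenty 10-minute, 59-channel recordings at
SNR 2 for model-order selection (k-range clustering capped at 1000
subsampled GFP-peak maps with 15 restarts — dispersion curves are stable
well below the full peak count), with template and dwell recovery
measured on a five-seed subset. Family-wise error uses 500 null cohorts
of a reduced 16-channel design with 12 subjects per group and 499
permutations each; planted-component recall uses a full synthetic cohort
(15 per group, 10-edge star, κ raised 0 → 5). Classification soundness
uses 30 separable and 50 label-shuffled 16-subject cohorts. At these
sizes the acceptance script completes on one CPU in roughly ten minutes.

On this generator, back-fitting with the planted templates at SNR 2
labels ~89% of all samples correctly and ~94% of samples above the
bottom-15% GFP threshold: near carrier zero crossings the instantaneous
map is noise-dominated and no decoder can do better, which is precisely
why template estimation uses GFP peaks.

## Known limitations

* EDF support covers the common 16-bit, single-rate case; EEGLAB `.set`
  files are not read — convert to EDF or the internal matrix + JSON
  sidecar format.
* The montage shipped for simulation is synthetic; supply real electrode
  positions for real data (unit-sphere coordinates).
* The surface Laplacian assumes a spherical head and returns CSD per
  unit-radius²; absolute units are not calibrated.
* Template ordering's exact assignment supports k ≤ 8 (enumeration with
  bound pruning); larger template sets would need a Hungarian solver.
* The NBS component p-value inherits the mild conservatism of its
  formula (factor 2 across the two signed families); empirical
  family-wise error sits at or slightly below the nominal level.
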