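---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `pfcplast`, the parameters that
matter, the numerical choices, and the limits of what the synthetic
validation demonstrates.

## Setting

The package analyses longitudinal recordings from a chronic 8 × 8
microelectrode array (0.75 mm pitch, covering 5.25 × 5.25 mm of lateral
prefrontal cortex) collected daily while a subject progresses through a
staged match/nonmatch training curriculum. Each daily session contains a
*passive* fixation block — two stimuli in sequence at locations on a 3 × 3
grid, separated by 1.5 s delays, no response required — and, once training
begins, an *active* block whose structure tracks the curriculum: phases
I–II use a single left/right cue pair with short fixed delays, phase III
generalizes the cue to all nine locations, and phase IV stretches the two
delay periods to variable durations between 0.25 and 1.5 s. Stimulus
locations are indexed 0–8 row-major; index 4 is the central (foveal)
location, which never appears as a nonmatch and is therefore excluded from
location decoding and from the dPCA stimulus factor. All analyses align
time to cue onset and use half-open bins `[t, t + dt)`, so a spike at a
boundary is counted exactly once.

## The synthetic experiment generator

`generateExperiment()` exists so that every downstream stage can be
validated against planted ground truth. It emulates the *design* of a
staged-training experiment, not the biophysics of the tissue.

**Spiking.** Each unit is an inhomogeneous Poisson process with intensity

$$\lambda(t) = g \,\Big[\, b\,\big(1 + (c-1)\,w\,\mathbf{1}_{\rm cue}(t)
 + (d-1)\,w\,\mathbf{1}_{\rm delay1}(t)\big)\, m(t) + s\,(t - t_{\rm cue\,off})^{+} \Big]$$

where $b$ is the unit's baseline rate (log-normal around the schedule's
per-phase value, 8–9 spikes/s by default), $c$ and $d$ are the cue and
first-delay gains applied to units drawn as *responsive* for that task,
$w \in (0, 1]$ is a von Mises tuning weight over the eight peripheral
location angles with concentration $\kappa$ (default 1.5; the centre
location receives the kernel's circular mean, i.e. it is untuned), $m(t)$
modulates the sample and second-delay epochs by match status in the active
task only (factor $1 \pm \tfrac12\,\mu\,p_u$ for match/nonmatch, with
per-unit preference $p_u = \pm 1$ and strength $\mu \in [0,1]$), and $s$
is a linear ramp toward the onset of the choice targets, present in
active phases I–III and zero in phase IV, where variable delays make the
target time unpredictable. Sampling is by thinning against the analytic
intensity bound, so trains are exact draws with no discretization error.
Poisson spiking without refractoriness is sufficient because every
downstream stage operates on counts and rates.

**Correlated variability.** Trial-to-trial covariability is produced by a
shared multiplicative gain: per trial the units' log gains are drawn from
$N(-\sigma^2/2,\ \Sigma)$ with $\Sigma_{ij} = \sigma^2 e^{-d_{ij}/L}$,
$d_{ij}$ the physical distance between the units' electrodes. Gains have
mean one, and pairwise spike-count correlations decay with distance at
length scale $L$ (default 1 mm). A multiplicative gain was chosen over
common-input spikes because it parameterizes the planted Pearson
correlation directly. The default $\sigma$ schedule (0.22 dropping to 0.16
across passive phases, 0.20 to 0.14 active, passive above active) yields
same-electrode fixation-count correlations around 0.2 — the order of
magnitude typical of cortical pair recordings — declining in later phases
and lower in the active task.

**LFP.** Each trace is $1/f$-shaped background noise plus band-limited
(FFT-masked) Gaussian oscillations in alpha (8–14 Hz), beta (20–45 Hz) and
gamma (46–70 Hz). Baseline band amplitudes are fixed; the schedule's
per-band factors multiply the amplitude during the cue epoch, so the
planted quantity is exactly what the analysis estimates — cue-epoch band
power relative to the fixation baseline. The default schedule plants a
monotone beta decline and alpha rise across phases, with a mild gamma
decrease. An optional fixed-frequency line component (amplitude 1) is
available for exercising line removal.

**Determinism.** All randomness derives from a mandatory master seed
through a hierarchical child-seed scheme (per session, per task, per unit,
per electrode), so identical configurations are byte-identical on disk and
subsets regenerate identically.

**What the generator does not emulate.** Refractoriness, bursting,
spike-sorting errors, non-Poisson count dispersion, electrode drift and
unit turnover across days, eye movements, error-trial structure beyond a
flat correct-rate, 1/f slope changes, and cross-frequency coupling. A
passing recovery test therefore shows that a stage measures what it claims
under its own model assumptions — not that those assumptions hold in any
given recording.

## Stage-level choices

**Epochs and screening.** Epoch rates are counts in `[start, end)` over
the epoch duration. Multi-location blocks are screened by one-way ANOVA
across cue locations, run separately on cue-epoch and first-delay-epoch
rates; a unit is responsive when either p-value is below α = 0.05
(configurable). Single-location blocks (active phases I–II) use a paired
t-test of epoch rate against fixation rate, requiring elevation; MUA
records must additionally show a ≥ 10 % cue-epoch rate increase. The 10 %
gate is applied to the cue epoch only — the guard exists to keep
threshold-crossing records from passing on noise during the stimulus —
and not to the delay path; sorted single units omit it entirely. Units
with too few trials are reported *unevaluable*, never unresponsive.
Degenerate inputs (zero variance everywhere) take an explicit p = 1 path.
`bestLocation` breaks exact ties toward the lowest location index.

**PSTHs.** Default 50 ms bins, no smoothing (an optional Gaussian kernel
can be layered on by the caller); rate analyses use correct trials only.
Windows are clipped to the extent shared by all selected trials, and
mixing trials of unequal post-cue duration beyond that extent is an error
rather than a silent truncation — phase-IV data need explicit
segment-aligned treatment.

**Noise correlation.** Counts come exclusively from the 1 s fixation
window, which is identical across tasks and phases, so no per-condition
z-scoring is needed. Pairs need ≥ 20 trials (configurable; the protocol
itself is silent here) and a constant count vector makes the coefficient
undefined — the pair is excluded, not recorded as r = 0. The phase
comparison is the linear model `r ~ phase + distance` with the phase
F-test computed against the distance-only model; distance enters
untransformed (a log option was considered and left out — the exponential
decay is planted in r, not log r). Display binning uses
{0, 0.75, 1.06–1.5, > 1.5} mm groups; statistics always use continuous
distance.

**LFP pipeline.** Zero-phase (forward–backward) Butterworth filters: order
2 bandpass at 0.5–200 Hz and order 2 notch at 58–62 Hz. Electrode
exclusion uses a robust z-score on log total variance (median/MAD, |z| >
3), catching both noisy and dead channels; the original acquisition
pipeline's outlier model is unspecified, so this decision is isolated
behind `flagVarianceOutliers()`. Multitaper parameters default to 0.5 s
windows, 50 ms steps, time–bandwidth NW = 3 with 5 tapers; DPSS sequences
are computed from the classical symmetric tridiagonal eigenproblem, which
is exact and dependency-free, and the estimator is scaled so the one-sided
PSD integrates to the signal variance. Baseline normalization is additive
per-frequency subtraction of the mean fixation-period power (a dB-ratio
mode is provided); baseline frames are kept clear of the cue by half a
window length so no post-cue energy leaks into the reference. Session
values average across trials and kept electrodes, and phase comparisons
treat one session as one observation.

**Decoding.** The classifier is the maximum-correlation-coefficient rule
(nearest class centroid by Pearson correlation) — the conventional default
of pseudo-population decoding toolboxes; it is isolated behind one
function so a regularized discriminant can be plugged in, and the
calibration tests are classifier-robust (chance level, separable limit).
Pseudo-trials draw k trials per condition per unit without replacement
(k ≥ 10 by default; units below threshold are excluded before sampling,
and units are sampled with replacement only when fewer than the requested
200 are eligible). Normalization uses training-fold means and standard
deviations only; features with zero training variance are dropped for that
fold. The shuffle null permutes labels within each resample and repeats
the identical procedure (100 shuffles by default); a bin is significant
when the mean actual accuracy falls outside the null's 2.5–97.5 percentile
interval, with a two-sided z-test p reported alongside. The suite includes
a deliberately broken mode that trains centroids on all trials including
the test fold; it demonstrably inflates shuffled-label accuracy and is the
negative control for leakage. Z-scoring from full-data statistics, by
contrast, leaves the shuffled-label expectation at exact chance (label
permutation symmetry) and is offered only as an option, not treated as a
leakage detector.

**Demixed PCA.** The condition-averaged tensor (units × 8 stimuli × 2
decisions × time) is centred per unit and split into additive
marginalizations (condition-independent, stimulus, decision,
stimulus × decision interaction) that sum exactly to the centred tensor.
Each marginalization is regressed onto the full centred data by
ridge-penalized reduced-rank regression; λ defaults to $10^{-6}$ × total
centred variance — enough to stabilize the Gram inversion without visibly
biasing components — and 5 components per marginalization are reported
with explained-variance shares against total centred variance. The
match/nonmatch trial label defines the decision factor in the passive task
as well, although no behavioural decision occurs there; that is precisely
what makes the passive decision components a meaningful negative control.

**Sliding ANOVA.** 200 ms bins, 50 ms steps, main effects only. Because
the match label is a deterministic function of the two locations, a
full-interaction model would alias the decision factor with the
location × location interaction; the decision effect is therefore
estimated from the two-level match label with the location factors as
covariates, and this aliasing is inherent to the design rather than
resolvable by modelling. Single-level factors are dropped per unit and
logged as NA; degenerate bins return p = 1. The selective-fraction test is
the exact two-sided binomial test (minimum-likelihood convention) against
the 5 % chance rate.

## Serialization

Experiments serialize to a plain-text directory layout: a
`manifest.json` (schema version, seed, configuration hash, session index),
per-session `trials.csv`, and JSON payloads for ragged spike-time lists
and LFP traces. The format is diffable, portable and loss-free at double
precision, and `readDataset()` validates every invariant on load with
located error messages. Vendor acquisition formats are out of scope;
adapters map external data onto this schema.

## Problem sizes used in validation

The test suite chooses sizes that make each statistical check
well-powered while keeping a full run modest: the shared medium fixture
uses 40 units/session × 5 sessions (200 units) with 6 trials per
condition; chance calibrations run 20 resampled pseudo-populations × 5
repeats; type-I calibration of the sliding ANOVA uses 200 null units;
ANCOVA power runs 50 record-level simulations at 600 pairs/phase; the
session-level beta ANOVA runs 25 simulations at 20 sessions/phase. The
acceptance script regenerates its inputs from scratch at the same sizes.

## Known limitations

- The variance-outlier "model", multitaper parameters, decoding
  classifier, shuffle count and minimum-trial thresholds are declared
  defaults where the original acquisition/analysis protocol leaves them
  unstated; all are configurable and isolated behind single functions.
- Phase-IV PSTHs require explicit piecewise alignment (cue-aligned then
  target-aligned); the package enforces the common-extent restriction
  rather than attempting automatic stitching across variable delays.
- dPCA component counts and regularization are reported transparently but
  not significance-tested; only qualitative structure (e.g. decision
  components absent in the passive task) should be interpreted.
- Real-data effect sizes (unit counts, F statistics, absolute decoding
  accuracies) depend on the recordings themselves; the synthetic defaults
  target realistic orders of magnitude, not those specific values.
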