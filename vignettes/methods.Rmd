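---
title: "Models and methods behind cbgtimer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind cbgtimer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cbgtimer)
```

`cbgtimer` packages the computational machinery used to study flexible motor
timing in the cortico-basal-ganglia loop: a one-dimensional accumulator
("timer") model of self-initiated movement timing, a zoo of threshold-linear
network architectures that could implement that accumulator, and the
behavioural and population-spike analyses that discriminate among them. This
vignette explains each model, the parameters that matter, the numerical
choices made where the methods admit more than one reading, and what the synthetic
data generator can and cannot establish.

## The accumulator timer

The timer represents elapsed time as the integral of a constant inflow,
$T(t) = \int_0^t r\,ds$, and triggers a lick when $T$ reaches a threshold
$\theta = 1$. The inflow $r$ is constant within a trial but varies across
trials: a target first-passage time $t^\ast$ is drawn from an inverse
Gaussian $\mathrm{IG}(\mu = 1.3\,\mathrm{s}, \lambda = 12)$ — the standard
first-passage-time family for drift-to-threshold processes, matched to the
dispersion of empirical lick times — and $r = \theta / t^\ast$, so an
unmanipulated trial licks at exactly $t^\ast$. Two transient manipulations
emulate the optogenetic perturbations, both lasting 0.6 s with the final
0.3 s at linearly decaying strength:

* **pause / slowdown** multiplies the inflow by a speed coefficient $c$
  ($c = 0$ full pause, $c = 0.5$ half speed). Because this warps all
  trials through the same monotone time map, every trial that licks after
  the manipulation offset is delayed by exactly the lost integral
  ($0.45$ s for $c = 0$, $0.225$ s for $c = 0.5$), independent of onset —
  the *state-independent* signature.
* **rewind** replaces the inflow by a negative rate $r_\mathrm{decay}$,
  so the accumulated state itself decreases, clamped at zero; a state
  pinned at zero for more than 320 ms continuously makes the trial a
  no-lick. The loss now depends on the accumulated state, so later onsets
  lose more — the *state-dependent* signature.

Integration is forward Euler at $dt = 1$ ms (steps coarser than 10 ms are
refused); halving $dt$ changes lick times by less than one step.
`simulate_trial()` is the scalar reference implementation;
`simulate_timer_experiment()` integrates all trials as vectors over one
time grid and closes the post-manipulation first passage analytically, and
the two paths are cross-checked in the test suite. The default
$r_\mathrm{decay} = -2r$ is exposed in `timer_manipulation()`; note that a
decay proportional to the trial's own rate makes the zero-dwell duration
rate-independent (0.2 s, below the 0.32-s no-lick criterion), so rewind
no-licks essentially require a *fixed* strongly negative rate (the
analyses use $r_\mathrm{decay} = -2$), under which slow trials dwell past
the criterion while fast ones relick.

### Hazard-rate readout

`hazard_rate()` bins first-lick times at 20 ms, forms
$h = f / (1 - F)$ with the survivor evaluated at the bin start (so the
discrete survival identity $1 - F = \prod (1 - h)$ holds exactly), smooths
with a centred 5-bin boxcar, and treats no-lick trials as right-censored at
the 5-s horizon (censoring is the convention that keeps the at-risk
denominator honest; treating no-licks as missing would inflate late
hazards). `hazard_shift()` fits each curve with a four-parameter logistic
(free baseline, amplitude, slope, midpoint) restricted to times before the
cumulative distribution reaches 80%, and reports the difference of 50%
points; when the fit fails to converge the half-maximum crossing by
interpolation is used and flagged.

One estimator caveat, documented because the test suite asserts around it:
for a *half-speed* pause at a late onset, the shifted 50% point falls
inside the manipulation window where the hazard is still suppressed, and
the fitted midpoint is biased late. The onset independence of the pause is
therefore asserted two ways: through the sigmoid estimator for the
complete pause (whose shifts at onsets 0.6 and 0.9 s agree within two
bins at $n = 10{,}000$), and through the exact trial-level delay identity
for $c = 0.5$. Shift quantification always restricts both the control and
the manipulated distribution to trials licking after the manipulation
onset, the same restriction used for behavioural comparisons.

## The network model zoo

All network variants share the rate dynamics
$\tau \dot h_i = -h_i + \sum_j W_{ij} r_j + I^\mathrm{base}_i +
I^\mathrm{ext}_i(t) + I^\mathrm{stim}_i(t)$, $r = \max(h, 0)$, with
$\tau = 10$ ms, integrated by forward Euler at $dt = 0.1$ ms, with convergence under
step halving verified in the tests. Temporal integration is an eigenvalue property of $W$: an
eigenvalue of exactly 1 yields a continuous attractor that accumulates
input, smaller eigenvalues leak, and chains of sub-unity recurrent modules
with feedforward links amplify without any single perfect integrator.

Rather than fixing one arbitrary parameterization per architecture,
`build_variant()` *synthesizes* each variant from its defining
constraints — eigenstructure, area wiring, input routing, and a stable
lower fixed point with the target neuron at 5 spikes/s — and verifies the
constraints at build time. Two choices deserve emphasis:

* In the **specialized striatal integrator**, cortical drive reaches the
  striatal integrator through a baseline-zero relay carrying the
  *above-baseline* cortical rate. This is not cosmetic: if the integrator
  received the full tonic cortical rate, silencing ALM would inject a net
  negative integrand and *rewind* the striatal state, whereas routing the
  difference makes ALM silencing remove the integrand and *pause* it —
  the behaviour attributed to this architecture.
* The **feedforward chains** use within-module eigenvalue 0.95 and
  near-marginal interstage links (0.1) under a global inhibitory baseline
  of $-0.5$, because that regime makes the last module's 10-Hz crossing
  time a smooth, monotone function of the step amplitude (graded speed
  control). Stronger links make the crossing time jump discontinuously
  with input. A consequence worth stating plainly: with sub-unity modules
  the chain's state necessarily decays during a 0.6-s silencing
  (timescale $\tau / (1 - 0.95) = 0.2$ s), so no feedforward variant
  reproduces the clean parallel-resume signature; among the implemented
  zoo only the specialized striatal integrator passes both perturbation
  classifiers.

`calibrate_baseline()` solves $I^\mathrm{base} = h^\ast - W f(h^\ast)$ for
the desired rest state and rejects architectures whose active
linearization has an eigenvalue above 1. `tune_step_input()` root-finds
the step amplitude so the control trial licks at 1.3 s. Ramp modes are
defined from the model's own activity with the same window rule as for
recorded populations, normalized so 0 is the target neuron's baseline and
1 its level when it reaches 10 spikes/s; the model lick is the moment the
normalized target-area ramp reaches 1. The signature classifiers
(`classify_silencing_response()`, `classify_d1_response()`) operate on
these normalized trajectories: parallel resume requires the ramp to resume
near its pre-stimulus level at the control slope with a lick delay near
the effective silencing duration; the rewind signature requires a gradual
(not step-like) decay during the stimulus and no jump back toward control
after the offset.

## The synthetic session generator

The generator exists so that every analysis stage has a testable ground
truth; its defaults encode the task conditions. Behaviour: delays
alternating between 1 and 3 s in blocks of 30-70 trials; ITI
$= 1 + \mathrm{Exp}(3)$ s capped at 7 s; ~10% no-cue probes; lick times
from $\mu_n = \beta_0 + \sum_k \beta_{T,k} LT_{n-k} + \sum_k
\beta_{TR,k} LT_{n-k} R_{n-k}$ with IG(mean $\mu_n$, shape 12) noise
clipped at 0.2 s, and defaults $\beta_0 = 1.17$, $\beta_{T,1} = 0.3$,
$\beta_{TR,1} = -0.2$ (positive dependence on previous lick times,
negative interaction with reward, stationary mean near 1.3 s). Lagged
values come from the most recent *licked* trials, matching the
regression's carry convention. Spikes: inhomogeneous Poisson at 1-ms
resolution with baseline 5 spikes/s, a monotone smoothstep ramp from cue
to lick peaking ~20 spikes/s above baseline (premotor ramps in this
preparation reach a few tens of spikes per second at movement), a 60/40
split of temporally scalable versus absolute-time units, and a tonic
trial-history current $h_i z_n$ on 40% of units, where $z_n$ is the
standardized history-predicted lick time. Perturbations act at the rate
level through a shared ramp-phase variable that pauses (silencing, with
ALM rates additionally multiplied by 0.02) or decays and resumes from the
decayed level (rewind), with the matching change applied to the trial's
lick time by an internal unit-speed timer.

What the generator does *not* emulate — and hence what green tests do not
establish about recordings: correlated (low-dimensional) noise, bursting
and oscillations, non-Poisson spiking statistics, cross-area transmission
lags beyond the shared phase variable, adaptation across sessions, and
electrode artefacts. Parameter-recovery results here certify the
*implementations*, not the identifiability of these quantities in real
data.

## Statistical machinery

**Trial-history regression.** The candidate set crosses the seven
non-empty subsets of {previous lick time $T$, previous outcome $R$,
interaction $T{\times}R$} with maximum lags 1-6 — the only natural grid
with the documented cardinality of 42 — scored by five-fold
cross-validated MAD explained ($1 - R_1/R_2$ with median absolute
residuals against the intercept-only null) and refit on all data. Because
reward is a threshold function of the lick time, $R$ and $T{\times}R$ are
strongly collinear and near-equivalent families often tie; parameter
recovery is therefore assessed on the generative family.

**Hierarchical bootstrap.** Animals, then sessions within drawn animals,
then trials within drawn sessions, all with replacement; 1,000 iterations
by default; percentile CIs; one-sided p as the fraction of iterations
violating the null direction. Type-I error under a true null is verified
to stay at or below the nominal level plus Monte-Carlo slack.

**Temporal warping.** Post-cue spike times are scaled by
$LT_\mathrm{target}/LT$. For the across-trial variance comparison the
default warp target is the *median* lick time of the analysed trials, and
rates are computed over the real-time span of each warped window:
otherwise the warped windows of slow trials cover more real time, their
Poisson variance shrinks, and an absolute-time unit shows a spurious
"reduction". Significance uses a 1,000-rep trial bootstrap of
$\mathrm{var}_\mathrm{orig} - \mathrm{var}_\mathrm{warped}$, significant
when the 95% CI excludes zero.

**Ramp characterization.** Ten random half-splits; polynomial orders 1-8
fit to the training-half PSTH on a 10-ms lattice (200-ms causal boxcar)
and scored by test-half MSE; the final order is the modal winner with ties
broken toward the smallest order (parsimony); monotonicity is a constant
derivative sign of the final fit from cue to lick.

**Targeted dimensionality reduction.** Each mode is the unit-norm
difference between a window mean and the pre-cue baseline mean;
Gram-Schmidt order: middle ⊥ ramp, cue ⊥ {middle, ramp}, execution ⊥
ramp; the trial-history mode (per-neuron Spearman correlation between ITI
rate and history-predicted lick time) is never orthogonalized. Projections
for two-dimensional analyses are scaled by the control-trial standard
deviation without mean subtraction so that 0 means zero spiking.
Variance-explained proportions subtract the 0-0.2-s pre-cue baseline
(trial-history mode: no subtraction) and respect Bessel's inequality over
orthogonal modes.

**Vector fields.** Displacements between consecutive 50-ms states in the
(middle, ramp) plane, averaged in spatial bins of 0.5 with more than 30
points; the stimulation field pools 100-400 ms after inhibition onset.
Bins whose control vector lies within $\pi/6$ of the through-origin
radial direction at that bin ($\mathrm{atan2}(Y, X)$, with quadrant
handling) are excluded: where the control flow already points along the
origin line, rewinding and collapsing toward zero are indistinguishable.

**kNN decoding.** All (trial, 50-ms bin) states from 1 s before the cue to
the first lick, labelled with the remaining time to lick; PCA retaining
90% variance; $k = 30$ neighbours (20-50 behave alike, asserted in
tests); ties broken by training order for determinism. One deliberate
deviation: distances default to Euclidean in the retained PC space rather
than whitening by the total-variance eigenvalues. Mahalanobis distance
should normalize by the *noise* covariance; for near-isotropic noise
(independent Poisson counts) that is the identity, whereas total-variance
whitening inflates retained near-noise components and, on matched
synthetic data, halves decodability. The whitened variant remains
available (`metric = "whitened"`). Matched-pair comparisons match each
perturbed trial to the control with the closest decoded lick time at the
last fully pre-onset bin, compare trajectories as *paired* differences
while both trials are unlicked, start post-stimulus readouts only after
the causal smoothing window has cleared the stimulus, and summarize the
perturbation-induced shift as the control-corrected within-trial change
in decoded lick time across the stimulus — the estimator that is free of
the attrition and matching-noise selection biases that inflate pooled
group differences.

## Engagement, classification and grouping conventions

Within-trial times are seconds from cue onset; bins are half-open
$[t, t + \Delta)$. The engaged block runs from the first run of five
consecutive licked cue trials to 21 cue trials before the last run of
three consecutive unperturbed no-lick cue trials (the 20 trials
immediately preceding the run are discarded; no-cue probes neither extend
nor break runs). Unit classes follow the waveform rules (ALM pyramidal:
rate > 0.5 spikes/s and width ≥ 0.5 ms; SPN: width ≥ 0.4 ms and
post-spike suppression ≤ 40 ms; FSI: width < 0.4 ms and < 10% long ISIs —
the "long ISI" cutoff has no canonical value and defaults to 2 s in
the generator's metadata). Lick-time groups use the six half-open ranges
from 0.80 to 2.00 s.

## Problem sizes

The shipped tests and the acceptance script run at the models' standard
simulation scale where one exists (10,000 timer trials; 1,000-instance
oracle comparisons) and otherwise at sizes chosen for stable Monte-Carlo
behaviour: synthetic sessions of 220-500 trials with 20-50 units,
bootstrap suites of 200-500 iterations, and 150-200 replicate null
datasets for level checks.

## Known limitations

* The network connectivity is constraint-synthesized; quantitative
  trajectory details (e.g. exact ramp curvature) depend on that choice,
  and only the signature structure is meaningful.
* The feedforward variants cannot hold state through a long silencing by
  construction; see above.
* The sigmoid hazard-shift estimator is biased when a manipulation window
  overlaps the fitted rise; use the complete-pause comparison or the
  trial-level delay identity in that regime.
* Decoded-shift summaries other than the within-trial change estimator
  carry attrition bias near the end of trials.
* The generator's lick-time history process is first-order; it cannot
  probe lag-selection behaviour beyond verifying that spurious long-lag
  structure is not invented.
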