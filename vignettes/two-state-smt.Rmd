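---
title: "Two-state mobility analysis for single-molecule tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-state mobility analysis for single-molecule tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smt2state)
```

## The problem

Membrane-bound enzymes such as bacterial penicillin-binding proteins
(PBPs) alternate between a *slow, substrate-bound* state — molecules
engaged in cell-wall synthesis — and a *fast, freely diffusive* state in
which they scan the membrane for new binding sites. Single-molecule
tracking (SMT) at millisecond frame rates records trajectories of
individual fluorophore-tagged proteins; the statistical structure of
those trajectories carries the two-state kinetics. `smt2state`
implements the standard analysis chain for this regime:

1. **Jump-distance (squared-displacement) mixture fitting** per
   condition, with BIC model selection (`extract_jumps`,
   `fit_rayleigh_mixture`, `select_model`);
2. **pooled Gaussian mixture fitting** across experimental conditions
   with shared diffusion coefficients and per-condition population
   weights (`extract_displacements`, `fit_pooled_gmm`,
   `population_shift_table`);
3. **dwell-time (residence-time) analysis** of confinement events with
   bootstrap errors and Levene tests (`extract_dwell_events`,
   `fit_dwell_exponential`, `compare_dwell`);
4. **standardized-cell localization maps** and long-axis zone statistics
   (`normalize_localizations`, `build_heatmap`, `zone_fractions`);
5. a **two-state trajectory simulator** (`sim_config`,
   `simulate_trackset`, `simulate_conditions`) that supplies ground truth
   for every stage, since raw SMT movies are rarely redistributable.

## The jump-distance model

For 2-D Brownian motion with diffusion coefficient $D$ observed at frame
interval $\Delta t$, the single-interval jump distance $r$ is Rayleigh
distributed and the squared displacement $u = r^2$ is exponential with
mean $4 D_\mathrm{app} \Delta t$. A population switching between $K$
mobility states therefore produces an exponential mixture

$$p(u) = \sum_{i=1}^{K} \frac{f_i}{4 D_i \Delta t}
         \exp\!\left(-\frac{u}{4 D_i \Delta t}\right),
         \qquad \sum_i f_i = 1 .$$

`fit_rayleigh_mixture` maximizes this likelihood by EM (closed-form
updates; the log-likelihood is asserted non-decreasing at every
iteration), `select_model` compares $K = 1..K_\mathrm{max}$ by
$\mathrm{BIC} = -2\ell + (2K-1)\ln n$, and the quality of fit is
summarized by the coefficient of determination $R^2$ between the
empirical and fitted CDFs of $u$ evaluated at all sample points.

**Apparent coefficients.** A localization error of $\sigma$ per axis
adds $2\sigma^2$ to the variance of every measured step, inflating each
coefficient to $D_\mathrm{app} = D + \sigma^2/\Delta t$. Fits report
apparent coefficients by default, which is how such values are
conventionally printed; `correct_precision = TRUE` subtracts
$\sigma^2/\Delta t$. At a typical $\Delta t = 20$ ms and
$\sigma = 30\text{–}50$ nm the correction is $0.045$–$0.125$ µm²/s —
the same order as the slow state itself, which is why the convention
matters and is stated explicitly.

**Fitting space.** The mixture is fitted on squared displacements (the
exponential form) rather than on the Rayleigh density of $r$: the two
parameterizations are equivalent, but the exponential form has exact
sufficient statistics and closed-form EM updates. Only lag-1 jumps enter
the sample; steps spanning frame gaps are skipped, never interpolated,
to avoid mixing lags.

**Numerical choices.** EM components are initialized from a K-quantile
split of $u$; convergence is declared at a relative log-likelihood
change of $10^{-8}$ (configurable), with a 5000-iteration cap — fits on
effectively single-population data at $K > 1$ walk a flat ridge where
two components merge, which converges but slowly. Non-convergence
raises a typed condition carrying the last iterate. Ties in BIC break
toward smaller $K$.

## The pooled cross-condition GMM

To compare *population sizes* across conditions without conflating them
with drifting coefficient estimates, the 1-D step components $d$ (both
axes pooled — each axis of a Brownian step is an independent zero-mean
Gaussian with sd $\sqrt{2 D_\mathrm{app} \Delta t}$) of all conditions
are fitted jointly: component standard deviations are *shared* across
conditions, population weights are free per condition. The EM M-step
pools responsibility-weighted second moments over all conditions for the
shared variances and renormalizes weights within each condition. The
population-shift table reports each condition's slow fraction with its
absolute (percentage-point) and relative change
$100 (f_c - f_\mathrm{ref}) / f_\mathrm{ref}$ versus a reference
condition, the relative change rounded to one decimal to match the
reporting precision of such tables. $K$ defaults to 2, the two-state
model; other values are exposed for testing.

## Dwell-time analysis

A *dwell event* is a stay of at least `min_frames = 9` consecutive
detections within `radius = 0.12` µm (about three times a typical
localization error) of the event's **first** localization. The anchored
definition — rather than a running centroid — is the simplest
deterministic reading of "staying within a set radius" and is
re-verified in the test suite by an independent brute-force scanner.
Durations count intervals, $(n_\mathrm{frames} - 1)\,\Delta t$, so a
9-detection stay spans 8 intervals of 20 ms and the truncation point is
$t_\mathrm{min} = 0.16$ s.

Durations are modelled as a left-truncated exponential; by
memorylessness the MLE of the excess is
$\hat\tau = \overline{t} - t_\mathrm{min}$ and the mean residence time
of recorded events is $t_\mathrm{min} + \hat\tau$. Standard errors come
from seeded bootstrap resampling of events (1000 replicates by default).
Bleaching truncates observed dwells, so uncorrected values
*underestimate* true binding times; the competing-risk correction
$1/\tau_\mathrm{true} = 1/\hat\tau - 1/\tau_\mathrm{bleach}$ is exposed
but off by default, matching the convention of reporting uncorrected
values. Conditions are compared by the classic mean-centred Levene test
applied to the bootstrap $\tau$ replicate sets (the variance-of-$\tau$
comparison), with significance tiers at $p < 0.1$ and $p < 0.01$.

## Standardized-cell maps

Localizations are projected into a standardized 3 × 1 µm rod cell:
translate by the cell centre, rotate by minus its orientation, scale by
half-length and half-width so that $x_\mathrm{rel} = \pm 1$ at the poles.
Points farther than 0.2 µm outside the spherocylinder outline are
rejected (and counted); nearer points are clamped, since localization
noise straddles the membrane. Heat maps are probability-normalized 2-D
histograms, by default folded by both reflections — a population of rod
cells has no intrinsic left/right or up/down labelling — with the
unfolded map available (`symmetrize = FALSE`). Zone statistics cut the
long axis at $|x_\mathrm{rel}| = 0.2$ (septal) and $0.8$ (polar); these
thresholds are artifact-defined knobs, chosen to make the qualitative
categories (septal / peripheral / polar) quantitative and testable, not
values taken from any measurement.

## The simulator: a stated world

`simulate_trackset` realizes the generative model the analysis assumes,
and its defaults *are* the experimental regime being emulated:

| parameter | default | meaning |
|---|---|---|
| `frame_interval` | 0.02 s | 20 ms stream acquisition |
| `localization_precision` | 0.03 µm | sub-50 nm SMT precision (see below) |
| `bleach_half_life` | 1.2 s | YFP half-life under comparable illumination |
| `D_slow`, `D_fast` | 0.035, 0.525 µm²/s | true coefficients whose *apparent* values at $\sigma = 30$ nm are 0.08 and 0.57 µm²/s |
| `f_slow` | 0.5 | roughly half of the molecules substrate-bound |
| `mean_state_dwell_slow` | 0.5 s | free parameter (see below) |
| cell | 3 × 1 µm spherocylinder | standardized medium-sized rod |

Per frame the molecule switches state with probability
$1 - e^{-\Delta t / \bar\tau_\mathrm{state}}$ (a discretized telegraph
process — adequate because $\Delta t \ll$ state dwell times), takes a
per-axis Gaussian step of variance $2 D \Delta t$, is reflected at the
spherocylinder boundary, and is observed with additive Gaussian noise of
sd $\sigma$ per axis. Track length is geometric with per-frame survival
$2^{-\Delta t / t_{1/2}}$. Motion is simulated on the 2-D projection
(confined to the outline) rather than the true 3-D membrane surface,
because the analysis itself operates on 2-D projected tracks and planar
diffusion is the fitted model. Zone bias acts on *initial positions
only*; motion is never biased.

Design decisions worth recording:

* **Stationarity.** Two-state kinetics are published as stationary
  fractions, not switching rates, so `mean_state_dwell_fast` is derived
  as $\bar\tau_s (1 - f_\mathrm{slow})/f_\mathrm{slow}$ by default,
  making the chain stationary at exactly `f_slow`; the slow-state dwell
  mean (0.5 s) is a free generator parameter, and recovery results are
  insensitive to it over 0.2–2 s. Supplying an explicit fast dwell
  overrides the derivation (then `f_slow` is only the initial-state
  probability).
* **Apparent-value convention.** Recovery experiments configure the
  generator with printed coefficients treated as *apparent* values at
  $\sigma = 30$ nm: true $D = D_\mathrm{app} - \sigma^2/\Delta t$. A
  40 nm precision would make the slow state's true coefficient exactly
  zero (0.08 − 0.0016/0.02), a degenerate corner; 30 nm stays within
  the stated sub-50 nm precision class and avoids it.
* **Seeding.** One master seed; per-track streams are derived by
  counter, and per-condition seeds by a stable hash of the condition
  label, so generation is reproducible and independent of the order in
  which conditions are listed.
* **Minimum track length.** "Five frames" is read as five detections
  (four displacement steps), the observation-count convention of the
  upstream tracking tools; it is a parameter everywhere it is used.
* **Nine-interval convention.** A dwell event requires nine detections
  (eight intervals); both the radius and the count are `dwell_config`
  knobs, since the frames-vs-intervals reading is ambiguous in prose.

## What a green test establishes — and what it does not

The simulator reproduces the *statistical* structure the estimators
assume: exponential mixtures of squared displacements, shared-variance
Gaussian step components, geometric bleaching, confinement in a
spherocylinder. It does **not** emulate camera noise beyond Gaussian
localization error, fluorophore blinking, directed (motor-like) motion,
3-D membrane geometry, cell-to-cell variability in size or expression,
or detection/linking errors (tracks are born perfect; the greedy linker
is plumbing for fixtures, not a u-track replacement). Parameter-recovery
tests therefore establish estimator correctness on the assumed model,
not robustness to every artifact of real microscopy.

Two systematic effects of the stated world show up in the recovered
numbers and are worth knowing:

* **Confinement bias.** Reflecting fast molecules at the 1 µm-wide cell
  boundary shortens their observed steps, biasing the recovered fast
  coefficient low by roughly 8% at $D_\mathrm{app} = 0.57$ µm²/s —
  within the 10% recovery band, and a real feature of tracking fast
  diffusion in small cells.
* **Escape truncation of dwells.** Nearly immobile molecules
  ($D = 0.005$ µm²/s, $\sigma = 30$ nm) still wander out of a 120 nm
  radius on the ~0.5 s scale, truncating long stays. On simulated
  immobile molecules with exponential observed lifetimes of mean 0.30 s,
  the pipeline's mean residence time measures ≈ 0.295 s rather than the
  no-escape value of 0.46 s; the dwell statistic is a property of the
  event definition, not a pure lifetime estimate — which is also why
  published residence times are underestimates.

## Degenerate inputs and tie-breaks

Tracks shorter than two detections are dropped at construction (a
single detection carries no dynamics); duplicated (track, frame) pairs
are validation errors naming the track. Zero-length jumps are floored at
the smallest positive double before entering the exponential likelihood.
All dwell durations at the truncation point give $\hat\tau = 0$ with a
boundary flag and warning. Mixture components are always reported in
ascending coefficient order, which also resolves initialization
permutations; equal-coefficient limits collapse onto the nested smaller
model (checked numerically in the tests). The Table-style mobility
classification uses a single threshold — relative slow-fraction change
above 20% — and a separate, artifact-defined 10-point threshold for
zone-occupancy shifts.

## A worked example

```{r example, eval = FALSE}
base <- sim_config(n_tracks = 1200, bleach_half_life = 0.5, seed = 42)
cfg <- run_config(
  sim = list(base = base,
             overrides = list(list(label = "unstressed", f_slow = 0.50),
                              list(label = "vancomycin", f_slow = 0.36))),
  reference = "unstressed", K_max = 2)
report <- run_pipeline(cfg)
report$shift_table
report$classification
```

A ~28% relative drop of the slow fraction (50% to 36%) exceeds the 20%
rule and labels the treated condition "more diffusive". The same
pipeline is exposed as a command line
(`smt2state simulate | fit-jd | fit-gmm | dwell | heatmap | report`; see
`smt_cli`).

## Known limitations

Only lag-1 statistics are used (no MSD curves, no anomalous exponents);
state assignment per step (HMM) is out of scope; the pooled GMM assumes
all conditions share both coefficients exactly; dwell fitting is
single-exponential; the linker performs no gap closing or merge/split
resolution. Where the published record is ambiguous — PDF-of-$r$ versus
CDF-of-$u$ fitting space, precision correction on or off, frames versus
intervals, symmetrized versus raw heat maps — both behaviours are
implemented with the documented default, so the choices are explicit
rather than baked in.
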