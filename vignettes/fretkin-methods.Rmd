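---
title: "Models and methods in fretkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in fretkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretkin)
```

fretkin analyses single-molecule FRET time series of transcription
elongation complexes. This vignette is the package's own account of the
models it implements, the defaults it chose where the underlying
experimental literature leaves choices open, and what its tests do and do
not establish.

## The generative model

### Kinetic scheme and trace simulation

A molecule is modelled as a continuous-time Markov chain over `K`
FRET-resolvable states. `kinetic_scheme()` holds the state levels
(mean FRET efficiency, distinct by construction), emission standard
deviations, a rate matrix (off-diagonal entries in s⁻¹, zero diagonal)
and an initial distribution. Dwell times in state *i* are exponential
with rate `sum(rates[i, ])`; a zero exit rate marks an absorbing state
(useful for irreversible cascades such as termination).

`simulate_state_path()` samples the chain by Gillespie jumps and then
records the state occupying each camera frame's **midpoint**. A dwell
shorter than one frame can therefore be missed entirely — deliberately
so, because that is exactly what a camera at 200 ms integration does.
The continuous jump path is retained as an attribute so that tests of
the dwell-time law can assert on the uncensored continuous quantity
rather than the discretized one.

`simulate_intensity_trace()` renders the path into two channels under
donor excitation: acceptor `= I·E + bg_A`, donor `= I·(1−E) + bg_D`,
plus additive Gaussian read noise per channel. Defaults: total intensity
1000 a.u., noise 20 a.u. (2%), frame interval 0.2 s, 600 frames (a 120 s
acquisition at 5 frames/s), 100 molecules per experiment. Photobleaching
is one irreversible exponential-time event per dye; the default acceptor
bleach lifetime is 11.3 s, the red-excitation Cy5 bleach scale in
oxygen-scavenged buffers. Blinking is not modelled (experimentally it is
suppressed with Trolox), and there is no camera EM-gain or photon-shot
model: additive Gaussian noise is sufficient to exercise every
downstream fit.

### What the generator does and does not emulate

The generator reproduces: Markov switching among discrete FRET levels,
anti-correlated channels, single-step bleaching of either dye with the
correct channel signatures (acceptor bleach ⇒ FRET lost, donor recovers
to full intensity; donor bleach ⇒ both channels to background),
multi-exponential ensemble decays, 1:1 binding isotherms with
multiplicative noise, Gaussian-mixture FRET populations, and
censored dwell samples. It does **not** emulate donor/acceptor spectral
crosstalk, direct acceptor excitation, gamma (detection-efficiency)
imbalance, intensity drift, or baseline fluctuations. Consequently,
passing recovery tests demonstrate the correctness of the estimators
under the stated noise model — they do not certify performance on real
movies, where those uncorrected effects shift absolute FRET values.

## FRET computation and the bleach horizon

`compute_fret()` uses the proximity ratio
`E = (I_A − bg_A)/((I_A − bg_A) + (I_D − bg_D))` with no gamma,
leakage or direct-excitation corrections. Simulator and analyser share
this convention, so all internal tests are consistent; on real data the
resulting values are apparent FRET.

Frames whose corrected total intensity falls below 10% of the
molecule's initial ten-frame median are masked — after full bleaching
the ratio of two near-zero channels is noise. `detect_photobleach()`
flags the first frame where total intensity drops below 50% of that
initial median and stays below for ≥ 5 frames (a below-threshold run
reaching the trace end also counts, since a bleach in the final frames
"stays below" for the remainder). Both thresholds are arguments, not
constants. A trace whose initial median is non-positive is dark from
the start and gets horizon 0.

One asymmetry deserves emphasis: a **total-intensity criterion cannot
see acceptor-only bleaching**, because the donor recovers exactly the
intensity the acceptor loses. Post-acceptor-bleach frames survive as
E ≈ 0 and masquerade as a low-FRET state. In real two-channel data this
is the classic reason analysts truncate traces at the first bleach of
either dye, usually identified from channel-specific signatures. The
package keeps the detector's contract simple and total-intensity-based,
and its own end-to-end demonstrations therefore place the bleach budget
on the donor channel, where the detector sees it. Simulations focused on
the acceptor-bleach signature itself (FRET loss, donor recovery) are
tested directly against the generator's recorded bleach frames.

## Idealization: ML-HMM with BIC selection

The idealization stage in the smFRET literature is often performed with
variational-Bayes HMM tools. fretkin instead uses a fully specified
maximum-likelihood route: Gaussian-emission HMM fitted by
Baum–Welch EM, 10 restarts from quantile-based initial means perturbed
by N(0, 0.05²), stopping when the log-likelihood gain is below 1e-6 or
at 500 iterations; the best restart wins. This keeps every ingredient
reproducible without guessing another tool's priors, at the cost of not
reproducing that tool's exact state counts. Model selection fits
`K = 1..k_max` (default 6) and minimizes
`BIC = −2 logL + (K² + 2K − 1) ln T`, ties toward smaller K.

Numerical choices: scaled (not log-space) forward–backward recursions,
with the transition-count update collapsed to a single matrix product
(each per-step pairwise posterior already sums to one under this
scaling); emission densities floored at 1e-300; emission sds floored at
1e-4; Viterbi ties broken toward the lower state index so decoding is
deterministic. Two fitted states whose means differ by less than 0.05
with overlapping ±1 sd intervals are merged before segments are built,
because regime classification needs distinct levels, not two labels for
one population. Masked frames are dropped and the usable frames
concatenated before fitting; this slightly miscounts transitions across
a masked gap, which is negligible at the default masking rate
(pre-bleach masking is rare).

Correctness anchors: the forward likelihood and Viterbi path are tested
against exhaustive enumeration over all `K^T` paths for short traces,
and posterior normalization is asserted to 1e-10.

## Classification, TDPs, dwell kinetics

The FRET axis is partitioned at 0.4 and 0.7. The published description
of these regimes uses overlapping interval endpoints, so the package
fixes a half-open convention — `[0, 0.4)` low, `[0.4, 0.7)` mid,
`[0.7, 1]` high — making 0.4 mid and 0.7 high; both cutoffs are
arguments. A trajectory with exactly one state is *static*; otherwise
its class is the set of regimes its fitted state means visit, with any
trajectory touching both high and low (with or without mid) counted as
*high-low* — the only reading under which the seven classes are mutually
exclusive and exhaustive, which is property-tested over random segment
sets. Regime membership uses fitted state means, not per-frame values.

Transition density plots pool transitions across all molecules of a
condition (whether the original analyses pooled per movie is unknowable
from the outside; pooling across molecules is the default and only
mode). The density is a product-Gaussian KDE on a 100×100 lattice over
[0,1]², Silverman bandwidth per axis floored at 0.01, normalized to
integrate to 1. The asymmetry score is (mass below diagonal − mass
above)/(total off-diagonal mass), positive when transitions
predominantly decrease FRET; a mirror-symmetric transition set scores 0
to machine precision because both axes then carry identical samples and
bandwidths.

Dwells in a FRET window (closed interval; the window is an explicit
argument everywhere) are maximal runs of in-window segments. The first
run of a trajectory is left-censored (already in progress when
observation began) and is **excluded** from fitting by default — the
standard unbiased policy, switchable via `include_left_censored`. Runs
ending at the analysis horizon are right-censored and enter the
likelihood through survival terms. The censored exponential MLE has the
closed form `τ̂ = (Σ all durations)/n_uncensored`, `SE = τ̂/√n`; the
gamma MLE optimizes over log(shape), log(scale) from method-of-moments
starts, with standard errors by the delta method from the numerical
Hessian. "Characteristic lifetime" of a gamma fit is reported as the
**scale** parameter (the per-step lifetime), with shape and mean also
returned, since the underlying literature does not pin its gamma
parameterization; recovery tests are therefore self-consistent
parameter-recovery statements, not claims about any one convention. A
near-degenerate sample (variance ≈ 0) drives the shape MLE to infinity;
it is capped at 100 with a warning. Model comparison prefers the lower
BIC and flags |ΔBIC| < 2 as indeterminate. No sub-frame missed-event
correction is applied (minimum dwell = 1 frame).

## Ensemble fits

**Global decay.** `global_decay_fit()` fits
`y_i(t) = A_1i e^{−t/τ} + A_2i e^{−t/τ_2i}` across all conditions at
once by Levenberg–Marquardt, τ shared, with selected conditions
constrained to a single exponential (`A_2i = 0`). Convergence is a
chi-square change below 1e-9; standard errors come from the covariance
at the optimum. Curves are normalized to their first point by default
(the normalization anchor of published "normalized intensity" curves
being unstated, first-point normalization is fixed and documented);
the acceptance simulations generate already-normalized curves and fit
with `normalize = FALSE`.

**FRET histograms.** `fit_three_gaussians()` bins at width 0.02 over
[−0.1, 1.1] and least-squares-fits a sum of three Gaussians to the
counts, initialized at the three largest modes of a five-point smoothed
histogram (quantile-spread fallbacks if fewer modes resolve). Weights
are recovered from amplitude×sd areas and normalized; components are
sorted by mean, 95% CIs on means come from the parameter covariance,
and a weight below 0.02 flags collapse. The histogram is fit — rather
than running sample EM — to mirror how such figures are produced;
`method = "em"` (Gaussian-mixture EM via mclust) is available as an
independent route, and the two agree on well-separated fixtures. The
intended input is the set of state levels visited by idealized
trajectories; raw per-frame values work identically if passed instead.

**Binding.** `fit_ssa()` fits `R_eq = R_max [A]/([A]+K_D)` by
Levenberg–Marquardt, initialized at the concentration of half-maximal
response and `1.1·max(R_eq)`. The fit is exact on noiseless isotherms
over at least a thousand-fold K_D range (property-tested). A response
decrease beyond 5% of the maximum flags non-monotonicity without
aborting. `steady_state_response()` averages a configured steady-state
window of a sensorgram; kinetic (association/dissociation) modelling is
out of scope. `overhang_trend()` tabulates K_D against overhang length
and reports the longest-to-shortest fold change.

**Spectra.** `difference_spectrum()` subtracts on identical wavelength
grids only (no interpolation); `moving_average()` is the five-point
centered smoother with shrinking windows at the edges.

## Reproducibility and problem sizes

Every stochastic function takes a `seed`; fixed seed means bit-identical
output, and the pipeline derives per-stage seeds deterministically from
one master seed (`run_simulate()` / `run_analyze()` write a manifest
with the config digest). File formats are plain CSV with a fixed column
order and full-precision floats, so write∘read is the identity.

The shipped test and acceptance runs use deliberately moderate problem
sizes chosen to exercise the estimators at realistic single-molecule
scales: 10⁴–10⁵ draws for law-of-large-numbers checks, 200 seeded
replicates for coverage of the dwell MLEs (n = 200 exponential dwells
censored at 120 s; n = 500 gamma dwells), n = 3000 for mixture
recovery, 20–30 replicates for BIC state-count studies, and an
end-to-end run of 60 molecules × 400 frames on a three-state chain with
an 11.3 s donor-bleach budget. Recovered state means agree with truth
within 0.03 and occupancies within the molecule-level sampling error
(frames within a molecule are autocorrelated, so molecule-level — not
frame-level — error is the honest yardstick).

## Known limitations

- Apparent-FRET convention: no gamma/crosstalk corrections, so absolute
  levels on real data are instrument-dependent.
- The total-intensity bleach detector is blind to acceptor-only bleach
  (see above); real-data use should truncate at channel-specific bleach
  signatures when acceptor survival matters.
- Idealization is per-molecule ML-HMM; there is no hierarchical or
  global rate inference across molecules, no changepoint alternative,
  and no dead-time correction for sub-frame events.
- The gamma "characteristic lifetime" convention is a package choice
  (scale), stated wherever reported.
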