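# fretkin

Simulation and kinetic analysis of single-molecule FRET trajectories of
transcription elongation complexes.

## The problem

In single-molecule FRET (smFRET) experiments on transcription, a
donor/acceptor dye pair reports the conformational register of an RNA
polymerase elongation complex: distinct FRET efficiencies correspond to
distinct kinetic states (e.g. a catalytically inactive pre-translocated
state near E ≈ 0.9, a catalytically poised post-translocated state near
E ≈ 0.6, and transcript-extended or terminated states at low E). Extracting
kinetics from such data requires a chain of analyses:

1. **Trajectories** — convert two-channel intensities to FRET,
   `E = (I_A − bg_A) / ((I_A − bg_A) + (I_D − bg_D))`, with per-molecule
   photobleach detection setting the analysis horizon;
2. **Idealization** — fit a Gaussian-emission hidden Markov model by
   maximum likelihood (EM, multiple restarts), select the number of states
   by BIC, and decode the Viterbi path into piecewise-constant segments;
3. **Classification** — partition the FRET axis into low/mid/high regimes
   ([0, 0.4), [0.4, 0.7), [0.7, 1]) and sort trajectories into static,
   single-regime, and cross-regime dynamic classes;
4. **Transition density plots** — kernel-density maps of
   (FRET before, FRET after) over all transitions, whose off-diagonal
   asymmetry quantifies irreversibility;
5. **Dwell-time kinetics** — censored maximum likelihood for exponential
   (`τ̂ = Σ durations / n_uncensored`, one rate-limiting step) and gamma
   (multiple sequential steps) residence-time models.

Ensemble-level companions: a **global two-exponential decay fit**
`y_i(t) = A_1i e^{−t/τ} + A_2i e^{−t/τ_2i}` with the photobleaching
lifetime τ shared across conditions; **three-Gaussian decomposition** of
FRET-state histograms; the **1:1 steady-state affinity model**
`R_eq = R_max [A]/([A]+K_D)` for SPR titrations; and 2-aminopurine
difference-spectrum helpers.

Because raw microscope movies are rarely portable, the package ships a
first-class synthetic-data generator: continuous-time Markov state paths
(Gillespie sampling, camera-frame discretization at 0.2 s), two-channel
intensity rendering with single-step photobleaching and Gaussian noise,
plus generators for decay curves, dwell samples, binding titrations and
mixture samples — all seeded and bit-reproducible, so every analysis stage
is testable against known ground truth.

Everything takes and returns tibbles, chains with the pipe, and provides
broom-style `tidy()`/`glance()` and ggplot2 `autoplot()` methods.

## Worked example

```r
library(fretkin)

scheme <- kinetic_scheme(
  states = data.frame(label = c("inactive", "poised"),
                      fret = c(0.9, 0.6), sd = c(0.04, 0.04)),
  rates = matrix(c(0, 0.12, 0.12, 0), 2, 2, byrow = TRUE))
phot <- photophysics(total_intensity = 1000, noise_sd = 25,
                     donor_bleach_rate = 1 / 40, acceptor_bleach_rate = 0)
ex <- simulate_experiment(scheme, phot,
                          sim_config(n_frames = 600, n_molecules = 30),
                          seed = 42)

fret     <- compute_fret(ex$traces)
segments <- idealize(fret, k_max = 4, n_restarts = 6, seed = 43)
class_percentages(segments)
#>   class        n percent
#> 1 static       2    7.41
#> 5 high-mid    25   92.6
#> ...

dwells <- extract_dwells(segments, window = c(0.5, 0.7))
fit_exponential(dwells)
#> <exp_fit: tau = 10.19 +/- 1.7 s (n = 34, censored = 13)>

asymmetry_score(build_tdp(extract_transitions(segments)))
#> 0.043
```

The two-state scheme switches at 0.12 s⁻¹, so almost every trajectory
that survives long enough is dynamic between the high and mid regimes
(92.6% "high-mid"); the mid-regime dwell estimate 10.2 ± 1.7 s is
consistent with the generating mean of 1/0.12 ≈ 8.3 s; and the near-zero
TDP asymmetry reflects fully reversible switching. Bleaching is placed on
the donor channel here because the photobleach detector watches total
intensity, which acceptor-only bleaching conserves (see the methods
vignette).

Ensemble fits work the same way:

```r
curves <- dplyr::bind_rows(
  simulate_ensemble_decay(0.973, 11.3, noise_sd = 0.01,
                          condition_id = "alone", seed = 1),
  simulate_ensemble_decay(c(0.49, 0.52), c(11.3, 4.6), noise_sd = 0.01,
                          condition_id = "plus_atp", seed = 2))
global_decay_fit(curves, single_exponential = "alone") |> tidy()

simulate_binding_series(kd = 170, rmax = 100, noise_frac = 0.02,
                        seed = 3) |> fit_ssa() |> glance()
```

A YAML-driven pipeline (`run_simulate()`, `run_analyze()`) orchestrates
the full workflow with per-condition outputs and a reproducibility
manifest; `inst/scripts/fretkin-cli.R` wraps it for shell use.

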