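---
title: "Simulating motor-pool activity and intrafascicular recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating motor-pool activity and intrafascicular recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(lifesim)
```

## The problem

Decoders for peripheral-nerve prostheses must infer graded, multi-dimensional
motor intent from composite voltage traces recorded by intrafascicular
electrodes (LIFEs), each of which picks up a weighted superposition of spikes
from roughly 2-10 motor axons plus noise. Real recordings give no ground
truth: the contribution of each axon, the amount of spike overlap, and the
crosstalk between motor pools are unknown and uncontrollable. `lifesim`
generates such recordings *with* ground truth, so decoding algorithms can be
benchmarked against known intent, known spike times, and methodically varied
difficulty (overlap, noise level, receptive-field composition).

## The model

The signal chain is deliberately functional rather than biophysical; all
temporal structure of a spike is folded into its template, and everything
else is linear mixing:

1. **Activation.** Intent $u(t) \in [0,1]^n$ (one component per degree of
   freedom) maps to motoneuron activation $x(t) = G\,u(t)$, with $G$ an
   $m \times n$ non-negative gain matrix ($m \ge n$ motoneurons). Uniform
   rows of $G$ model uniform drive across a pool. Activation is interpreted
   on a normalized scale; values above 1 are clipped with a warning, keeping
   the rate-curve domain well defined (the model itself does not define
   behaviour above maximal activation).
2. **Rate coding.** Each motoneuron has a piecewise-linear rate curve with
   recruitment threshold $x_{thr}$, rate at recruitment $f_{thr}$, saturation
   activation $x_{sat}$ and saturation rate $f_{sat}$:
   $$f(x) = \begin{cases} 0 & x \le x_{thr} \\
   f_{thr} + \kappa_f\,(x - x_{thr}) & x_{thr} < x < x_{sat} \\
   f_{sat} & x \ge x_{sat}\end{cases},
   \qquad \kappa_f = \frac{f_{sat}-f_{thr}}{x_{sat}-x_{thr}}.$$
   The size principle (orderly S $\to$ FR $\to$ FF recruitment) is expressed
   by assigning low thresholds to slow units and high thresholds to fast
   ones. Note the threshold is *exclusive*: $x_{thr}$ is the activation
   above which the unit begins to fire, so a unit held exactly at its
   threshold stays silent. This choice makes recruitment boundaries exact
   (an FF pool with $x_{thr}=0.5$ contributes nothing at intent 0.5) and is
   the only reading consistent with both the threshold's definition and the
   intended meaning of $f_{thr}$ as the rate *at recruitment*.
3. **Spike timing.** Event times come from one of five point processes
   (identity, Poisson, truncated Gaussian, gamma, uniform) parameterized by
   the instantaneous mean ISI $\xi = 1/f(x)$. The train is realized
   sequentially: the rate is frozen at the previous event, one ISI is drawn,
   and the next event placed; if the unit is below threshold the clock jumps
   to the next recruited sample. The first event falls one drawn ISI after
   recruitment onset. This construction is standard in motor-unit models and
   accurate for intent that varies slowly relative to the ISI (the intended
   regime); it is *not* a thinning algorithm and will lag rate changes that
   are fast on the ISI scale.
4. **Templates.** Extracellular spike shapes are differentiated Gaussian or
   Gamma kernels, normalized to peak 1 on a unit support, then scaled to a
   per-unit amplitude and duration. Every template has zero integral (a
   recording chain with AC coupling transmits no DC) and finite energy; both
   properties are enforced on the discrete grid by subtracting the mean
   after every resampling, then peak-normalizing. Amplitudes are arbitrary
   recording units — all downstream SNR arithmetic is unit-free.
5. **Mixing.** Axon traces $y(t)$ reach electrodes through $z(t) = H\,y(t) +
   W(t)$ with $H = C\,B$: $B$ maps axons to *virtual electrodes* (pure motor
   pool signals $v = B\,y$) and $C$ adds crosstalk between pools. Distance,
   encapsulation, and (static) drift are all modeled as smaller gains.
6. **Noise.** Either $1/f^\beta$ power-law noise of specified amplitude
   (spectral synthesis with the DC bin zeroed), band-limited Gaussian noise
   calibrated to a target SNR, or a user-supplied noise file. The SNR
   convention is $\sigma_{noise} = (Q_{99.9}-Q_{0.1})/(3\,\mathrm{SNR})$,
   where the percentiles are taken on the *noise-free* composite trace of
   each electrode. Computing them per electrode makes per-electrode SNR well
   defined; the average across electrodes then satisfies the same target
   automatically.

## Key parameters and defaults

| parameter | default | units | why |
|---|---|---|---|
| sampling rate | 20000 | Hz | extracellular spikes occupy ~100 Hz-10 kHz; 20 kHz satisfies Nyquist with margin |
| ISI floor | 0.001 | s | prevents one axon overlapping itself; far below every mean ISI used here (>= 28 ms) |
| template duration | 0.002-0.006 | s | published S (4-6 ms) and FF (2-4 ms) ranges |
| template amplitude | 45-105 | a.u. | published S (45-65) and FF (95-105) ranges |
| noise band | 100-7500 | Hz | broadband relative to spike energy, below Nyquist |
| decoder window | 0.2 | s | the moving-average decoder's published setting |
| Welch window / overlap | 0.5 s / 50% | | the spectral pipeline's published setting |
| band-pass | 80-4000 Hz, order 4, zero-phase | | published order and band; zero phase so spike timing is unaffected |

The "4th-order" band-pass is realized as two poles per band edge applied
forward-backward (`signal::butter(2, band)` + `filtfilt`), with reflective
padding so start-up transients stay out of the data.

## Preset scenarios

* `build_run1()` — one ramp of intent, 6 S + 6 FF units drawn uniformly from
  the published ranges, Poisson timing, five electrodes (1 S, 6 S, 1 FF,
  6 FF, 3 S + 3 FF) with weights equally spaced on [0.5, 1] and SNR-3 noise.
* `build_run2()` — two DOFs (ramp-and-hold; contraction/relaxation bursts),
  two mixed pools, and a third electrode whose crosstalk row weights both
  pools at 0.5, so its noise-free trace is exactly the half-sum of the two
  pool signals.
* `build_run3()` — thirty electrodes (2-10 axons; all S, all FF, or an even
  mix; two replicates) at three steady intent levels. Executed with
  `run_steady_levels()`.
* `build_run4()` — the overlap sweep: fifteen electrodes (S/FF/mixed x
  2, 4, 6, 8, 10 axons), ten steady levels in 10% steps, S units 4 ms /
  5-18 Hz over the lower half of the intent range, FF units 2 ms / 18-35 Hz
  over the upper half, Poisson timing. Executed with `run_overlap_sweep()`,
  which works from spike trains and template durations only — the overlap
  statistic does not require rendered voltages.

Two scenario-level choices were genuinely open and are fixed as follows.

**Steady-level pools (run 3).** The steady-level demonstration requires
every electrode's power to grow across the three tested levels, which fails
if a pool saturates below (or recruits above) the tested range. The original
demonstration tuned these pools to mimic amputee recordings without printing
parameters, so this package chooses them on first principles: S units recruit
near zero ($x_{thr} \in [0, 0.1]$) and saturate only near maximal intent
($x_{sat} \in [0.85, 1]$); FF units recruit at intermediate intent
($x_{thr} \in [0.25, 0.4]$) with the same late saturation; levels are
low/moderate/high = 0.2/0.55/0.9. Rate ranges, durations and amplitudes keep
the published run-1 values. The noise floor of each electrode is calibrated
once (SNR 3 against its most active level) and then held fixed across
levels, as a physical electrode's noise floor would be; this is what makes
total power rise and mean frequency fall as spiking (low-frequency energy,
relative to broadband noise) comes to dominate the spectrum.

**Overlap segments (run 4).** Each (electrode, level) cell is a constant
intent segment of 10 s — long enough that the overlap estimate's standard
error is below one percentage point at the firing rates involved — rather
than a continuous ramp, because overlap is reported per level. Mixed
electrodes split axons evenly between S and FF (all counts used are even).

## Determinism

Every stochastic component draws from its own substream derived from the
master seed and a stream label (`derive_seed(seed, "mn", i)` etc.), so a
configuration re-run with the same seed is bit-identical, and adding
electrodes or noise channels never perturbs spike trains. Seeds are plain
32-bit integers.

## What the generator does and does not emulate

Passing tests on simulated data shows that the analysis chain and the model
are internally consistent and that the simulator reproduces the structural
phenomena it was built for: sequential recruitment, superposition, spike
overlap statistics, crosstalk, SNR calibration, and spectral trends across
effort levels. It does **not** show that a decoder tuned here will work on
real nerve recordings: templates are stationary (no electrode drift as a
process, no per-electrode morphology differences for one axon), the
intent-to-activation map is linear, there are no conduction delays, fatigue,
or indirect pathways, and noise is stationary Gaussian or power-law rather
than the mixture of EMG, ECG and instrumentation artifacts seen in vivo.

## Numerical choices and degenerate inputs

* Events align to the nearest sample (<= 25 us jitter at 20 kHz, far below
  2-6 ms templates); template copies are truncated at the recording edge.
* Zero-mean enforcement happens after every resampling, so the discrete
  zero-integral law holds to floating precision at any duration.
* Stochastic ISIs are kept at or above the floor by rejection (truncated
  Gaussian) or clipping (Poisson, gamma, uniform); at the rates used here
  the induced bias is orders of magnitude below sampling error.
* `noise_sigma_from_snr()` refuses constant traces (the percentile span, and
  hence the SNR, is undefined); `quiescent_normalize()` refuses zero-variance
  quiescent segments; pool sampling redraws inconsistent threshold/saturation
  pairs up to 100 times before erroring, preserving marginal uniformity.
* Activation above 1 after the $G$ product is clipped with a warning.

## A worked example

```{r run1, eval = FALSE}
cfg <- build_run1(seed = 1, duration = 10)
res <- run_simulation(cfg)

# ground truth and measured SNR on the 6-S electrode
length(res$trains[[1]]$event_times)
measured_snr(res$recording$pure[2, ], res$recording$noise[2, ])

# overlap sweep and its headline number
sweep <- run_overlap_sweep(build_run4(seed = 1), seeds = 1:3)
max(sweep$percent_overlap)
```

The decoding-recovery check used in the test suite runs the mixed electrode
of a noise-free run-1 ramp through the 200 ms moving-average decoder,
smooths (1 s moving average for rank correlation; 2 s bin means for
monotonicity), and verifies that the decoded trajectory is monotone
non-decreasing and rank-correlates with the true ramp at rho > 0.95.

## Problem sizes used by the test suite

The packaged tests simulate 10 s per condition at 20 kHz: the full overlap
sweep (15 electrodes x 10 levels x 3 seeds), the 30-electrode steady-level
set (3 levels), and single run-1/run-2 executions; ISI calibrations use
10^4-10^5 draws. These sizes put Monte-Carlo error comfortably inside every
asserted tolerance while keeping a complete run in the low minutes on one
core.
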