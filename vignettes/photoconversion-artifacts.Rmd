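---
title: "Quantifying photoconversion artifacts: models, simulators and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photoconversion artifacts: models, simulators and analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photoblueR)
```

## The problem

Repeated illumination in confocal and STED microscopy does two things to
organic fluorophores: it photobleaches them (red → dark) and it can
photoconvert them into species with blue-shifted emission
("photoblueing", red → blue). The photoblued species shows up in detection
channels normally reserved for other dyes, shifts ratiometric spectral
readouts, and — through a separate mechanism, partial bleaching of
multi-dye conjugates — changes apparent fluorescence lifetimes. All of
these bias quantitative microscopy readouts.

photoblueR packages a seeded synthetic photophysics simulator together with
the analyses used to quantify these artifacts, so every stage of the
pipeline can be verified end-to-end without experimental data: the
generators' ground truth is known exactly, and the analyses must recover
it.

## The kinetic model

We model the fluorophore pool as three species with first-order
continuous-time kinetics, sampled at integer frame indices (one imaging
frame = one unit of light dose):

* red → blue at rate $k_{blue}$ (photoconversion),
* red → dark at rate $k_{bleach,red}$ (bleaching of the original dye),
* blue → dark at rate $k_{bleach,blue}$.

With $\lambda = k_{blue} + k_{bleach,red}$ the closed form is
$f_{red}(t) = e^{-\lambda t}$ and
$f_{blue}(t) = k_{blue}(e^{-k_{bleach,blue}t} - e^{-\lambda t}) /
(\lambda - k_{bleach,blue})$, with the obvious limit when the two decay
rates coincide. Direct blue → red back-conversion is excluded: nothing in
the observable series requires it and it would not be identifiable from
fraction-versus-frame data alone. `simulate_photoconversion()` evaluates
the closed form; `euler_photoconversion()` is a fine-step Euler integrator
kept as an independent numerical cross-check (they agree to below 1e-6 for
rates up to ~1/frame).

No measured rate constants exist for these photoreactions, so the scenario
presets are calibrated to the qualitative magnitudes a strongly converting
red dye shows: about 20% of the initial pool photoblued after ten frames
with strong parallel bleaching (`star_red_confocal`: $k_{blue} = 0.04$,
$k_{bleach,red} = 0.12$ per frame), a photostable control
(`atto655_confocal`), and an oxygen-depleted arm in which only $k_{blue}$
is suppressed (tenfold, as photoblueing is an oxidative pathway while
bleaching proceeds through several channels). These presets are stated
working conditions, not measurements.

Exchangeable (PAINT-mode) probes bind their target transiently, so
photodamaged molecules are replaced from the solution reservoir between
frames. We model this as a full pool reset at the start of every frame —
the trajectory stays at $(1, 0, 0)$ — rather than as partial exchange
kinetics; the reservoir is effectively infinite and unilluminated, and the
paper-level observable (no spectral shift, stable GP) only requires the
limit.

## Spectra and unmixing

Emission bands are asymmetric log-normal peaks
$$I(\lambda) = A \exp\left(-\ln 2\,
  \left[\frac{\ln(1 + 2a(\lambda - \lambda_{max})/w)}{a}\right]^2\right),$$
parameterized by peak counts $A$, peak position $\lambda_{max}$,
approximate FWHM $w$, and asymmetry $a$ (frozen at 0.24 throughout, the
standard value for red emitters; the Gaussian with FWHM $w$ is the
$a \to 0$ limit). This is the standard asymmetric log-normal peak shape
expressed directly in the parameters of interest; spectra are integrated
over 16 channels of 12.5 nm by the midpoint rule, which is accurate to
well below the shot-noise level since the channel width is small against
$w \approx 50$ nm.

Unmixing follows the two-step protocol: fit the pre-irradiation spectrum
with one component to freeze the reference dye's $\lambda_{max}$ and $w$,
then fit every later spectrum with reference-plus-unknown, refitting only
the reference's amplitude. The photoblued species' peak is constrained
blueward of the reference by at least 2 nm (smaller shifts are not
considered detections). Fits are weighted least squares with Poisson
weights $\sqrt{y + 1}$ via Levenberg–Marquardt (minpack.lm), started from
a coarse grid of candidate shifts and widths because overlapping
asymmetric bands make the objective multi-modal.

Two choices deserve emphasis:

* **Background.** A constant detector offset is fitted jointly with the
  band(s) (`background = "fit"`). We first implemented pre-subtraction of
  an edge-channel estimate, but any such estimator swallows part of the
  band's own red tail (~0.3% of peak in typical geometry), and a noiseless
  round trip showed this distorts the recovered blue shift by ~1.5 nm and
  the emission fraction by ~0.04. Joint fitting removes the bias exactly;
  pre-subtraction remains available as `background = "subtract"`.
* **Fraction definition.** The photoblued "emission fraction" is the
  bin-integrated area fraction over the recorded window (excitation- and
  amplitude-scale independent); amplitude fractions are also reported for
  comparison.

## FCS: correlation, models, brightness, spot size

Intensity traces are correlated with a streaming multi-tau correlator
(Rcpp): 16 linear lags in the first octave, then 8 lags per octave with
pairwise coarsening, symmetric normalization (each lag's two window means
taken over the overlapping samples only). `direct_correlate()` is a
brute-force reference evaluating the identical estimator definition with
independent code; on integer photon counts both routes are exact in double
precision and agree bitwise. Per-lag standard errors come from splitting
the trace into 10 segments; repeat curves are averaged lag-by-lag before
fitting (`average_curves()`), as in standard FCS practice.

Curves are fitted to the two-dimensional anomalous-diffusion model
$$G(\tau) = \frac{1}{N}\left(1 + (\tau/\tau_D)^\alpha\right)^{-1},$$
optionally multiplied by the triplet factor
$(1 - T + T e^{-\tau/\tau_{triplet}})$. Any parameter can be frozen — the
conventional choice for red-detection membrane curves is
$\tau_{triplet} = 5\,\mu s$ — and $\alpha$ is bounded to $[0.3, 2]$. The
first correlator lag is excluded by convention (shot-noise/afterpulsing
territory on real hardware). Brightness is $Q = \bar{r}/N$; molecule
percentages divide $N$ by the initial red-channel $N$; the apparent STED
spot follows $\omega_{0,STED} = \omega_{0,conf}
\sqrt{\tau_{D,STED}/\tau_{D,conf}}$.

The trace simulator realizes the model's physical picture directly: 2D
Brownian walkers in a periodic box observed through a Gaussian profile
$e^{-2r^2/\omega_0^2}$, a per-molecule bright/dark telegraph chain with
stationary dark fraction $T$ and correlation time $\tau_{triplet}$, and
Poisson photon counting. Three numerical choices matter:

* the realized molecule count is a Poisson draw around
  (density × box area) — the box is a patch of an infinite membrane, and a
  fixed count would depress $G(0)$ by $1/M$;
* the box must be large against the beam: its slowest diffusion mode
  relaxes on $L^2/4\pi^2 D$, which truncates the correlation tail. The
  default $L = 25\,\omega_0$ puts that cutoff at ~60 diffusion times,
  making the residual $\tau_D$ bias ~1%; smaller boxes (e.g.
  $L \approx 6\,\omega_0$) bias $\tau_D$ low by tens of percent;
* the bin time defaults to ~1/36 of the transit time — fine enough to
  resolve the decay, coarse enough that a 60 s trace stays cheap.

Default conditions emulate a fluid-bilayer lipid analogue: $D = 1$
µm²/s, $\omega_0 = 240$ nm (so $\tau_D = 14.4$ ms), 30 kcounts/s per
molecule at beam center, $N = 5$ in the spot, 60 s traces for parameter
recovery and 10 s acquisitions (×6 repeats — two measurements per spot in
three independent experiments — with curves averaged before fitting) inside
scenarios. At these sizes single 60-s fits recover $N$ to a few percent
and $\tau_D$ to ~10–15%.

## GP imaging

The ratiometric readout is per-pixel generalized polarization
$GP = (I_b - I_r)/(I_b + I_r)$ with $I_b$, $I_r$ the 580–630 and
650–700 nm band intensities. Membrane pixels are selected on the summed
image at a threshold fraction (default 0.2) of the maximum summed
intensity — the threshold is configurable and recorded, since the
published analyses do not state a numeric value — and saturated pixels
are excluded unconditionally. Pixels with $I_b + I_r = 0$ are masked, not
set to zero, which would bias ROI means. For time series the frame-0 mask
is reused for all frames so that bleaching-driven mask shrinkage cannot
itself shift the mean; the ROI statistic is the unweighted mean of
per-pixel GP.

The stack synthesizer couples the kinetics to the imaging model: the
original probe splits emission between the bands according to the
ground-truth GP, while the photoblued fraction emits entirely in the blue
band with a configurable relative brightness, so the apparent GP
$$GP_{app} = \frac{f_{red}\,GP_{true} + \beta f_{blue}}
                  {f_{red} + \beta f_{blue}}$$
exceeds the truth monotonically in $f_{blue}/f_{red}$ — the artifact the
exchangeable probe avoids by construction.

## FLIM

TCSPC decays live on one 25 ns excitation period (40 MHz repetition). Two
estimators are provided, deliberately simple and fully specified (the
commercial fitting software they stand in for is proprietary, and no
parity with it is claimed):

* `mean_arrival`: background-subtracted mean arrival time, inverted
  through the truncated-exponential mean
  $\langle t\rangle(\tau) = \tau - P e^{-P/\tau}/(1 - e^{-P/\tau})$. The
  background is estimated from the last 10% of the period and refined by
  subtracting the decay's own expected tail contribution (a fixed-point
  iteration; without it a $\tau = 3.5$ ns lifetime reads ~2% low).
* `mono_exp_fit`: weighted least-squares $A e^{-t/\tau} + B$ on the decay
  tail from two bins past the histogram peak, so a narrow instrument
  response does not enter the fitted window.

The multi-dye quenching mechanism is a two-level switch: while ≥ 2 dyes on
an antibody survive, photons carry the quenched lifetime (default 2.3 ns)
at a reduced per-dye yield (default 0.35); exactly one survivor emits
unquenched (3.5 ns, yield 1). Per-dye bleaching is i.i.d. per frame
(default 0.12), so survivor counts follow a binomial Markov chain with an
exact closed form (`antibody_flim_expectation()`) used as the oracle for
the stochastic ensemble. A quenched yield below one half reproduces the
characteristic intensity bump (rise, then bleaching-driven fall) alongside
the >1 ns lifetime rise; FRET-radius physics is deliberately not modeled.
Frame decays pool all photons of the ensemble (per-pixel fitting is out of
scope, and the pooled alternative is stated openly).

## Scenarios, seeding, determinism

`scenario_config()` holds the full parameter tree (unknown keys rejected);
`run_scenario()` executes the selected stages and aborts with the stage
name if any fit flags non-convergence. All randomness derives from the one
scenario seed through fixed integer offsets, so every table is
bit-reproducible from config + seed; `run_scenario(cfg, out_dir = )`
writes the tables as CSV and the resolved config with its hash as JSON.

## What the synthetic data does and does not show

The generators reproduce the statistical structure the analyses assume:
first-order conversion kinetics, log-normal bands on a uniform 16-channel
grid, Gaussian-profile 2D diffusion with telegraph blinking and Poisson
counting, binomial dye survival, wrapped-exponential arrival times. Real
data differ in ways the simulator intentionally omits: photon antibunching
and detector afterpulsing, 3D beam structure and STED depletion-pattern
physics, spectral instrument response, partial (rather than complete)
probe exchange, spatially heterogeneous membranes, and any photochemical
mechanism behind the rate constants. Passing tests therefore certify the
analysis chain — estimator correctness, calibration recovery, artifact
sign and monotonicity — not the photochemistry of any particular dye.

## Problem sizes

Tests and the acceptance script run at the study conditions above: 60 s
traces (10 seeds) for FCS recovery, 3 seeds per arm for the spot-size
calibration, 2×10^5-count spectra, 48×48×31 image stacks at 500
counts/pixel, and 4000–20000-antibody ensembles. These sizes were chosen
so each check has comfortable statistical margin while the whole suite
runs in minutes.
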