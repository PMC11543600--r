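# photoblueR

Illumination in confocal and STED microscopy doesn't just photobleach
fluorophores — it can photoconvert them into blue-shifted emitters
("photoblueing"). The converted species leaks into detection channels meant
for other dyes, biases ratiometric spectral readouts such as membrane-packing
(GP) imaging, and — through a distinct mechanism, partial bleaching of
multi-dye antibody conjugates — shifts apparent fluorescence lifetimes.

photoblueR is for microscopists and methods developers who want to quantify
these artifacts and verify the quantification itself. It pairs a fully seeded
synthetic photophysics simulator with the analyses used on real data, so
every estimator can be validated against exact ground truth:

* **Kinetics** — three-state first-order scheme red → blue → dark (with a
  direct red → dark branch), solved in closed form per illumination frame;
  exchangeable (PAINT-mode) probes modeled as per-frame pool replenishment.
* **Spectra** — 16-channel (12.5 nm) emission spectra as asymmetric
  log-normal bands
  `I(λ) = A exp(−ln2 [ln(1 + 2a(λ−λmax)/w)/a]²)` (asymmetry a = 0.24);
  two-component unmixing with the reference dye frozen from the
  pre-irradiation spectrum recovers the photoblued species' peak shift and
  emission fraction.
* **FCS** — 2D Brownian trace simulation through a Gaussian spot with
  triplet blinking; streaming multi-tau correlator (Rcpp) with a brute-force
  oracle; fits of `G(τ) = (1/N)(1+(τ/τD)^α)^{-1}` with optional triplet
  factor `(1−T+T·e^{−τ/τtriplet})`; brightness `Q = rate/N`, molecule
  percentages `100·N/N0`, and STED spot calibration
  `ω0,STED = ω0,conf·√(τD,STED/τD,conf)`.
* **GP imaging** — two-channel membrane stacks with known ground-truth
  `GP = (Ib − Ir)/(Ib + Ir)`, intensity-threshold membrane masking with
  saturated-pixel exclusion, and bias time series over illumination frames.
* **FLIM** — wrapped-exponential TCSPC decays (25 ns period, 40 MHz);
  mean-arrival (with truncated-exponential correction) and tail-fit
  estimators; binomial dye-survival model for the quenching-driven lifetime
  rise of multi-dye conjugates.

## Worked example

Simulate the kinetics of a strongly converting red dye (4%/frame conversion,
12%/frame bleaching — the regime in which a fifth of the pool is photoblued
within ten frames), generate the matching noisy spectral series, and unmix
it:

```r
library(photoblueR)

pk <- photo_kinetics(k_blue = 0.04, k_bleach_red = 0.12)
tail(simulate_photoconversion(pk, 10), 3)
#>    frame  f_red f_blue f_dark
#> 9      8 0.2780 0.1805 0.5415
#> 10     9 0.2369 0.1908 0.5723
#> 11    10 0.2019 0.1995 0.5986

ser <- synth_spectral_series(pk, frames = c(0, 10, 20, 30),
  spectrum = scenario_preset("star_red_confocal")$spectrum, seed = 42)
bf <- blue_fraction_series(ser$spectra, ser$initial)
data.frame(frame = c(0, 10, 20, 30), fraction_blue = bf$fraction_blue,
           truth = ser$fraction_true, shift_nm = bf$shift_nm)
#>   frame fraction_blue  truth shift_nm
#> 1     0        0.0021 0.0000   2.0000
#> 2    10        0.5395 0.4973  20.3775
#> 3    20        0.8835 0.8548  21.5928
#> 4    30        1.0000 0.9679  21.2419
```

After ten frames ~20% of the molecules are photoblued (`f_blue`), and the
unmixing recovers both the emission fraction of the blue-shifted species and
its ~22 nm peak shift from 2×10⁵-count spectra. `run_scenario()` chains all
five stages from one seeded configuration; the numbered scripts under
`analysis/` run each quantification and write its table to `results/`:

```sh
Rscript analysis/01_photoconversion_kinetics.R
Rscript analysis/03_fcs_molecule_counts.R   # molecule % and brightness Q
```

## Layout

* `R/`, `src/` — package code (simulators, correlator, fitters, scenario
  runner).
* `analysis/` — numbered narrative drivers, one per quantification.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
* `vignettes/photoconversion-artifacts.Rmd` — the models, their
  assumptions, parameter defaults and numerical choices.
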