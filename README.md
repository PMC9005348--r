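# caswitch

Kinetic analysis of photo-switchable genetically encoded Ca²⁺ sensors.

Reversibly switchable Ca²⁺ indicators (rsGEIs) photo-switch only when
Ca²⁺-bound: 488-nm light drives the bound state OFF, 405/420-nm light
switches it back ON, and the **bulk OFF-switching decay constant τ gets
faster with Ca²⁺ concentration**. Because τ is a ratio-free, kinetic
observable, it survives the depth-dependent light fluence that corrupts
absolute amplitudes in tissue — which is what makes these sensors readable
by optoacoustic (OA) tomography and by RESOLFT-type super-resolution
microscopy. This package is for researchers analysing (or simulating) such
measurements: it provides the forward photophysics model, seeded
synthetic-data generators with embedded ground truth, the per-pixel
temporal unmixing of OA image time-series, the τ→Ca²⁺ calibration, and the
SRM photophysics/deconvolution toolchain.

## The model in brief

Equilibrium binding is a single-site Hill isotherm,
*f*(c) = cⁿ/(K_d ⁿ + cⁿ). The recorded signal is

    s(t) = g(t) · B · f · [α·p_fast(t) + (1−α)·p_slow(t)]
         + ε_free·(1−f)·B + d

with two switchable species decaying under 488-nm light at rates σ_fast·I
and σ_slow·I, recovering under 405/420-nm light at σ_on·I, mixing weight
α = f, per-cycle photo-fatigue g, a dim non-switching free state ε_free,
and dark offset d. Pixels are classified as switching by a frequency-domain
score plus the r² of a single-exponential fit to the cycle-averaged 488-nm
phase; masked pixels are fitted with a fixed-offset exponential (offset
from the Ca²⁺-saturated reference) and calibrated with a four-parameter
logistic in log₁₀[Ca²⁺] whose endpoints are pinned to the measured extremes
("dose–response with Hill slope"). Details and all defaults are in the
methods vignette, `vignettes/photoswitching-calcium-readout.Rmd`.

## Worked example

Simulate the four-tube phantom, unmix it, and recover relative Ca²⁺:

```r
library(caswitch)

res <- run_pipeline(list(
  out_dir  = "results/phantom_run",
  seed     = 3,
  sensor   = list(kd = 0.46),                      # cytosolic-affinity variant
  schedule = caswitch:::schedule_to_list(
    oa_tomography_schedule(pulses_per_frame = 10)), # 10×(120+120) pulses, 240 frames
  noise_sd = 0.002))

res$summary[res$summary$kind == "sensor",
            c("ca_true", "n_masked", "tau_mean", "tau_sd", "ca_est")]
```

prints (tube concentrations in µM, τ in seconds):

```
  ca_true n_masked tau_mean tau_sd ca_est
1    0.35      197    5.142 0.1002   0.35
2    1.35      197    1.989 0.0502   1.35
3    5.20      197    0.761 0.0201   2.34
4   39.00      197    0.514 0.0191  39.00
```

Every sensor-tube pixel is detected (197/197 per tube, zero blood false
positives), the decay constant falls monotonically with Ca²⁺, and inverting
the fixed-endpoint dose–response recovers the concentration ranking
exactly. The middle tubes invert close to truth while 5.2 µM lands at
2.3 µM — at 0.002 a.u. frame noise the upper tubes sit near the fast end of
the calibration where τ changes little per decade of Ca²⁺, a limitation the
vignette discusses.

The numbered scripts under `analysis/` run the full study as a narrative:
`01_characterize_sensor.R` (binding curve: Kd = 70.8 ± 2.0 µM recovered
from a noisy titration generated at 72 µM; ER occupancy 87.4% ≈ 90%;
global biexponential rates 3.00/0.40 s⁻¹; fatigue 0.50%/cycle),
`02_spectrometer_calibration.R` (six-concentration 0–39 µM series →
fixed-endpoint calibration and round trip), `03_phantom_unmixing.R` (the
example above), `04_srm_photophysics.R` (pump-probe average rate,
ON-power series, 80-nm line-profile FWHM, Richardson–Lucy contrast). Each
writes its tables under `results/`.

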