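---
title: "Kinetic readout of photo-switchable calcium sensors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetic readout of photo-switchable calcium sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caswitch)
```

## The measurement principle

Reversibly switchable genetically encoded Ca²⁺ indicators (rsGEIs) couple a
calmodulin-type binding domain to a reversibly switchable fluorescent
protein. Only the Ca²⁺-bound form photo-switches: 488-nm light drives it to
a dark OFF state, 405/420-nm light switches it back ON. The Ca²⁺-free form
is dim and does not switch. Crucially, the *bulk OFF-switching kinetics
speed up with Ca²⁺ concentration*, so the decay constant τ of the signal
under pulsed 488-nm illumination encodes Ca²⁺ — an observable that is
robust to absolute intensity and therefore usable deep in tissue, where
optoacoustic (OA) imaging reads the absorbing states but absolute
amplitudes are confounded by light fluence.

`caswitch` implements the full computational readout around this idea:

1. a forward model of Ca²⁺-dependent photo-switching (`simulate_trace()`),
2. seeded generators for every input the analyses consume
   (`make_titration()`, `make_spectrometer_series()`,
   `make_phantom_stack()`),
3. the per-pixel temporal unmixing of OA image series
   (`classify_pixels()`, `fit_pixel_kinetics()`),
4. the dose–response calibration linking τ to Ca²⁺
   (`fit_dose_response()`, `invert_tau()`), and
5. the super-resolution microscopy (RESOLFT-type) photophysics analyses
   (`pump_probe_off_kinetics()`, `double_gaussian_fwhm()`,
   `dual_gaussian_psf()`, `rl_deconvolve()`).

## The forward model

### Binding

Equilibrium occupancy follows a single-site Hill isotherm,

$$f(c) = \frac{c^{n}}{K_d^{\,n} + c^{\,n}},$$

with dissociation constant $K_d$ (µM) and Hill coefficient $n$
(default 1). The isotherm form is a modelling choice — it is the standard
description for GCaMP-family sensors — and $n$ is left free so cooperative
variants can be represented.

### Switching

The observed signal is

$$s(t) = g(t)\, B\, f \left[\alpha\, p_\mathrm{fast}(t) +
  (1-\alpha)\, p_\mathrm{slow}(t)\right] +
  \varepsilon_\mathrm{free}(1-f)B + d,$$

where $B$ is the bound-state brightness, $\varepsilon_\mathrm{free}$
(default 0.1) the relative brightness of the non-switching free state, $d$
a non-modulating dark offset, and $p_\mathrm{fast}, p_\mathrm{slow}$ the
ON-state occupancies of two switchable species. During 488-nm phases each
species decays with rate $\sigma_i I$ (defaults
$\sigma_\mathrm{fast} = 3.0$, $\sigma_\mathrm{slow} = 0.4$ s⁻¹ per unit
intensity); during 405/420-nm phases both recover with rate
$\sigma_\mathrm{on} I$ (default 5.0). Rates scale linearly with intensity
$I$; saturation is not modelled. $g(t)$ is the accumulated photo-fatigue:
the switchable amplitude loses a fraction `fatigue_per_cycle` at every
ON→OFF phase boundary.

The mixing weight is tied to occupancy, $\alpha(c) = f(c)$: Ca²⁺-bound
molecules switch fast, a residual pool slow. Bulk fluorescence decays at
different Ca²⁺ concentrations are biexponential with *shared rates* and
Ca²⁺-dependent amplitudes — the "at least two species" signature — while
the effective single-exponential τ decreases monotonically with Ca²⁺. The
identity of the two species (protonation vs. conformation) is not modelled;
this mixing rule is the minimal mechanism reproducing the Ca²⁺-dependent
bulk kinetics, and is our convention.

### Time base and sampling

Every trace and stack is sampled one value per laser pulse at
`pulse_rate` Hz (default 10 Hz), and consecutive `pulses_per_frame` pulses
are averaged into one recorded frame (default 3, the acquisition's
three-pulse averaging). The default tomography schedule is ten cycles of
120 pulses at 488 nm followed by 120 pulses at 420 nm. Because the sum of
exponentials sampled on a regular grid averages to an exponential with the
same rate, pulse averaging rescales amplitudes but leaves decay constants
unbiased.

## Synthetic data: what it emulates, and what it does not

The generators embed their ground truth in the returned objects and are
bit-reproducible under a fixed integer seed (`withr::with_seed`; a pipeline
base seed is fanned out deterministically per stage).

* `make_titration()` — equilibrium fluorescence vs. Ca²⁺ with
  multiplicative replicate noise (default CV 2%, 3 replicates), mirroring a
  dilution titration from 0.1 µM to 10 mM.
* `make_spectrometer_series()` — per concentration, six OFF-switching
  decays are simulated, averaged, and max-normalised, following the OA
  spectrometer protocol.
* `make_phantom_stack()` — a tube phantom: sensor disks at stated free-Ca²⁺
  concentrations and blood disks (static absorbers) in a zero background,
  with depth-dependent fluence $I(x, y) = e^{-\mu_\mathrm{eff}\,
  \mathrm{depth}}$ from one illumination side. Fluence scales both the OA
  amplitude (linear-response regime) and the switching rates, which
  reproduces the depth confound: equal concentrations at different depths
  show different apparent τ. Illumination is reduced to an axis-aligned
  direction so the fluence field stays separable and testable; the default
  phantom is 128 × 128 px at 0.1 mm/px with four sensor tubes
  (0.35/1.35/5.2/39 µM) side by side at equal depth plus two blood tubes.

What the generators do *not* emulate: acoustic propagation and transducer
response, tomographic reconstruction artefacts, motion, spectral colouring
of blood, shot noise (noise is additive Gaussian per frame), and any
intensity saturation of switching. Passing tests therefore demonstrate the
correctness of the analysis chain under the stated forward model, not
robustness to every artefact of real instrument data.

Two affinity settings are used. Binding and ER-occupancy analyses use the
ER-targeted variant ($K_d = 72$ µM). The spectrometer and tomography
calibration analyses use a cytosolic-affinity variant ($K_d = 0.46$ µM,
the GCaMP5G affinity, since the tomography sensor responds like GCaMP5G);
only that choice puts the 0–39 µM calibration span across the binding
transition — with the ER affinity the span has no transition and a
dose–response is unidentifiable.

## Per-pixel unmixing

A pixel is accepted as photo-switching when two measures agree
(`classify_pixels()`):

1. **Fourier score** — the per-frame trace is mean-detrended and the DFT
   magnitude at the cycle frequency (`n_cycles` periods per record) is
   divided by the summed magnitude over all positive non-zero frequencies.
   The score is scale-free and lies in [0, 1]; a constant trace scores 0
   and white noise about 1/#bins. Default threshold θ_f = 0.2.
2. **Goodness of exponential fit** — r² of a free-offset single-exponential
   fit to the cycle-averaged 488-nm phase. Default threshold θ_r = 0.8 with
   polarity "high": switchable pixels must be *well* described by an
   exponential decay. The opposite polarity is selectable
   (`r2_polarity = "low"`) because the combination of the two measures can
   be stated either way round depending on whether the r² refers to the
   switching or the static model; on synthetic data only the "high"
   polarity reproduces the ground-truth masks.

The measures are combined with AND. Cycle averaging (align all 488-nm
phases, average across cycles) precedes every per-pixel fit; fatigue scales
cycle amplitudes uniformly, so the average remains a clean exponential.

Masked pixels are then fitted with a *fixed-offset* exponential
(`fit_pixel_kinetics()`), the offset $y_0$ taken from a free fit to the
ROI-mean trace of the highest-Ca²⁺ sample (`reference_offset()`), exactly
as the tomography analysis pins the offset from the saturated tube. For
mesoscopy data, `on_off_difference()` provides the proportional
(ON − OFF)/ON unmixer.

## Calibration

`fit_dose_response()` fits a four-parameter logistic in
$\log_{10}$ concentration,

$$\tau(c) = \tau_\mathrm{min} + \frac{\tau_\mathrm{max} -
  \tau_\mathrm{min}}{1 + 10^{(c - \log_{10}\mathrm{EC}_{50})\, h}},$$

the standard "dose–response with Hill slope". With `fix_from`, the
asymptotes are pinned to the measured τ of the stated minimum and maximum
concentration samples and only EC₅₀ and slope remain free — the
fixed-endpoint strategy that makes the fit converge on noisy series. τ is
modelled as decreasing with Ca²⁺ (kinetics are faster at higher Ca²⁺), but
the fit accepts either slope sign and canonicalises the parameters.
`invert_tau()` is the closed-form inverse; τ outside
$(\tau_\mathrm{min}, \tau_\mathrm{max})$ clamps to the corresponding
endpoint concentration with an `out_of_range` flag.

A `ca = 0` sample is special: in this model the Ca²⁺-free sensor does not
switch at all, so no finite τ exists at exactly zero and `ca = 0` is
representable only as the pinned $\tau_\mathrm{max}$ endpoint. In
practice the lowest measurable concentration of a series supplies that
endpoint.

One honest caveat, visible in the acceptance suite: the effective τ of a
*biexponential* mixture fitted with a single exponential is not exactly
logistic in log concentration. Near the upper plateau, where
$d\tau/d\log c \to 0$, a ~1–2% τ lack-of-fit translates into ~10%
concentration error on inversion (the 0.1 µM point of the kit-style
series); mid-transition points invert to within ~1%. Concentrations close
to a pinned plateau are intrinsically poorly identified by this readout.

## SRM photophysics

* `pump_probe_off_kinetics()` averages repeated pump-probe cycles and fits
  a biexponential plus offset. The reported *average rate* is the
  amplitude-weighted mean $(A_1 k_1 + A_2 k_2)/(A_1 + A_2)$ — the
  convention chosen here, since no single formula is standard — and the
  *background level* is the fitted value at the end of the 488-nm pulse as
  a fraction of the initial fluorescence.
* `double_gaussian_fwhm()` fits a sum of two Gaussians plus baseline to a
  line profile (single Gaussian first, the second component seeded from the
  residual peak) and reports $2\sqrt{2\ln 2}\,\sigma$ per resolved
  component.
* `dual_gaussian_psf()` builds the deconvolution kernel: a 50-nm-FWHM
  Gaussian plus a 175-nm-FWHM Gaussian at 10% amplitude, normalised to
  unit sum and truncated at ±3σ of the wide component. "10% of the PSF
  amplitude" is read as *peak* amplitude by default; an integrated-energy
  reading is available via `amp_mode = "area"`.
* `rl_deconvolve()` runs standard multiplicative Richardson–Lucy updates
  (default 5 iterations) with reflective boundary handling; with a
  normalised kernel and interior-supported objects the update conserves
  total intensity exactly.

## Numerical choices

* Nonlinear least squares uses Levenberg–Marquardt (`minpack.lm::nlsLM`)
  with analytic-free multi-start initialisation: decay fits seed τ from a
  log-linear regression and fall back to spans of the record; the
  biexponential profile out its linear amplitudes and optimises only the
  two rates from several starts, always including the degenerate
  single-rate solution so the nested-model inequality (biexponential
  residual ≤ single-exponential residual) holds by construction.
* Decay fits report `valid = FALSE` — never an exception — for constant
  traces, amplitudes below the floor (3× the noise estimate from the
  median absolute deviation of first differences), or non-convergence.
  Per-pixel failures propagate as `NA`/mask-false.
* Extreme-scale start values (e.g. a baseline of 10⁻⁴⁶ from an exact-zero
  tail) are clamped to 0 before fitting; they break LM parameter scaling.
* The Fourier score returns 0 when the detrended residual is numerical
  dust (below 10⁻¹² of the trace scale), so constant pixels cannot acquire
  spurious scores from floating-point noise.
* TIFF stacks: 32-bit samples pass through an asymmetric scaled-integer
  conversion in the underlying library, so frames are affinely mapped to
  [0, 1] (scale and offset in the JSON sidecar) and snapped to a uint32
  grid with a quarter-step margin. The first write quantises at ~2 × 10⁻¹⁰
  of the data range; thereafter write → read is bitwise idempotent.
  Integer input stacks are promoted to float with the source bit depth and
  scale recorded.

## Problem sizes

The test suite runs reduced but structurally identical conditions: phantom
classification uses the full 128 × 128 grid with the complete
10 × (120 + 120) pulse schedule averaged to 240 frames; module tests use
48 × 48 phantoms and 4-cycle schedules. The analysis scripts under
`analysis/` run the same sizes and write their tables under `results/`.

## Known limitations

* Effective-τ calibration degrades near the plateaus of the dose–response
  (see above); absolute Ca²⁺ quantification in vivo, and any fluence
  correction model, are out of scope.
* The two-species mechanism is a phenomenological minimum; photochemical
  microkinetics (cis/trans isomerisation, protonation states) are not
  modelled.
* The classifier's probability combination is a hard AND of two
  thresholds; no soft/weighted score is provided.
* Noise is Gaussian and frame-independent; correlated acquisition noise
  will widen all recovery tolerances.
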