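---
title: "Measuring two-photon excitation efficiency of pulsed lasers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring two-photon excitation efficiency of pulsed lasers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etalaser)
```

## The problem

Two-photon (2p) fluorescence excitation requires two photons to arrive
at a fluorophore nearly simultaneously, so the excitation rate scales
with the *square* of the instantaneous light intensity. Femtosecond
pulsed lasers concentrate their average power into ~100 fs bursts
precisely to exploit this: at a fixed average power $P_{av}$, shorter
and cleaner pulses produce more fluorescence. Commercial lasers are
specified by average power, repetition rate $R$, and pulse duration
$\tau_p$ — but two lasers with identical specifications can differ
substantially in the fluorescence they actually generate, because pulse
*shape* defects (satellite "side lobes", pedestal energy, spurious
pulses) divert energy away from the central peak where it no longer
contributes meaningfully to 2p excitation.

`etalaser` implements the quantitative machinery for diagnosing this:
pulse-profile simulation, intensity autocorrelation analysis,
trace-based fluorescence prediction, the efficiency statistic $\eta$,
and the camera-image pipeline that turns frames of a fluorescent
excitation volume into the measurements $\eta$ is computed from.

## Model and estimators

### Fluorescence from a pulse profile

For a train of identical pulses $P_{pulse}(t)$ at repetition rate $R$,

$$F \propto R \int P_{pulse}^2(t)\,dt .$$

`predict_fluorescence()` evaluates this with trapezoidal sums — the
package's only quadrature rule, applied consistently so that simulated
and file-loaded (e.g. FROG-reconstructed) traces are treated
identically. Because reconstructed traces come in arbitrary amplitude
units, the trace is first rescaled so its integral equals the
single-pulse energy $P_{av}/R$ at an assumed average power (1 W by
default). Two consequences are guaranteed algebraically and tested as
properties: predictions scale exactly with $P_{av}^2$, and they are
invariant to the input trace's amplitude units. Only *ratios* of
predictions are meaningful; no absolute proportionality constant is
ever fixed.

For an idealized square pulse the integral collapses to the scaling law

$$F \propto \frac{P_{av}^2}{R\,\tau_p},$$

(`ideal_fluorescence()`), which holds for any fixed pulse shape and is
the "ideal" yardstick that defines efficiency.

### Autocorrelation and the 1.54 factor

Femtosecond pulses are too fast to record directly; autocorrelators
measure the intensity autocorrelation function (ACF)

$$A(\tau) = \int P(t)\,P(t+\tau)\,dt,$$

which is symmetric for *any* pulse profile and is reported
peak-normalized. The "autocorrelation time" is the full width of the
ACF at half its amplitude; instrument firmware divides it by a
shape-dependent deconvolution factor to report a pulse duration. For a
sech² pulse that factor is quoted as 1.54 throughout the field;
`intensity_acf()` + `acf_width()` reproduce it from first principles
(the numeric value is 1.5427, and the package's tests pin the computed
ratio to 1.543 ± 0.005 across pulse durations from 50 to 158 fs).
`deconvolve_duration()` uses 1.54 verbatim for sech², $\sqrt 2$ for
Gaussian, and 1 for square pulses.

The ACF does **not** determine the pulse: a distorted pulse with energy
in side lobes can be tuned to the same 154 fs autocorrelation width as
a clean 100 fs sech² pulse of equal energy, yet it predicts strictly
less fluorescence. `make_pulse_trace()` constructs exactly such pulses
(see below), and the package tests this non-uniqueness as a property —
it is the phenomenon that motivates measuring efficiency directly
rather than inferring it from specifications.

### The efficiency statistic

Real lasers deviate from the ideal law by a dimensionless factor,

$$F \propto \eta\,\frac{P_{av}^2}{R\,\tau_p},$$

estimated against a reference laser defined to have $\eta = 1$:

$$\eta = \frac{F_{test}}{F_{ideal}}
       = \frac{F_{test}\,R_{test}\,\tau_{p,test}}
              {F_{ref}\,R_{ref}\,\tau_{p,ref}} .$$

The pipeline in `eta_study()` proceeds in the order the measurement
protocol implies:

1. **Reference regression** — ordinary least squares of
   $\log_{10} F$ on $\log_{10} P$ for the reference laser
   (`reference_regression()`). Pure 2p excitation gives slope 2.
2. **Quadraticity guard** — every laser's own log–log slope must lie
   within 2 ± 0.1 (configurable `slope_tolerance`); datasets bent by
   fluorophore saturation or quenching are rejected rather than
   silently biased.
3. **Normalization** — every point from every laser is divided by the
   reference fit's prediction at the same power
   (`normalize_fluorescence()`), which brings the reference's own mean
   to 1 and makes points comparable across power levels. Points outside
   the reference's observed power range are extrapolated with a
   warning, not an error.
4. **Scaling** — each normalized point is multiplied by
   $(R_{test}\tau_{test})/(R_{ref}\tau_{ref})$ (`compute_eta()`). The
   pulse durations are the sech²-deconvolved instrument readings; since
   only the *ratio* of durations enters, the arbitrary sech² assumption
   cancels as long as it is applied consistently.
5. **Summary and comparison** — per-point $\eta$ values (one per power
   level per session, pooled) give the per-laser mean and SD; all
   pairs of lasers are compared with Welch two-sample tests under Holm
   step-down adjustment (`pairwise_compare()`), reported in an
   upper-triangular matrix. Welch/Holm is used deliberately in place of
   multiple-comparison procedures based on studentized
   maximum-modulus quantiles (e.g. Dunnett's T3): it is exact in the
   unequal-variance setting relevant here, available in closed form,
   and conservative under Holm adjustment; the choice is recorded in
   the report header written by `write_report()`.

The sampling unit for dispersion is the per-point $\eta$ (power levels
and sessions pooled). Sessions remain tracked by id so a per-session
breakdown is available by grouping `fit$points`, but the headline mean
and SD pool them.

### Image pipeline

The measured quantity $F$ is the peak pixel of a camera frame imaging
the excitation volume side-on in a fluorescent dye cell. Frames are
12-bit sensor data scaled into 16-bit containers: counts are multiples
of 16 with ceiling 65520, and saturation is tested against that
ceiling, not 65535. `normalize_image()`:

- estimates background as the mean of the outer border frame of the
  image (default: outer 10% on every side — the spot sits in the
  interior by construction of this geometry, and the fraction is
  configurable);
- subtracts it and divides by the exposure in milliseconds, so frames
  taken anywhere in the 600 ms – 5 s exposure range are directly
  comparable (tested to < 0.5% drift on noiseless scenes);
- flags any frame containing a saturated pixel for exclusion from
  intensity quantification.

`peak_intensity()` takes the brightest pixel (ties broken by row-major
first occurrence), and `profile_fwhm()` measures the lateral and axial
FWHM of the excitation volume along the raw single-pixel row and column
through that peak, with linear interpolation at the half-max crossings
— no smoothing and no 2-D fitting, so the estimator is exactly the
stated procedure. A Gaussian-fit estimator
(`profile_fwhm_gaussfit()`) is included purely as a cross-check. In the
side-view geometry the image row is the lateral (x) dimension and the
column is the axial (z) dimension.

On the dispersion of the profile FWHM estimator: first-order error
propagation (crossing jitter ≈ noise at half-max divided by the profile
slope there) gives a width SD of roughly 4% of the FWHM at a
peak signal-to-noise ratio of 20, independent of the width in pixels.
The estimator is unbiased (mean within 1% over repeated noise
realizations, which the tests verify), but per-frame widths at that
noise level should be read with ~5% error bars; averaging over the six
power levels is what makes the session-level FWHM values in a study
meaningful.

## The synthetic-data generator

No instrument data ships with the package; `synthetic-data.R` generates
every input with known ground truth, which is what the test suite and
the worked examples run on.

- **Pulse traces** (`make_pulse_trace()`, `composite_spec()`): clean
  sech², Gaussian, and square pulses, plus distorted pulses built as a
  main sech² lobe with two symmetric side lobes of adjustable energy
  fraction. Exact distorted-pulse waveforms from real lasers are not
  tabulated anywhere, so the composite family reproduces the
  *qualitative* property that matters — energy outside the central peak
  at a matched autocorrelation width — rather than any specific
  instrument trace. When a target ACF width is requested, all lobe
  delays and widths are scaled by a common multiplier found by
  bisection (tolerance 0.5%, geometric midpoint, bracket [0.05, 20]).
- **Spot images** (`make_spot_series()`): background offset + an
  anisotropic Gaussian spot whose peak rate scales as
  $\eta\,(P/P_{ref})^2$, times exposure, with Poisson shot noise on the
  signal, additive Gaussian read noise (default SD 2 counts — no camera
  noise model is published for this protocol, so the generator uses the
  minimal physically sensible one), then quantization to
  12-bit-in-16-bit counts. The default scene is 256 × 256 pixels with
  lateral FWHM 8 px and axial FWHM 24 px: an elongated ~3:1 spot of the
  kind a side-view image of a focused excitation volume shows. Frames
  that would saturate raise an error unless saturation is explicitly
  requested.
- **Studies** (`make_study()`, `make_measurement_table()`): multi-laser
  datasets at six power levels spanning 4–10 mW (the range over which
  the quadratic law holds without quenching in the underlying
  protocol). The ground-truth $\eta$ enters as a pure multiplicative
  factor; the study-level generator additionally applies the ideal
  scaling $(R_{ref}\tau_{ref})/(R\tau)$ per laser, so that the
  estimand of `eta_study()` is exactly the generator's `true_eta`.
  `make_study()` writes TIFF frames plus the manifest and
  laser-metadata CSVs consumed by the readers and the CLI.
  `make_measurement_table()` is the image-free equivalent for
  measurement-level work, with multiplicative noise of configurable CV
  (default 1%) and an optional saturation term for exercising the
  slope guard.

Each generator call uses a single global random stream, seeded
explicitly; identical specifications and seed give identical output.

**What passing tests do and do not show.** The generator emulates the
*statistical structure* of the protocol — quadratic power dependence,
multiplicative measurement noise, camera quantization, shot noise,
exposure variation — but not optical physics: the spot is a Gaussian
stand-in rather than a diffraction-limited 2p point-spread function,
there is no refraction or aberration modeling, no pulse-to-pulse
variability, and no fluorophore photophysics (saturation appears only
as a parametric distortion term). Recovery of ground-truth $\eta$ from
synthetic studies therefore validates the estimator chain, not the
instrument: it shows the pipeline is unbiased and correctly scaled
given data that obey the model, which is the strongest claim desk-scale
simulation can make.

## Numerical choices

- **Time grid**: uniform, centered on the main peak, default span 40 ×
  FWHM with 8192 samples. At that resolution trapezoidal integrals are
  converged far below all stated tolerances (doubling the sampling
  changes pulse energy by < 1e-6 relative), and a sech² pulse decays to
  < 1e-6 of its peak at the grid ends, so pulses are fully contained;
  generation rejects grids whose span is too small for the requested
  shape.
- **ACF evaluation**: `stats::convolve` (FFT) for the correlation
  sums, converted to exact trapezoidal weighting by subtracting half
  the overlap endpoint products at each lag, then mirrored onto
  negative lags — symmetric by construction, and equal to the direct
  O(N²) shift-multiply-trapezoid evaluation to better than 1e-9
  (tested against an independent oracle).
- **Half-max widths** everywhere (pulses, ACFs, image profiles) use
  linear interpolation between the bracketing samples on each side of
  the first/last crossing; flat or non-crossing profiles are an error,
  not a guess.
- **Degenerate inputs**: zero-energy traces cannot be normalized or
  autocorrelated (error); zero-variance groups make pairwise p-values
  undefined, so `eta_study()` leaves the pairwise table empty rather
  than failing the study; peak ties break row-major; peaks closer than
  5 pixels to an image edge refuse profile measurement.
- **Units**: SI internally (seconds, watts, joules, meters); file
  headers and manifests declare their units explicitly
  (`time_fs,power_au`; `power_mw`, `exposure_ms`, `pixel_size_um`) and
  are converted on read. No default pixel size exists — it depends on
  the detection optics and sensor pitch and must come with the data.

## Problem sizes in the test suite

The suite runs in well under a minute: pulse-level checks use 4096–8192
sample grids; oracle comparisons use 256-sample traces; image tests use
128 × 128 and 129 × 129 scenes (odd sizes place the spot center exactly
on a pixel, making noiseless quantization checks exact); estimator
recovery uses 20-seed batches of two-laser studies at six powers, and
the FWHM bias study uses 200 noise realizations. These sizes were
chosen as the smallest at which the tested tolerances are comfortably
resolved.

## Limitations

- Intensity-only: pulses are power-vs-time profiles. There is no
  complex field, spectral phase, chirp, or dispersion propagation, and
  FROG reconstruction itself is out of scope — the package consumes
  traces, it does not produce them.
- $\eta$ is an *empiric* catch-all: it absorbs every effect that
  degrades fluorescence relative to the ideal law (pulse shape,
  spurious pulses, power instability, polarization), and the package
  deliberately does not attempt to decompose it.
- Reported dispersions are over measurement points; instrument error in
  the repetition-rate and pulse-duration readings is not propagated
  into $\eta$.
- The interferometric (fringe-resolved) autocorrelation mode of real
  autocorrelators is not modeled; the computed ACF is the background-
  free intensity autocorrelation.
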