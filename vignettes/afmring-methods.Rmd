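---
title: "Methods: Ringing-mode adhesion extraction and surface-texture analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Ringing-mode adhesion extraction and surface-texture analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(afmring)
```

This vignette is the package's own account of the models it implements,
the free choices that were made where the underlying methodology leaves
them open, and what the synthetic system can and cannot show about real
measurements.

## 1. The force cycle and Ringing-mode extraction

Each pixel of a sub-resonance AFM image is one approach–retract cycle:
baseline (A), contact and loading to the maximum force (B–C), retract
through the adhesion well to the point of rapid detachment (D, the
adhesion force `F_adh`), and, after detachment, free damped oscillation of
the cantilever at its resonance (F). Modelling region F as a damped free
oscillator,

`F(t) = A exp(−(t − t_d)/τ) cos(2π f (t − t_d) + φ) + c`, with
`τ = Q / (π f₀)`,

and back-extrapolating to the detachment instant `t_d` yields the restored
adhesion `F_rest` (point E); the viscoelastic adhesion is the exact
identity `F_visc = F_adh − F_rest`, clamped at zero (with a counter) when
noise pushes the fitted `F_rest` slightly above `F_adh`.

Free choices, and how they were made:

* **Fit parametrisation.** The oscillator is fitted by trust-region least
  squares (`minpack.lm::nlsLM`) in the linear-in-quadrature form
  `e^{−Δ/τ}(p cos ωΔ + q sin ωΔ) + c`, initialised from the configured
  resonance and the log-envelope slope, with a linear least-squares warm
  start for `(p, q, c)`. This is standard ring-down practice and avoids
  phase-wrapping problems.
* **Detachment instant.** The detachment is located as the largest
  positive force step after the retract minimum, thresholded at five
  times the baseline step noise and restricted to a short window after
  the minimum (noisy ring upswings would otherwise masquerade as the
  step). When no step clears the threshold — e.g. when `F_adh − F_rest`
  is comparable to the noise — the minimum itself is used.
* **Back-extrapolation target.** At complete detachment the cantilever
  sits at a (negative) extremum of its free oscillation. The restored
  adhesion is therefore read off as the fitted envelope at the
  negative-extremum phase nearest the detected detachment, which makes
  the estimate insensitive to detachment-sample slop of up to half a
  period. The first ringing period is excluded from the fit for the same
  reason; with at least three periods required and the residual gate at
  20% of the fitted amplitude, fits outside this envelope are flagged
  unreliable and their pixels median-filled from 4-neighbours in map
  assembly.

The deliberately noise-sensitive single-sample retract minimum
(`adhesionMinimum`) is kept alongside: on synthetic cycles with 0.1 nN
noise its error is dominated by the extreme-value bias of picking one
minimum sample, and the multi-point oscillator fit beats it — this is the
quantitative motivation for Ringing-mode imaging and is asserted in the
test suite.

## 2. Cantilever calibration

* **Deflection sensitivity** (nm/V) comes from a rigid-substrate ramp:
  local slopes over a lag of one tenth of the record identify the contact
  segment (longest run within 10% of the median contact slope, widened by
  the slope-noise floor under noise), and the sensitivity is the inverted
  least-squares slope of signal on the noise-free z coordinate —
  regressing this way round avoids regression-dilution bias.
* **Spring constant** uses the thermal-noise route: Welch-averaged PSD
  (Hann window, segment length 2^13, 50% overlap — no installed R package
  provides a Welch estimator, so a small one is implemented here), an
  SHO-Lorentzian-plus-white-baseline fit in log space, and the
  equipartition closure `k = k_B T / ⟨z²⟩` with
  `⟨z²⟩ = A π Q f₀ / 2` (the closed form of the SHO integral). Whether
  the instrument's "thermal/Sader" calibration closes with equipartition
  or with the full hydrodynamic formula is not documented for this
  instrument class; equipartition is implemented, and the cantilever
  plan-view dimensions a hydrodynamic closure would need are not part of
  the configuration. The temperature default is 295 K.

On synthetic thermal records of 2^18–2^20 samples the recovered spring
constant is unbiased to well under 2% with RMSE under 5%; the residual
scatter is the physical record-length fluctuation of the thermal variance
(the effective number of independent samples is the record length over
the ring-down time), not estimator bias.

## 3. Surface maps, QC and the texture suite

Height maps are pre-normalised by removing the least-squares plane (the
height origin is arbitrary); adhesion channels are used as is, since
their absolute values are physical. The visual artifact screening of scan
images is replaced by automated proxies — largest adjacent-row-median
jump relative to the map RMS (scan-line artifacts), the fraction of
pixels beyond 6 MAD (spikes/debris), and the fraction of pixels at the
extreme recorded values (range clipping) — with documented default
thresholds (1.0, 0.01, 0.001). These proxies and thresholds are this
package's own operationalisation of a visual step.

The 37-parameter registry covers four families: nine amplitude parameters
(`Smean, Sa, Sq, Ssk, Sku, Sp, Sv, Sz, S10z`), nine spatial
(`Sal, Str20, Str37, Std, Stdi, Srw, Srwi, Shw, Sfd`), seven hybrid
(`Sdq, Sdq6, Sdr, Ssc, Sds, S2A, S3A`) and twelve functional
(bearing-curve) parameters (`Sbi, Sci, Svi, Sk, Spk, Svk, Smr1, Smr2,
Sdc0-5, Sdc5-10, Sdc10-50, Sdc50-95`). The exact identities behind a
commercial 37-parameter suite are not public; this registry is the
package's documented default, with each formula stated in the code, and
the count pinned at 37.

Spectrum conventions (all switchable where noted):

* The map mean is subtracted, no window is applied, and the 2D DFT
  modulus is quadrant-swapped so DC sits at the centre pixel.
* The **angular spectrum** defaults to interpolated line sampling: each
  of `M` equiangular half-plane lines is sampled bilinearly at integer
  radii with a finite angular acceptance of one line spacing (five
  sub-angles averaged), then smoothed with a circular 5-tap average.
  Nearest-pixel sector binning is retained (`method = "sector"`) — it
  conserves the total amplitude exactly and is what the brute-force
  oracle test exercises — but it is not the default because the number
  of lattice pixels per sector varies strongly with direction, which
  biases even an isotropic surface towards apparent directionality.
* The **radial spectrum** slot keeps the raw semicircle sums (bins by
  rounded integer radius, DC excluded, radii above `M/2 − 1` discarded),
  which conserve the binned half-plane amplitude. `Srwi` and the
  integral (cumulative) radial spectrum use the count-normalised profile
  — mean amplitude per semicircle — because raw sums grow roughly
  linearly with the pixel count per semicircle and would make even white
  noise look like it had a short dominant wavelength. With this
  convention white noise gives a flat profile (`Srwi` near 1) and
  `Shw = 2 δx`, the pixel scale, as it should.
* `r₀.₅` is found by linear interpolation of the cumulative profile
  through `(0, 0)`; `Shw = δx (M − 1) / (2 r₀.₅)`, so a pure sinusoid of
  wavelength λ yields λ/2 up to one radial bin of interpolation error.
  The printed formula this convention descends from is typographically
  ambiguous about the factor 2; the alternative without it is available
  as `halfFactor = FALSE`.
* `Sfd` (fractal dimension) is the clipped log–log slope of the mean
  amplitude per annulus over the fine-scale regime `r ∈ [M/8, M/2)`;
  self-affine scaling is an asymptotic fine-scale property, so the fit
  window deliberately excludes the long-wavelength structural band.
* `Sal`/`Str20`/`Str37` use the circular autocorrelation (via
  Wiener–Khinchin), sampled along 180 directions with bilinear
  interpolation; decay lengths are the interpolated first crossings below
  0.2 and 1/e, censored at `M/2 − 1`.

## 4. The synthetic generator

No public data exist for this system, so every stage is validated against
a generator with known ground truth.

**Force cycles** are piecewise linear in force (baseline, linear loading
to 2 nN, linear retract through the adhesion well) with an instantaneous
snap-off at D and a damped cosine of initial amplitude `F_rest` starting
at the detachment instant — the phase convention that makes the
back-extrapolation model exact. Defaults: `k = 0.4` N/m, `f₀ = 75` kHz
(the probe class used for this kind of imaging), `Q = 25`,
`f_s = 2` MHz, contact stiffness 0.01 N/m, retract speed 3·10⁵ nm/s —
chosen so a full cycle lasts ~2 ms with a well-resolved ring-down.
**Thermal records** are synthesised in the frequency domain (complex
Gaussian amplitudes shaped by the SHO response, scaled so the expected
variance satisfies equipartition exactly on the discrete grid), so sample
variance fluctuates as a physical record would.

**Surface maps** follow a two-component mixture controlled by the latent
activation level `a ∈ [0, 1]`:

```
field = (1 − a) · 0.44 · fold + a · grain (+ white pixel noise),
```

rescaled to an exact target RMS before the plane tilt is added, so
amplitude parameters carry no activation information by construction and
only the spatial organisation changes.

* The **fold field** (resting membrane) is a Gaussian random field whose
  spectrum is a narrow oriented ring at the fold wavelength (36% of the
  fold power; the quasi-periodic, direction-selective part) plus an
  isotropic annular skirt at the same wavelength (fold segments of all
  orientations). Its intrinsic amplitude is kept below the granular
  relief (factor 0.44 at equal mixture weight): folds are a subtle
  large-scale modulation of the effective height, visible to
  amplitude-spectrum statistics long after their share of the total
  power is negligible.
* The **grain field** (activated membrane) is a shot-noise field of
  symmetric Gaussian bumps (radius 55 nm, density
  `120 · (0.2 + 0.8 a)` per µm², Poisson counts) mixed with a Gaussian
  random field of identical spectrum (bump variance share 0.4) so the
  height distribution stays near-Gaussian at every level, and with a
  structure-factor-like low-frequency suppression (granules are solid
  bodies with a minimum spacing, so long-wavelength clustering is
  suppressed). Bumps and pits both occur; this keeps skewness flat
  across levels.
* The fold wavelength default (420 nm) sets the fold autocorrelation
  zero at the granular field's 0.2-crossing radius, so the
  autocorrelation length `Sal` is insensitive to the fold's rise and
  fall; the noise floor (0.25 of the structural RMS, ~6% of the power)
  dominates the gradient- and summit-based parameters.

The activation time course is `a(t) = 1 − exp(−t/τ)` with `τ = 10` min,
so the level reaches 95% of its plateau by 30 min; the series has two
control groups at level 0 (before activation, and after 120 min without
stimulus) plus one group per activation time (5, 10, 30, 60, 120 min),
20 cells each. Height-channel structure is held time-invariant (with a
random plane tilt); the adhesion channels carry the activation response,
the viscoelastic one with a smaller amplitude and more noise. Cell-to-cell
variability magnitudes are not reported anywhere for this system and are
**invented defaults**: log-normal spreads of 5% on the fold wavelength,
2% on the grain radius, 10% on the target RMS, 5% on the noise level, a
clamped Gaussian spread of 0.10 on the fold anisotropy, a random fold
direction per cell, and a 0.02 spread on the realised level.

All randomness flows from one integer seed per call; per-cell and
per-channel seeds are derived deterministically from it.

### What the generator does and does not emulate

It reproduces the qualitative phenomenology the analysis targets:
granularity increasing with activation, the dominant direction and
wavelength washing out, RMS amplitude carrying no signal, saturation
within ~30 min, stable controls. It does **not** emulate tip convolution,
nonlinear contact mechanics, scanner drift or line artifacts (those are
injected explicitly in QC tests), spatial correlation between channels
beyond shared per-cell parameters, or any biology of the granules'
identity. Passing tests on this system therefore validates the
*computational chain*, not instrument-specific behaviour on real cells.

## 5. The activation screen and estimator

Trends are screened by Spearman rank correlation of per-cell parameter
values against activation time over the activated groups only, with
Benjamini–Hochberg adjustment across all parameter × channel tests; a
parameter is selected when the adjusted p-value is below 0.05, |ρ| ≥ 0.5,
and the two control groups agree (two-sided Mann–Whitney p ≥ 0.05 and
absolute standardised difference < 0.5). How the original analysis
decided that parameters "correlate" is not documented (most likely visual
inspection of group plots); this gate stack is the package's documented
operationalisation.

A structural property of this design is worth stating plainly. With the
saturating level curve, the activated groups sit at levels 0.39, 0.63,
0.95, 0.998 and 1.0: all structural change is concentrated between the
first two or three groups, which caps the attainable rank correlation of
*any* saturating response near the tied-groups ceiling (≈0.5–0.78
depending on how many groups separate cleanly). The generator was
deliberately designed (fold amplitude, ring/skirt split, matched
autocorrelation scales, noise floor, per-cell spreads) to push the
spatial trio to the top of that range while holding the other 34
parameters below the gate; `Str20`/`Str37`, which measure the same
anisotropy washout as `Stdi` through the autocorrelation function, are
the closest competitors, and their population correlations sit near the
0.5 gate. Exact-trio selection at the default study size is therefore the
expected but not a guaranteed outcome of every seed, and the test suite
asserts it at a fixed documented seed. The direction of effect
(`Shw` down, `Srwi`/`Stdi` up from control to full activation), the
saturation property, and the permutation-null behaviour of the screen are
robust across seeds.

The activation-level estimator uses isotonic regressions of `Srwi`
(increasing) and `Shw` (decreasing) against the latent level, inverted by
interpolation and combined by inverse-variance weights from 200 bootstrap
replicates (resampling cells within groups); queries outside the
calibrated range are clamped and flagged. `Stdi` is excluded from the
estimator: its time course is not monotone at late times, so it cannot be
inverted, though it remains in the screen. On held-out synthetic cells
the mean absolute level error is well under 0.15. Levels translate to
exposure minutes through the same saturating curve.

## 6. Problem sizes and tolerances used in the tests

The test suite runs the full default study (7 groups × 20 cells × 3
channels of 256 × 256 maps) once and caches it; property sweeps use
128 × 128 or 64 × 64 maps, 1000 seeds for the boundedness battery, 100
noisy cycles for the estimator comparison, 25 seeds for calibration bias,
and 2^18–2^20-sample thermal records. Numerical tolerances follow the
precision of each construction: exact identities at 1e-9–1e-12, Monte
Carlo quantities at 2–10%, and the half-wavelength example at one radial
bin of interpolation error.

## 7. Known limitations

* The registry's parameter identities are a documented default, not a
  bit-exact replica of any commercial implementation.
* GSF I/O stores float32, so round trips are exact only to single
  precision; CSV round trips are exact.
* The deformation and height channels of grid assembly are pass-throughs
  of generator ground truth: recovering them from data requires the
  z-trajectory, which the trace container does not carry.
* The screen's exact-trio selection sits near its statistical ceiling by
  construction of the saturating design (see Section 5).
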