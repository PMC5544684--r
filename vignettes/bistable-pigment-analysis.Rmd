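---
title: "Spectral analysis of bistable visual pigments with opsinspec"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral analysis of bistable visual pigments with opsinspec}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>",
                      fig.width = 6, fig.height = 4)
library(opsinspec)
```

## The measurement problem

A bistable visual pigment interconverts between two thermally stable
states: a dark state carrying an 11-cis retinal chromophore and a
metarhodopsin state carrying all-trans retinal. Light drives both
directions, so irradiation never produces a pure state — it produces a
*photosteady* mixture in which forward and reverse photoconversion rates
balance. For a UV-absorbing pigment the problem is worse: both states
absorb in the UV, so their bands overlap and neither state's spectrum
can be read off a measurement directly.

The package implements the classical workaround. At wavelengths well
beyond the dark state's band only the metarhodopsin absorbs, so the
long-wavelength flank of a photoconversion *difference spectrum* is a
scaled copy of the metarhodopsin spectrum alone. Fitting a pigment
template there pins down the metarhodopsin's peak wavelength
(`lambda_max`) and amplitude; adding the signed difference spectrum back
then reconstructs the dark-state spectrum that was never observed in
isolation.

## Pigment templates

Visual pigment absorbance spectra share a common shape when wavelength
is expressed relative to `lambda_max`. `template_spectrum()` implements
the standard A1 alpha-band closed form

$$S(x) = \frac{1}{e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D},
\qquad x = \lambda_{\max}/\lambda,$$

with $A = 69.7$, $b = 0.922$, $c = 1.104$, $D = 0.674$ and the
`lambda_max`-dependent bandwidth term
$a = 0.8795 + 0.0459\,e^{-(\lambda_{\max}-300)^2/11940}$. Three families
differ only in the flank constants $B$ and $C$:

| family               | B    | C     | typical use                      |
|----------------------|------|-------|----------------------------------|
| `a1_pigment`         | 28.0 | -14.9 | dark states (11-cis, A1 retinal) |
| `metarhodopsin_like` | 25.2 | -13.4 | all-trans photoproducts          |
| `retinochrome_like`  | 26.6 | -14.2 | retinochrome-shaped states       |

Every template is normalized so the absorbance at `lambda_max` is
exactly 1.0. A UV beta band (a Gaussian satellite) can be switched on
with `include_beta_band = TRUE`; it is off by default because the
analysis fits the alpha band.

```{r templates}
g <- default_grid()   # 250-700 nm, 1 nm
plot(template_spectrum(360, g), main = "Template spectra")
lines(g, template_spectrum(415, g)$absorbance, col = 2)
lines(g, template_spectrum(510, g, family = "metarhodopsin_like")$absorbance,
      col = 4)
legend("topright", c("T(360)", "T(415)", "T(510, meta)"),
       col = c(1, 2, 4), lty = 1, bty = "n")
```

## Sign conventions

Difference spectra are the dominant source of sign bugs, so the package
makes the direction explicit. `difference(after, before)` computes
`after - before` and tags the result; `flip_convention()` negates it and
updates the tag. The internal canonical form for reconstruction is
*(original − irradiated)*: `reconstruct_original()` then uses the exact
identity

```
original = irradiated + (original - irradiated)
```

which holds at machine precision, so reconstruction is perfect whenever
the irradiated-state estimate is.

`fit_irradiated_state()` expects the irradiated state as the *positive*
lobe inside the fit window, which is why
`reconstruct_bistable_pair()` fits the flipped back-conversion
difference.

## The fit window

The template is fitted only where the original state no longer absorbs.
With `window = NULL` the automatic red-flank rule is used:

* lower bound — wavelength of the positive-lobe maximum plus 10 nm;
* upper bound — the last grid point where `|diff|` exceeds three times
  the estimated noise level (estimated from first differences of the
  trace), falling back to the end of the grid when that leaves fewer
  than ten points.

A constant baseline offset is co-fitted by default, because real
difference measurements carry unsteady baselines. `lambda_max` is found
by a 1 nm grid search over 380–650 nm followed by parabolic refinement
of the residual sum of squares; ties break toward the lower
`lambda_max`, so results are deterministic.

## A complete worked cycle

The package ships a synthetic fixture, `rh7_pigment_pair()`, emulating a
UV-absorbing bistable pigment with a composite dark band: the dark state
is `0.65*T(360) + 0.35*T(415)` and the metarhodopsin is a 510 nm
metarhodopsin-like template whose amplitude is solved numerically so the
visible:UV difference-amplitude ratio is exactly 8. These numbers are
package-chosen fixture parameters, not measurements. Alpha-band-only
templates are used so that template fits close the simulation →
analysis loop exactly at zero noise.

```{r cycle}
pp <- rh7_pigment_pair()
meas <- run_protocol(pp, uv_yellow_protocol(1),
                     noise = noise_model(sigma_additive = 0.002,
                                         baseline_drift_slope = 0.001,
                                         seed = 1))
rec <- reconstruct_bistable_pair(meas[[1]]$spectrum,  # dark
                                 meas[[2]]$spectrum,  # after UV
                                 meas[[3]]$spectrum)  # after yellow
rec
plot(rec)
```

The default noise condition used throughout the documentation and tests
is additive Gaussian noise of 0.002 AU with a baseline drift scale of
0.001 AU per 100 nm. At that level the metarhodopsin `lambda_max` is
recovered within 2 nm in over 95% of seeded replicates, with bias well
under 1 nm.

## Composite decomposition and model selection

Broad or shouldered dark-state bands are decomposed into one or two
templates with nonnegative weights by exhaustive search over peak
wavelengths (330–500 nm, 1 nm grid, minimum separation 15 nm), with the
weights solved in closed form at every grid node:

```{r composite}
fit <- fit_composite(rec$original_spectrum, n_components = 2)
fit
```

`select_n_components()` compares the one- and two-component fits by BIC
computed from Gaussian residuals. BIC rather than an AIC-type penalty is
a deliberate choice: the exhaustive search over thousands of candidate
peak-wavelength pairs almost always finds a pair that improves the fit
by more than the nominal two-parameter cost, so small-sample AIC
over-selects two components on single-template inputs; the `log(n)`
penalty absorbs that search optimism. Ties — including the noise-free
case where both models fit exactly — resolve to the simpler model.

## Photosteady-state simulation

`photosteady_fraction()` computes the metarhodopsin fraction at which
forward and reverse rates balance,
$f = k_{\mathrm{fwd}}/(k_{\mathrm{fwd}}+k_{\mathrm{rev}})$ with each
rate the source-weighted sum of state absorbance times quantum yield.
Finite-duration steps use the closed-form exponential relaxation of the
two-state kinetic equation. The simulator assumes an optically thin
sample (rate proportional to absorbance, no inner-filter effect) and no
thermal decay between states — both documented limitations. The standard
filter set (`standard_filters()`) encodes ideal top-hat bands: UV
330–390 nm, blue 440–460 nm, and >500 / >550 / >575 nm longpass cuts.

## Retinal isomer chromatograms

`simulate_chromatogram()` renders a known isomer composition as a
sum-of-Gaussians retinaloxime trace (six species: syn and anti oximes of
11-cis, 13-cis and all-trans retinal, with a configurable 70/30
syn/anti split). `detect_and_integrate_peaks()` detects peaks on a
rolling-minimum baseline-corrected, lightly smoothed copy of the trace,
then co-fits all detected peaks on the *raw* trace as Gaussians plus a
constant offset — baseline subtraction is used for detection only, since
subtracting a rolling minimum through a peak distorts its area. Areas
are analytic (`amplitude * width * sqrt(2*pi)`), and
`compose_fractions()` maps peaks to species by retention time and
normalizes to fractions:

```{r hplc}
truth <- c("11-cis" = 0.85, "13-cis" = 0.05, "all-trans" = 0.10)
trace <- simulate_chromatogram(truth, noise_sd = 0.01, seed = 2)
compose_fractions(detect_and_integrate_peaks(trace, min_prominence = 0.05))
```

## G-protein activation rates

`fit_initial_rate()` estimates the initial slope of a nucleotide-binding
time course (default: linear fit with intercept over the first five
points; an exponential-saturation model with a delta-method standard
error is available). `summarize_conditions()` aggregates replicates per
irradiation condition and reports fold changes against the required
`"dark"` reference:

```{r gprotein}
tc <- simulate_timecourses(c(dark = 0.1, uv = 1.0, yellow = 0.3), seed = 3)
summarize_conditions(tc)
```

## The end-to-end demonstration

`run_demo_pipeline()` chains every stage on the fixture — simulate the
UV/yellow protocol, reconstruct both states, decompose the dark band,
analyze matched chromatograms, summarize activation rates — and reports
recovered against true parameters. All randomness flows from one seed;
`write_demo_report()` emits timestamp-free files so reruns are
byte-identical.

```{r demo}
run_demo_pipeline(seed = 1)
```

All stages run in seconds on one CPU: the spectral grid is 451 points,
the composite search examines ~12,000 wavelength pairs in vectorized
closed form, and the chromatogram grid is 776 points.

## Limitations

* Two states only: no photocascade intermediates and no time-resolved
  spectroscopy.
* At most two composite components; closely spaced components
  (separation under ~15 nm) are not identifiable at realistic noise and
  are excluded from the search by design.
* Thin-sample optics; no inner-filter correction.
* Equal molar extinction across oxime species by default (a correction
  hook is provided).
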