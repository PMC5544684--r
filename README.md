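# opsinspec

Spectral analysis of bistable visual pigments in R: template (nomogram)
curves, difference-spectrum reconstruction of photopigment states,
composite band decomposition, photosteady-state irradiation simulation,
retinal-isomer HPLC quantification, and G-protein activation kinetics.

## The science

Bistable visual pigments have two thermally stable, light-interconvertible
states: a dark state (11-cis retinal chromophore) and a metarhodopsin
(all-trans). Because light drives both directions, irradiation yields a
*photosteady* mixture, never a pure state — and for UV-absorbing pigments
the two states' bands overlap in the UV, so neither spectrum can be
measured directly.

The classical solution, implemented here, works from difference spectra:

1. **Fit the red flank.** At wavelengths beyond the dark state's band,
   only the metarhodopsin absorbs, so the long-wavelength flank of a
   photoconversion difference spectrum is a scaled copy of the
   metarhodopsin spectrum. Fitting a pigment template there
   (`fit_irradiated_state()`) gives its peak wavelength and amplitude.
2. **Reconstruct additively.** `original = irradiated + (original − irradiated)`
   is an exact identity, so `reconstruct_original()` recovers the
   dark-state spectrum that was never observed in isolation.
3. **Decompose composite bands.** Broad or shouldered dark bands are
   decomposed into one or two templates with nonnegative weights
   (`fit_composite()`), with BIC-based selection between the two model
   sizes (`select_n_components()`).

A forward simulator (`run_protocol()`, `photosteady_fraction()`)
generates synthetic measurements under UV/longpass irradiation
protocols, which closes the loop: every estimator in the package is
validated against data whose ground truth is known. Companion modules
quantify retinal isomer composition from retinaloxime chromatograms and
estimate G-protein activation rates from nucleotide-exchange time
courses.

## Worked example

Simulate one UV/yellow irradiation cycle of the bundled synthetic
Rh7-like fixture (dark band `0.65·T(360) + 0.35·T(415)`, metarhodopsin at
510 nm with a visible:UV difference-amplitude ratio of 8) and analyze
the three resulting spectra:

```r
library(opsinspec)

pp <- rh7_pigment_pair()
meas <- run_protocol(pp, uv_yellow_protocol(1),
                     noise = noise_model(sigma_additive = 0.002,
                                         baseline_drift_slope = 0.001,
                                         seed = 1))
rec <- reconstruct_bistable_pair(meas[[1]]$spectrum,   # dark
                                 meas[[2]]$spectrum,   # after UV
                                 meas[[3]]$spectrum)   # after yellow
rec
#> Bistable-pair reconstruction
#>   irradiated state: lambda_max 510.01 nm, amplitude 4.679 AU (metarhodopsin_like)
#>   original state:   apparent peak 367 nm, 0.6721 AU
#>   fit rmse 0.00305 AU in [519, 625] nm; baseline -0.00253 AU
#>   photoregeneration residual (rms): 0.0034 AU

fit_composite(rec$original_spectrum, n_components = 2)
#> Composite template fit (2 components, a1_pigment)
#>   lambda_max 360 nm, weight 0.5486 AU
#>   lambda_max 415 nm, weight 0.2964 AU
#>   rmse 0.00336 AU; BIC -5106.01
```

The recovered 510 nm peak matches the fixture's truth, and the composite
weights match the dark weights scaled by the cycle's conversion
completeness (0.848 × {0.65, 0.35} = {0.551, 0.297}).

The full closed loop — simulation, reconstruction, decomposition,
chromatogram analysis, activation kinetics — runs in a few seconds:

```r
run_demo_pipeline(seed = 1)
#> Demonstration pipeline report (seed 1)
#>           stage                   parameter     true recovered
#>        photosim      fraction_meta_after_uv       NA 8.480e-01
#>        photosim  fraction_meta_after_yellow       NA 9.879e-05
#>        photosim      vis_uv_amplitude_ratio   8.0000 7.958e+00
#>  reconstruction          meta_lambda_max_nm 510.0000 5.100e+02
#>  reconstruction           meta_amplitude_AU   4.6780 4.679e+00
#>  reconstruction       dark_apparent_peak_nm 366.0000 3.670e+02
#>       composite    component1_lambda_max_nm 360.0000 3.600e+02
#>       composite    component2_lambda_max_nm 415.0000 4.150e+02
#>       composite        component1_weight_AU   0.5512 5.486e-01
#>       composite        component2_weight_AU   0.2968 2.964e-01
#>       composite       selected_n_components   2.0000 2.000e+00
#>            hplc      max_abs_fraction_error   0.0000 6.079e-03
#>            hplc cis_decrease_trans_increase   1.0000 1.000e+00
#>        gprotein      uv_fold_change_vs_dark  10.0000 9.913e+00
#>        gprotein     ordering_uv_yellow_dark   1.0000 1.000e+00
```

`write_demo_report(report, outdir)` writes all spectra and a
timestamp-free report, so reruns with the same seed are byte-identical.

See the vignette (`vignettes/bistable-pigment-analysis.Rmd`) for the
template closed form, sign conventions, the automatic fit-window rule,
and the rationale behind the BIC model selection.

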