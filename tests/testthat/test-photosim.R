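test_that("photosteady fraction: symmetry and one-way limits", {
  g <- default_grid()
  t350 <- template_spectrum(350, g)
  # identical spectra, equal yields -> 0.5
  pp_same <- pigment_pair(t350, t350)
  expect_equal(photosteady_fraction(pp_same, standard_filters()$uv), 0.5)

  # source confined to where meta absorbance is exactly zero -> complete
  # conversion (templates never reach exact zero, so use explicit bands)
  dark_band <- new_spectrum(g, exp(-((g - 350) / 25)^2) * (g < 450))
  meta_band <- new_spectrum(g, exp(-((g - 510) / 30)^2) * (g > 450))
  pp <- pigment_pair(dark_band, meta_band)
  uv_only <- light_source("band", lower = 320, upper = 380)
  expect_equal(photosteady_fraction(pp, uv_only), 1.0)

  # neither state absorbs -> error (both templates ~0 beyond 700 is not
  # representable on this grid, so use zero spectra instead)
  z <- new_spectrum(g, rep(0, length(g)))
  expect_error(photosteady_fraction(pigment_pair(z, z), uv_only),
               "no photochemistry")
})

test_that("photosteady fraction matches brute-force ODE integration", {
  g <- default_grid()
  t350 <- template_spectrum(350, g)
  t510 <- template_spectrum(510, g, family = "metarhodopsin_like")
  pp <- pigment_pair(t350, t510)
  lp550 <- standard_filters()$longpass550
  expect_equal(photosteady_fraction(pp, lp550),
               oracle_steady_state_ode(pp, lp550), tolerance = 1e-6)

  # ten randomized pigment/source combinations
  set.seed(99)
  for (i in 1:10) {
    l_dark <- runif(1, 330, 420)
    l_meta <- runif(1, 460, 560)
    ppi <- pigment_pair(template_spectrum(l_dark, g) * runif(1, 0.5, 2),
                        template_spectrum(l_meta, g,
                                          family = "metarhodopsin_like") *
                          runif(1, 0.5, 2),
                        phi_forward = runif(1, 0.2, 1),
                        phi_reverse = runif(1, 0.2, 1))
    lo <- runif(1, 320, 500)
    src <- light_source("band", lower = lo, upper = lo + runif(1, 20, 150),
                        relative_intensity = runif(1, 0.5, 2))
    expect_equal(photosteady_fraction(ppi, src),
                 oracle_steady_state_ode(ppi, src, f0 = runif(1)),
                 tolerance = 1e-6)
  }
})

test_that("steady state forgets the initial condition", {
  pp <- rh7_pigment_pair()
  quiet <- noise_model(0, 0, seed = 5)
  step1 <- uv_yellow_protocol(1)[1]
  from0 <- run_protocol(pp, step1, initial_fraction_meta = 0, noise = quiet)
  from1 <- run_protocol(pp, step1, initial_fraction_meta = 1, noise = quiet)
  expect_lt(abs(from0[[2]]$fraction_meta - from1[[2]]$fraction_meta), 1e-9)
  # idempotence: repeating the same step leaves the fraction unchanged
  twice <- run_protocol(pp, rep(step1, 2), noise = quiet)
  expect_lt(abs(twice[[3]]$fraction_meta - twice[[2]]$fraction_meta), 1e-12)
})

test_that("mixture spectrum endpoints, convexity and isosbestic point", {
  pp <- rh7_pigment_pair()
  expect_equal(mixture_spectrum(pp, 0)$absorbance, pp$dark$absorbance)
  expect_equal(mixture_spectrum(pp, 1)$absorbance, pp$meta$absorbance)
  expect_error(mixture_spectrum(pp, 1.2), "\\[0, 1\\]")

  # all mixtures agree where the state spectra cross
  d <- pp$dark$absorbance - pp$meta$absorbance
  cross <- which(diff(sign(d)) != 0)[1]
  # interpolate the crossing wavelength and evaluate mixtures there
  wl <- pp$dark$wavelength
  x0 <- wl[cross] - d[cross] * (wl[cross + 1] - wl[cross]) /
    (d[cross + 1] - d[cross])
  vals <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    resample(mixture_spectrum(pp, f), c(x0, x0 + 1))$absorbance[1]
  }, numeric(1))
  expect_lt(max(vals) - min(vals), 1e-9)
})

test_that("repeated cycles are photoreversible at zero noise", {
  pp <- rh7_pigment_pair()
  quiet <- noise_model(0, 0, seed = 1)
  meas <- run_protocol(pp, uv_yellow_protocol(2), noise = quiet)
  # steps 1 and 3 (after UV), steps 2 and 4 (after yellow) identical
  expect_identical(meas[[2]]$spectrum$absorbance, meas[[4]]$spectrum$absorbance)
  expect_identical(meas[[3]]$spectrum$absorbance, meas[[5]]$spectrum$absorbance)
})

test_that("same seed gives bit-identical noisy outputs", {
  pp <- rh7_pigment_pair()
  nm <- noise_model(0.002, 0.001, seed = 42)
  a <- run_protocol(pp, uv_yellow_protocol(1), noise = nm)
  b <- run_protocol(pp, uv_yellow_protocol(1), noise = nm)
  expect_identical(a, b)
  c2 <- run_protocol(pp, uv_yellow_protocol(1), noise = noise_model(0.002, 0.001, 43))
  expect_false(identical(a[[1]]$spectrum$absorbance, c2[[1]]$spectrum$absorbance))
})

test_that("with_seed restores the RNG state of the caller", {
  set.seed(1)
  x1 <- runif(1)
  set.seed(1)
  invisible(with_seed(999, runif(5)))
  expect_identical(runif(1), x1)
})

test_that("UV-then-longpass difference has exactly one sign change", {
  g <- default_grid()
  # unimodal, essentially non-overlapping state bands
  pp <- pigment_pair(template_spectrum(350, g),
                     template_spectrum(550, g, family = "metarhodopsin_like"))
  quiet <- noise_model(0, 0, seed = 1)
  meas <- run_protocol(pp, uv_yellow_protocol(1), noise = quiet)
  d <- difference(meas[[2]]$spectrum, meas[[1]]$spectrum)$absorbance
  s <- sign(d[abs(d) > 1e-9])
  expect_equal(sum(diff(s) != 0), 1)
})

test_that("finite-duration steps relax exponentially toward steady state", {
  pp <- rh7_pigment_pair()
  uv <- standard_filters()$uv
  quiet <- noise_model(0, 0, seed = 1)
  f_ss <- photosteady_fraction(pp, uv)
  k <- sum(source_weights(uv, pp$dark$wavelength) * pp$dark$absorbance) +
    sum(source_weights(uv, pp$dark$wavelength) * pp$meta$absorbance)
  tshort <- 0.01 / k  # well before steady state
  meas <- run_protocol(pp, list(protocol_step(uv, duration = tshort)),
                       noise = quiet)
  f_expect <- f_ss * (1 - exp(-k * tshort))
  expect_equal(meas[[2]]$fraction_meta, f_expect, tolerance = 1e-10)
  expect_lt(meas[[2]]$fraction_meta, f_ss)
})

test_that("closing the loop: simulate then reconstruct at zero noise", {
  pp <- rh7_pigment_pair()
  quiet <- noise_model(0, 0, seed = 1)
  meas <- run_protocol(pp, uv_yellow_protocol(1), noise = quiet)
  rec <- reconstruct_bistable_pair(meas[[1]]$spectrum, meas[[2]]$spectrum,
                                   meas[[3]]$spectrum)
  conv <- meas[[2]]$fraction_meta - meas[[3]]$fraction_meta
  true_amp <- conv * pp$truth$meta_amplitude
  expect_lte(abs(rec$fit$lambda_max - pp$truth$meta_lambda_max), 1)
  expect_lte(abs(rec$fit$amplitude - true_amp) / true_amp, 0.005)
})

test_that("rh7 fixture hits the requested difference-amplitude ratio", {
  pp <- rh7_pigment_pair()
  d <- pp$meta$absorbance - pp$dark$absorbance
  expect_equal(max(d) / abs(min(d)), 8, tolerance = 1e-6)
  pp12 <- rh7_pigment_pair(ratio = 12)
  d12 <- pp12$meta$absorbance - pp12$dark$absorbance
  expect_equal(max(d12) / abs(min(d12)), 12, tolerance = 1e-6)
})

test_that("light source and pigment pair validation", {
  expect_error(light_source("band", lower = 500, upper = 400), "lower")
  g <- default_grid()
  t1 <- template_spectrum(350, g)
  expect_error(pigment_pair(t1, template_spectrum(510, 300:700)),
               "share a grid|grid")
  expect_error(pigment_pair(t1, t1, phi_forward = 0), "quantum yield")
  f <- standard_filters()
  expect_setequal(names(f),
                  c("uv", "blue450", "longpass500", "longpass550", "longpass575"))
  off_grid <- light_source("monochromatic", wavelength = 900)
  expect_error(source_weights(off_grid, g), "overlap")
})
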