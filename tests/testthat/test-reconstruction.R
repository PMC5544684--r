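# A noise-free difference spectrum with a known metarhodopsin component:
# diff = 1.0 * T(510, meta) - 0.8 * T(350, a1), signed (irradiated - original)
# so the irradiated state is the positive lobe.
make_known_diff <- function(amp_meta = 1.0, amp_dark = 0.8, grid = default_grid()) {
  m <- template_spectrum(510, grid, family = "metarhodopsin_like") * amp_meta
  d <- template_spectrum(350, grid) * amp_dark
  difference(m, d)
}

test_that("noise-free fit recovers lambda_max and amplitude exactly", {
  diffsp <- make_known_diff()
  fit <- fit_irradiated_state(diffsp, window = c(480, 650))
  expect_lte(abs(fit$lambda_max - 510), 1)
  expect_lt(abs(fit$amplitude - 1.0), 0.01)
  expect_lt(abs(fit$baseline), 1e-6)
  expect_lt(fit$rmse, 1e-6)
})

test_that("fit matches the exhaustive 2-D grid-search oracle", {
  set.seed(7)
  for (i in 1:5) {
    lm_true <- sample(460:560, 1)
    amp_true <- round(runif(1, 0.3, 1.8), 3)
    g <- default_grid()
    diffsp <- difference(
      template_spectrum(lm_true, g, family = "metarhodopsin_like") * amp_true,
      template_spectrum(350, g) * 0.5)
    win <- c(lm_true - 20, 650)
    fit <- fit_irradiated_state(diffsp, window = win, baseline = FALSE,
                                refine = FALSE)
    orc <- oracle_fit_grid_search(diffsp, win)
    expect_equal(unname(fit$lambda_max), unname(orc["lambda_max"]))
    # oracle amplitude grid step is 0.005; the closed form is continuous
    expect_lt(abs(fit$amplitude - orc["amplitude"]), 0.005)
  }
})

test_that("amplitude linearity: scaling the input scales the fit", {
  diffsp <- make_known_diff()
  f1 <- fit_irradiated_state(diffsp, window = c(480, 650))
  f2 <- fit_irradiated_state(diffsp * 0.37, window = c(480, 650))
  expect_equal(f2$amplitude, 0.37 * f1$amplitude, tolerance = 1e-8)
  expect_lt(abs(f2$lambda_max - f1$lambda_max), 1e-6)
})

test_that("degenerate and malformed inputs raise the documented errors", {
  g <- 400:650
  zero <- difference(new_spectrum(g, rep(0, length(g))),
                     new_spectrum(g, rep(0, length(g))))
  expect_error(fit_irradiated_state(zero), "no signal")
  neg <- difference(new_spectrum(g, rep(0, length(g))),
                    new_spectrum(g, exp(-((g - 500) / 30)^2)))
  expect_error(fit_irradiated_state(neg, window = c(480, 650)), "no signal")
  d <- make_known_diff()
  expect_error(fit_irradiated_state(d, window = c(480, 485)),
               "fewer than 10 grid points")
  expect_error(fit_irradiated_state(d, window = c(650, 480)), "lower < upper")
})

test_that("auto red-flank window excludes the dark-state band", {
  diffsp <- make_known_diff()
  win <- auto_red_flank_window(diffsp)
  # positive lobe peaks near 510; lower bound = peak + 10
  expect_equal(unname(win["lower"]),
               diffsp$wavelength[which.max(diffsp$absorbance)] + 10)
  expect_gt(unname(win["upper"]), unname(win["lower"]) + 10)
  fit <- fit_irradiated_state(diffsp)  # window = NULL -> auto
  expect_lte(abs(fit$lambda_max - 510), 1)
})

test_that("monte-carlo recovery at sigma = 0.002 AU", {
  base <- make_known_diff()
  g <- base$wavelength
  hits <- 0L
  errs <- numeric(200)
  with_seed(2024, {
    for (r in 1:200) {
      noisy <- new_spectrum(g, base$absorbance + stats::rnorm(length(g), sd = 0.002))
      noisy <- difference(noisy, new_spectrum(g, rep(0, length(g))))
      fit <- fit_irradiated_state(noisy, window = c(480, 650))
      errs[r] <- fit$lambda_max - 510
      if (abs(errs[r]) <= 2) hits <- hits + 1L
    }
  })
  expect_gte(hits / 200, 0.95)
  expect_lt(abs(mean(errs)), 1)  # bias of lambda_max under 1 nm
})

test_that("reconstruct_original is an exact algebraic identity", {
  g <- default_grid()
  dark <- template_spectrum(350, g) * 0.8
  meta <- template_spectrum(510, g, family = "metarhodopsin_like")
  d <- difference(dark, meta)  # original - irradiated
  orig <- reconstruct_original(d, meta)
  expect_lt(max(abs(orig$absorbance - dark$absorbance)), 1e-12)

  zero <- difference(meta, meta)
  same <- reconstruct_original(zero, meta)
  expect_equal(same$absorbance, meta$absorbance)

  # flipped sign convention is honored
  orig2 <- reconstruct_original(flip_convention(d), meta,
                                diff_sign = "irradiated_minus_original")
  expect_lt(max(abs(orig2$absorbance - dark$absorbance)), 1e-12)

  narrow <- template_spectrum(510, 450:600, family = "metarhodopsin_like")
  expect_error(reconstruct_original(d, narrow), "does not cover")
})

test_that("full photoreversible cycle closes the loop", {
  pp <- rh7_pigment_pair()
  quiet <- noise_model(0, 0, seed = 1)
  meas <- run_protocol(pp, uv_yellow_protocol(1), noise = quiet)
  rec <- reconstruct_bistable_pair(meas[[1]]$spectrum, meas[[2]]$spectrum,
                                   meas[[3]]$spectrum)
  # conversion is nearly complete, so the recovered state parameters match
  expect_lte(abs(rec$fit$lambda_max - pp$truth$meta_lambda_max), 1)
  conv <- meas[[2]]$fraction_meta - meas[[3]]$fraction_meta
  expect_lt(abs(rec$fit$amplitude - conv * pp$truth$meta_amplitude),
            0.01 * conv * pp$truth$meta_amplitude)
  # regeneration residual ~ 0 for a reversible cycle at zero noise; the
  # yellow photosteady state retains a ~1e-4 meta fraction, so the
  # residual is small but not machine zero
  expect_lt(rec$regeneration_residual_norm, 1e-3)
  # algebraic conservation at machine precision
  expect_lt(max(abs(rec$original_spectrum$absorbance -
                      (rec$irradiated_spectrum$absorbance +
                         rec$diff$absorbance))), 1e-12)
})

test_that("over-regeneration leaves a positive residual at the dark peak", {
  pp <- rh7_pigment_pair()
  quiet <- noise_model(0, 0, seed = 1)
  # start with 5% of the pigment already in the all-trans (meta) state;
  # yellow light then converts that extra pool back too, so the spectrum
  # after yellow exceeds the starting one at the dark-state peak
  meas <- run_protocol(pp, uv_yellow_protocol(1),
                       initial_fraction_meta = 0.05, noise = quiet)
  rec <- reconstruct_bistable_pair(meas[[1]]$spectrum, meas[[2]]$spectrum,
                                   meas[[3]]$spectrum)
  dark_peak <- lambda_max(pp$dark)
  at_peak <- rec$regeneration_residual$absorbance[
    rec$regeneration_residual$wavelength == dark_peak]
  expect_gt(at_peak, 0)
  expect_gt(rec$regeneration_residual_norm, 1e-4)
})

test_that("incomplete conversion scales the fitted amplitude linearly", {
  pp <- rh7_pigment_pair()
  g <- pp$dark$wavelength
  full <- difference(mixture_spectrum(pp, 0), mixture_spectrum(pp, 1))
  partial <- difference(mixture_spectrum(pp, 0), mixture_spectrum(pp, 0.7))
  f_full <- fit_irradiated_state(flip_convention(full))
  f_part <- fit_irradiated_state(flip_convention(partial))
  expect_equal(f_part$amplitude / f_full$amplitude, 0.7, tolerance = 1e-6)
  expect_lte(abs(f_part$lambda_max - f_full$lambda_max), 1)
})

test_that("irradiated_fit methods are mutually consistent", {
  diffsp <- make_known_diff()
  fit <- fit_irradiated_state(diffsp, window = c(480, 650))
  expect_named(coef(fit), c("lambda_max", "amplitude", "baseline"))
  inwin <- diffsp$wavelength >= 480 & diffsp$wavelength <= 650
  expect_equal(fitted(fit) + residuals(fit), diffsp$absorbance[inwin])
  expect_equal(sqrt(mean(residuals(fit)^2)), fit$rmse, tolerance = 1e-10)
  pr <- predict(fit, grid = c(500, 510, 520))
  expect_s3_class(pr, "spectrum")
  expect_equal(max(pr$absorbance), fit$amplitude, tolerance = 1e-3)
  expect_output(print(fit), "lambda_max")
})
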