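# Forward simulator of a bistable pigment under filtered-light
# irradiation: the synthetic-data generator for the whole pipeline.
#
# Two-state photokinetics in the optically thin regime: a sample with
# metarhodopsin fraction f converts at rates
#   k_fwd = sum_lambda I(lambda) eps_dark(lambda) phi_forward   (dark -> meta)
#   k_rev = sum_lambda I(lambda) eps_meta(lambda) phi_reverse   (meta -> dark)
# so df/dt = k_fwd (1 - f) - k_rev f, relaxing exponentially to the
# photosteady fraction k_fwd / (k_fwd + k_rev) regardless of the initial
# composition.

#' Bistable pigment pair (simulator ground truth)
#'
#' @param dark_spectrum spectrum of the dark (11-cis-retinal-bound) state,
#'   extinction-proportional AU.
#' @param meta_spectrum spectrum of the metarhodopsin (all-trans) state,
#'   same grid.
#' @param phi_forward,phi_reverse photoconversion quantum yields in (0, 1].
#' @return Object of class `"pigment_pair"`.
#' @export
pigment_pair <- function(dark_spectrum, meta_spectrum,
                         phi_forward = 1, phi_reverse = 1) {
  stopifnot(inherits(dark_spectrum, "spectrum"),
            inherits(meta_spectrum, "spectrum"))
  if (!isTRUE(all.equal(dark_spectrum$wavelength, meta_spectrum$wavelength))) {
    stop("dark and meta spectra must share a grid")
  }
  for (phi in c(phi_forward, phi_reverse)) {
    if (!is.numeric(phi) || phi <= 0 || phi > 1) {
      stop("quantum yields must lie in (0, 1]")
    }
  }
  structure(list(dark = dark_spectrum, meta = meta_spectrum,
                 phi_forward = phi_forward, phi_reverse = phi_reverse),
            class = "pigment_pair")
}

#' @export
print.pigment_pair <- function(x, ...) {
  cat(sprintf(
    "<pigment pair: dark peak %g nm (%.3g AU), meta peak %g nm (%.3g AU), phi %g/%g>\n",
    lambda_max(x$dark), max(x$dark$absorbance),
    lambda_max(x$meta), max(x$meta$absorbance),
    x$phi_forward, x$phi_reverse))
  invisible(x)
}

#' Irradiation light source
#'
#' Ideal top-hat band or monochromatic line. Longpass filters are encoded
#' as bands extending to the end of the working grid.
#'
#' @param kind `"band"` or `"monochromatic"`.
#' @param lower,upper band edges in nm (band kind); `upper = Inf` is
#'   clamped to the grid end.
#' @param wavelength line position in nm (monochromatic kind).
#' @param relative_intensity dimensionless scale factor.
#' @return Object of class `"light_source"`.
#' @export
light_source <- function(kind = c("band", "monochromatic"),
                         lower = NULL, upper = NULL, wavelength = NULL,
                         relative_intensity = 1) {
  kind <- match.arg(kind)
  if (kind == "band") {
    stopifnot(is.numeric(lower), is.numeric(upper), lower < upper)
  } else {
    stopifnot(is.numeric(wavelength))
  }
  structure(list(kind = kind, lower = lower, upper = upper,
                 wavelength = wavelength,
                 relative_intensity = relative_intensity),
            class = "light_source")
}

#' Standard irradiation filter set
#'
#' Idealized top-hat versions of the glass filters used in bench
#' photoconversion protocols: a UV band (330-390 nm), a blue band-pass
#' (440-460 nm), and three longpass cutoffs (>500, >550, >575 nm).
#'
#' @return Named list of [light_source()] objects:
#'   `uv`, `blue450`, `longpass500`, `longpass550`, `longpass575`.
#' @export
standard_filters <- function() {
  list(
    uv          = light_source("band", 330, 390),
    blue450     = light_source("band", 440, 460),
    longpass500 = light_source("band", 500, Inf),
    longpass550 = light_source("band", 550, Inf),
    longpass575 = light_source("band", 575, Inf)
  )
}

source_weights <- function(source, grid) {
  stopifnot(inherits(source, "light_source"))
  if (source$kind == "band") {
    upper <- min(source$upper, max(grid))
    w <- as.numeric(grid >= source$lower & grid <= upper)
  } else {
    if (source$wavelength < min(grid) || source$wavelength > max(grid)) {
      stop("light source does not overlap the spectrum grid")
    }
    w <- numeric(length(grid))
    w[which.min(abs(grid - source$wavelength))] <- 1
  }
  if (!any(w > 0)) stop("light source does not overlap the spectrum grid")
  w * source$relative_intensity
}

photo_rates <- function(pigments, source) {
  grid <- pigments$dark$wavelength
  w <- source_weights(source, grid)
  k_fwd <- sum(w * pmax(pigments$dark$absorbance, 0)) * pigments$phi_forward
  k_rev <- sum(w * pmax(pigments$meta$absorbance, 0)) * pigments$phi_reverse
  c(k_fwd = k_fwd, k_rev = k_rev)
}

#' Photosteady-state metarhodopsin fraction
#'
#' Under continued irradiation the two-state system relaxes to the
#' composition where forward and reverse photoconversion rates balance:
#' `f = k_fwd / (k_fwd + k_rev)`, with the rates integrated over the
#' source support. Returns 1 when only the dark state absorbs the light,
#' 0 when only the metarhodopsin does.
#'
#' @param pigments a [pigment_pair()].
#' @param source a [light_source()].
#' @return Fraction of pigment in the metarhodopsin state at photosteady
#'   state, in \[0, 1\].
#' @export
photosteady_fraction <- function(pigments, source) {
  k <- photo_rates(pigments, source)
  if (k[1] == 0 && k[2] == 0) {
    stop("no photochemistry: neither state absorbs within the source support")
  }
  unname(k[1] / (k[1] + k[2]))
}

#' Linear mixture of the two state spectra
#'
#' @param pigments a [pigment_pair()].
#' @param fraction_meta metarhodopsin fraction in \[0, 1\].
#' @return `(1 - f) * dark + f * meta` as a spectrum.
#' @export
mixture_spectrum <- function(pigments, fraction_meta) {
  if (!is.numeric(fraction_meta) || fraction_meta < 0 || fraction_meta > 1) {
    stop("fraction_meta must lie in [0, 1]")
  }
  s <- pigments$dark * (1 - fraction_meta) + pigments$meta * fraction_meta
  s$label <- sprintf("mixture (f_meta = %.3f)", fraction_meta)
  s
}

#' Measurement noise model
#'
#' @param sigma_additive additive Gaussian noise s.d., AU.
#' @param baseline_drift_slope baseline drift scale, AU per 100 nm; each
#'   measurement receives a linear-in-wavelength baseline with a
#'   seeded standard-normal multiplier of this slope (drift varies
#'   between measurements, as unsteady instrument baselines do).
#' @param seed integer RNG seed for the run.
#' @return Object of class `"noise_model"`.
#' @export
noise_model <- function(sigma_additive = 0, baseline_drift_slope = 0, seed = 1) {
  stopifnot(sigma_additive >= 0)
  structure(list(sigma_additive = sigma_additive,
                 baseline_drift_slope = baseline_drift_slope,
                 seed = as.integer(seed)),
            class = "noise_model")
}

#' Protocol step
#'
#' @param source a [light_source()].
#' @param duration `"to_steady_state"` or a finite time in seconds
#'   (rates are in the simulator's per-second convention: summed
#'   absorbance x quantum yield x relative intensity).
#' @return Object of class `"protocol_step"`.
#' @export
protocol_step <- function(source, duration = "to_steady_state") {
  stopifnot(inherits(source, "light_source"))
  if (!(identical(duration, "to_steady_state") ||
        (is.numeric(duration) && duration >= 0))) {
    stop("duration must be 'to_steady_state' or a nonnegative number of seconds")
  }
  structure(list(source = source, duration = duration),
            class = "protocol_step")
}

#' Alternating forward/back irradiation protocol
#'
#' The canonical bench sequence: forward (UV) irradiation to photosteady
#' state, then back (longpass) irradiation, repeated.
#'
#' @param n_cycles number of forward/back cycles.
#' @param forward,backward light sources; defaults: the UV band and the
#'   >500 nm longpass of [standard_filters()].
#' @return List of [protocol_step()]s.
#' @export
uv_yellow_protocol <- function(n_cycles = 1,
                               forward = standard_filters()$uv,
                               backward = standard_filters()$longpass500) {
  rep(list(protocol_step(forward), protocol_step(backward)), n_cycles)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

observe_spectrum <- function(pigments, fraction, noise, label) {
  s <- mixture_spectrum(pigments, fraction)
  grid <- s$wavelength
  drift_z <- stats::rnorm(1)
  drift <- noise$baseline_drift_slope * drift_z *
    (grid - mean(grid)) / 100
  eps <- stats::rnorm(length(grid), sd = noise$sigma_additive)
  out <- new_spectrum(grid, s$absorbance + drift + eps, label)
  out
}

#' Run an irradiation protocol and record noisy spectra
#'
#' Simulates the measurement sequence of a photoconversion experiment:
#' the initial composition is recorded first, then after each protocol
#' step the metarhodopsin fraction is updated (to the photosteady
#' fraction for `"to_steady_state"` steps; by the closed-form exponential
#' relaxation of the two-state photokinetic equation for finite
#' durations) and a spectrum is recorded. Each recorded spectrum is the
#' linear state mixture plus a seeded linear baseline drift and additive
#' Gaussian noise. All randomness derives from `noise$seed`; reruns with
#' the same seed are bit-identical.
#'
#' @param pigments a [pigment_pair()].
#' @param steps list of [protocol_step()]s.
#' @param initial_fraction_meta starting metarhodopsin fraction in \[0, 1\].
#' @param noise a [noise_model()].
#' @return List with one element per measurement (the initial one plus one
#'   per step): each a list of `spectrum`, `fraction_meta`, `step`
#'   (0 for the initial measurement).
#' @export
run_protocol <- function(pigments, steps, initial_fraction_meta = 0,
                         noise = noise_model()) {
  stopifnot(inherits(pigments, "pigment_pair"))
  if (initial_fraction_meta < 0 || initial_fraction_meta > 1) {
    stop("initial_fraction_meta must lie in [0, 1]")
  }
  with_seed(noise$seed, {
    f <- initial_fraction_meta
    out <- vector("list", length(steps) + 1L)
    out[[1]] <- list(spectrum = observe_spectrum(pigments, f, noise, "initial"),
                     fraction_meta = f, step = 0L)
    for (i in seq_along(steps)) {
      st <- steps[[i]]
      stopifnot(inherits(st, "protocol_step"))
      k <- photo_rates(pigments, st$source)
      if (k[1] == 0 && k[2] == 0) {
        stop("no photochemistry: neither state absorbs within the source support")
      }
      f_ss <- unname(k[1] / (k[1] + k[2]))
      if (identical(st$duration, "to_steady_state")) {
        f <- f_ss
      } else {
        f <- f_ss + (f - f_ss) * exp(-unname(k[1] + k[2]) * st$duration)
      }
      out[[i + 1]] <- list(
        spectrum = observe_spectrum(pigments, f, noise,
                                    sprintf("after step %d", i)),
        fraction_meta = f, step = i)
    }
    out
  })
}

#' Rh7-like bistable pigment fixture (synthetic)
#'
#' Synthetic ground-truth pigment pair emulating a UV-absorbing bistable
#' pigment with a composite dark-state band: the dark state is
#' `0.65 * template(360) + 0.35 * template(415)` (A1 family), the
#' metarhodopsin a 510 nm metarhodopsin-like template whose amplitude is
#' solved numerically so that the UV:visible amplitude ratio of the
#' forward photoconversion difference spectrum is exactly `1 : ratio`.
#' Alpha-band-only templates are used so that template fits close the
#' loop exactly at zero noise. These parameters are a synthetic fixture,
#' not measured values.
#'
#' @param grid wavelength grid; defaults to [default_grid()].
#' @param dark_weights weights of the 360/415 nm dark-state components.
#' @param meta_lambda_max metarhodopsin peak wavelength, nm.
#' @param ratio target visible:UV difference-amplitude ratio (default 8).
#' @param phi_forward,phi_reverse quantum yields.
#' @return A [pigment_pair()].
#' @export
rh7_pigment_pair <- function(grid = default_grid(),
                             dark_weights = c(0.65, 0.35),
                             meta_lambda_max = 510, ratio = 8,
                             phi_forward = 1, phi_reverse = 1) {
  dark <- template_spectrum(360, grid) * dark_weights[1] +
    template_spectrum(415, grid) * dark_weights[2]
  dark$label <- "synthetic Rh7-like dark state"
  meta1 <- template_spectrum(meta_lambda_max, grid,
                             family = "metarhodopsin_like")
  # visible:UV amplitude ratio of (a * meta - dark) is monotone in a
  ratio_at <- function(a) {
    d <- a * meta1$absorbance - dark$absorbance
    max(d) / abs(min(d))
  }
  a <- stats::uniroot(function(a) ratio_at(a) - ratio,
                      lower = 1e-3, upper = 100, tol = 1e-10)$root
  meta <- meta1 * a
  meta$label <- sprintf("synthetic Rh7-like metarhodopsin (%g nm)",
                        meta_lambda_max)
  out <- pigment_pair(dark, meta, phi_forward, phi_reverse)
  out$truth <- list(dark_lambda_max = c(360, 415), dark_weights = dark_weights,
                    meta_lambda_max = meta_lambda_max, meta_amplitude = a,
                    ratio = ratio)
  out
}
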