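# Visual-pigment template (nomogram) curves.
#
# The alpha band follows the Govardovskii-type closed form in the
# normalized coordinate x = lambda_max / lambda:
#
#   S(x) = 1 / ( exp(A (a - x)) + exp(B (b - x)) + exp(C (c - x)) + D )
#
# with a = a0 + a1 exp(-(lambda_max - a2)^2 / a3). The curve is divided by
# its value at x = 1 so absorbance at lambda_max is exactly 1. The optional
# beta band is a Gaussian satellite at lambda_mb = beta_b0 + beta_b1 *
# lambda_max with width beta_w0 + beta_w1 * lambda_max and amplitude
# beta_amp relative to the alpha peak.

.template_families <- c("a1_pigment", "metarhodopsin_like", "retinochrome_like")

template_constants <- function(family, shape_overrides = NULL) {
  base <- list(
    A = 69.7, B = 28.0, C = -14.9, D = 0.674,
    b = 0.922, c = 1.104,
    a = NA_real_,                      # resolved from lambda_max unless overridden
    a0 = 0.8795, a1 = 0.0459, a2 = 300, a3 = 11940,
    beta_amp = 0.26, beta_b0 = 189, beta_b1 = 0.315,
    beta_w0 = -40.5, beta_w1 = 0.195
  )
  tweaks <- switch(family,
    a1_pigment = list(),
    # broader bands for photoproduct-like shapes; same functional form
    metarhodopsin_like = list(B = 25.2, C = -13.4),
    retinochrome_like = list(B = 26.6, C = -14.2),
    stop(sprintf("unknown template family '%s'", family))
  )
  base[names(tweaks)] <- tweaks
  if (!is.null(shape_overrides)) {
    bad <- setdiff(names(shape_overrides), names(base))
    if (length(bad)) {
      stop(sprintf("unknown shape override(s): %s", paste(bad, collapse = ", ")))
    }
    base[names(shape_overrides)] <- shape_overrides
  }
  base
}

template_alpha <- function(lambda, lambda_max, k) {
  a <- if (is.na(k$a)) {
    k$a0 + k$a1 * exp(-(lambda_max - k$a2)^2 / k$a3)
  } else {
    k$a
  }
  x <- lambda_max / lambda
  raw <- function(x) {
    1 / (exp(k$A * (a - x)) + exp(k$B * (k$b - x)) + exp(k$C * (k$c - x)) + k$D)
  }
  raw(x) / raw(1)
}

#' Pigment template (nomogram) spectrum
#'
#' Generates a visual-pigment absorbance template parameterized by the
#' wavelength of maximal absorbance. The alpha band is a fixed-shape
#' closed form in the normalized coordinate `lambda_max / lambda`,
#' normalized to 1.0 at `lambda_max`; the optional beta band adds a
#' Gaussian satellite in the UV. Three families are provided: the A1
#' (11-cis-retinal pigment) shape and two slightly broadened variants
#' used for photoproduct states (bovine metarhodopsin-I-like, squid
#' retinochrome-like). All families share the functional form and differ
#' only in default shape constants, which can be overridden per call.
#'
#' @param lambda_max peak wavelength, nm, in \[300, 650\].
#' @param grid wavelength grid, nm, within \[250, 800\];
#'   defaults to [default_grid()].
#' @param family `"a1_pigment"`, `"metarhodopsin_like"`, or
#'   `"retinochrome_like"`.
#' @param include_beta_band add the Gaussian beta band (default `FALSE`;
#'   fits to the long-wavelength flank never need it).
#' @param shape_overrides named list overriding shape constants
#'   (`A`, `B`, `C`, `D`, `b`, `c`, `a`, `a0`..`a3`, `beta_*`). Supplying
#'   `a` freezes the bandwidth parameter so the alpha band becomes a
#'   function of `lambda_max / lambda` only.
#' @return A [new_spectrum()] with absorbance 1.0 at `lambda_max`.
#' @examples
#' t510 <- template_spectrum(510)
#' lambda_max(t510)
#' @export
template_spectrum <- function(lambda_max, grid = default_grid(),
                              family = c("a1_pigment", "metarhodopsin_like",
                                         "retinochrome_like"),
                              include_beta_band = FALSE,
                              shape_overrides = NULL) {
  family <- match.arg(family)
  if (!is.numeric(lambda_max) || length(lambda_max) != 1 ||
      lambda_max < 300 || lambda_max > 650) {
    stop("lambda_max must be a single value in [300, 650] nm")
  }
  grid <- as.numeric(grid)
  if (min(grid) < 250 || max(grid) > 800) {
    stop("template grid must lie within [250, 800] nm")
  }
  k <- template_constants(family, shape_overrides)
  ab <- template_alpha(grid, lambda_max, k)
  if (include_beta_band) {
    mb <- k$beta_b0 + k$beta_b1 * lambda_max
    bw <- k$beta_w0 + k$beta_w1 * lambda_max
    ab <- ab + k$beta_amp * exp(-((grid - mb) / bw)^2)
  }
  new_spectrum(grid, ab,
               label = sprintf("%s template, lambda_max %g nm", family, lambda_max))
}

#' Bank of template spectra on a shared grid
#'
#' Convenience wrapper generating one template per requested peak
#' wavelength, used as the fitting basis for grid searches.
#'
#' @inheritParams template_spectrum
#' @param lambda_max_values numeric vector of peak wavelengths.
#' @return A named list of spectra (names are the lambda_max values).
#' @export
template_bank <- function(lambda_max_values, family = "a1_pigment",
                          grid = default_grid(), include_beta_band = FALSE,
                          shape_overrides = NULL) {
  if (length(lambda_max_values) == 0) {
    stop("lambda_max_values must be non-empty")
  }
  out <- lapply(lambda_max_values, template_spectrum, grid = grid,
                family = family, include_beta_band = include_beta_band,
                shape_overrides = shape_overrides)
  names(out) <- as.character(lambda_max_values)
  out
}

# Matrix of template curves (rows = grid points, cols = lambda_max values);
# the workhorse behind the grid-search fitters.
template_matrix <- function(lambda_max_values, grid, family = "a1_pigment",
                            include_beta_band = FALSE, shape_overrides = NULL) {
  vapply(lambda_max_values, function(lm) {
    template_spectrum(lm, grid = grid, family = family,
                      include_beta_band = include_beta_band,
                      shape_overrides = shape_overrides)$absorbance
  }, numeric(length(grid)))
}
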