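# Independent oracles, written as literal transcriptions of the
# closed forms, separate from the package's code paths.

# Direct single-point evaluation of the alpha-band template closed form,
# normalized at lambda = lambda_max. Constants are duplicated here on
# purpose so the test does not share code with the implementation.
oracle_template_point <- function(lambda, lambda_max,
                                  family = c("a1_pigment",
                                             "metarhodopsin_like",
                                             "retinochrome_like")) {
  family <- match.arg(family)
  A <- 69.7; D <- 0.674; b <- 0.922; cc <- 1.104
  B <- switch(family, a1_pigment = 28.0, metarhodopsin_like = 25.2,
              retinochrome_like = 26.6)
  C <- switch(family, a1_pigment = -14.9, metarhodopsin_like = -13.4,
              retinochrome_like = -14.2)
  a <- 0.8795 + 0.0459 * exp(-(lambda_max - 300)^2 / 11940)
  f <- function(x) 1 / (exp(A * (a - x)) + exp(B * (b - x)) +
                          exp(C * (cc - x)) + D)
  f(lambda_max / lambda) / f(1)
}

# Long-time limit of brute-force integration of the two-state
# photokinetic rate equations df/dt = k_fwd (1 - f) - k_rev f.
oracle_steady_state_ode <- function(pigments, source, f0 = 0) {
  grid <- pigments$dark$wavelength
  upper <- if (source$kind == "band") min(source$upper, max(grid)) else NA
  w <- if (source$kind == "band") {
    as.numeric(grid >= source$lower & grid <= upper)
  } else {
    w0 <- numeric(length(grid))
    w0[which.min(abs(grid - source$wavelength))] <- 1
    w0
  }
  w <- w * source$relative_intensity
  k_fwd <- sum(w * pmax(pigments$dark$absorbance, 0)) * pigments$phi_forward
  k_rev <- sum(w * pmax(pigments$meta$absorbance, 0)) * pigments$phi_reverse
  rate <- function(t, y, parms) list(k_fwd * (1 - y[1]) - k_rev * y[1])
  t_end <- 60 / (k_fwd + k_rev)  # dozens of relaxation times
  sol <- deSolve::ode(y = c(f = f0), times = c(0, t_end), func = rate,
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  unname(sol[nrow(sol), "f"])
}

# Exhaustive 2-D grid search over (lambda_max, amplitude) for the
# irradiated-state fit, no baseline; the brute-force reference for the
# closed-form least-squares path.
oracle_fit_grid_search <- function(diff, window, family = "metarhodopsin_like",
                                   lam_grid = seq(400, 620, by = 1),
                                   amp_grid = seq(0.05, 3, by = 0.005)) {
  inwin <- diff$wavelength >= window[1] & diff$wavelength <= window[2]
  wl <- diff$wavelength[inwin]
  y <- diff$absorbance[inwin]
  best <- c(NA, NA, Inf)
  for (lm in lam_grid) {
    tv <- template_spectrum(lm, grid = wl, family = family)$absorbance
    ssr <- colSums((y - outer(tv, amp_grid))^2)
    j <- which.min(ssr)
    if (ssr[j] < best[3]) best <- c(lm, amp_grid[j], ssr[j])
  }
  c(lambda_max = best[1], amplitude = best[2], ssr = best[3])
}

# Independent pointwise linear interpolation formula.
oracle_linear_interp <- function(x, y, xout) {
  vapply(xout, function(x0) {
    i <- max(which(x <= x0))
    if (x[i] == x0) return(y[i])
    y[i] + (y[i + 1] - y[i]) * (x0 - x[i]) / (x[i + 1] - x[i])
  }, numeric(1))
}
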