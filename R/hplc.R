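# HPLC quantification of retinal isomer composition.
#
# Chromophores are extracted as retinaloximes (syn and anti forms of
# 11-cis-, 13-cis-, and all-trans-retinal oximes) and separated on a
# silica column; the trace is the absorbance at 360 nm versus retention
# time. Peaks are detected by prominence, co-fitted as Gaussians, and
# integrated; fractions are corrected areas over the total.

.isomer_species <- c("11-cis syn", "11-cis anti", "13-cis syn",
                     "13-cis anti", "all-trans syn", "all-trans anti")
.isomers <- c("11-cis", "13-cis", "all-trans")

#' Chromatogram object
#'
#' @param retention_time minutes, strictly increasing, at least 10 points.
#' @param signal absorbance at 360 nm, AU.
#' @param label free text.
#' @return Object of class `"chromatogram"`.
#' @export
new_chromatogram <- function(retention_time, signal, label = "") {
  retention_time <- as.numeric(retention_time)
  signal <- as.numeric(signal)
  if (length(retention_time) != length(signal)) {
    stop("retention_time and signal must have the same length")
  }
  if (length(retention_time) < 10) stop("a chromatogram needs at least 10 points")
  if (anyNA(retention_time) || anyNA(signal) ||
      !all(is.finite(c(retention_time, signal)))) {
    stop("chromatogram values must be finite")
  }
  if (any(diff(retention_time) <= 0)) {
    stop("retention times must be strictly increasing")
  }
  structure(list(retention_time = retention_time, signal = signal,
                 label = as.character(label)[1]),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf("<chromatogram%s: %d points, %.2f-%.2f min, max %.4g AU>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$retention_time), min(x$retention_time),
              max(x$retention_time), max(x$signal)))
  invisible(x)
}

#' @export
plot.chromatogram <- function(x, ..., type = "l") {
  graphics::plot(x$retention_time, x$signal, type = type,
                 xlab = "Retention time (min)", ylab = "A360 (AU)",
                 main = x$label, ...)
  invisible(x)
}

#' Default retention-time map for retinaloxime species
#'
#' Plausible elution order on a silica column: syn oximes elute first,
#' anti oximes later. Synthetic defaults for simulation and testing, not
#' calibrated values.
#'
#' @return Named numeric vector of retention times (minutes) for the six
#'   species.
#' @export
default_retention_map <- function() {
  c("11-cis syn" = 5.4, "13-cis syn" = 6.4, "all-trans syn" = 7.6,
    "11-cis anti" = 10.8, "13-cis anti" = 12.0, "all-trans anti" = 13.8)
}

# rolling-minimum baseline, fixed window (points), centered
rolling_min_baseline <- function(y, window = 20) {
  n <- length(y)
  half <- window %/% 2
  vapply(seq_len(n), function(i) {
    min(y[max(1, i - half):min(n, i + half)])
  }, numeric(1))
}

# local maxima with topographic prominence
find_peaks <- function(y) {
  n <- length(y)
  idx <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(idx) == 0) return(data.frame(index = integer(), prominence = numeric()))
  prom <- vapply(idx, function(i) {
    h <- y[i]
    left <- y[seq_len(i - 1)]
    higher_l <- which(left > h)
    base_l <- if (length(higher_l)) min(y[(max(higher_l) + 1):(i - 1)]) else min(left)
    right <- y[(i + 1):n]
    higher_r <- which(right > h)
    base_r <- if (length(higher_r)) min(y[i + seq_len(min(higher_r) - 1)]) else min(right)
    h - max(base_l, base_r)
  }, numeric(1))
  data.frame(index = idx, prominence = prom)
}

#' Detect and integrate chromatogram peaks
#'
#' Detection runs on a rolling-minimum-baseline-subtracted, lightly
#' smoothed copy of the trace: local maxima whose topographic prominence
#' exceeds `min_prominence` are kept. All detected peaks are then
#' co-fitted on the raw trace as a sum of Gaussians plus a constant
#' offset (overlapping peaks are therefore fitted jointly). The area of
#' each peak is the analytic Gaussian area
#' `amplitude * width * sqrt(2*pi)`.
#'
#' @param chromatogram a [new_chromatogram()].
#' @param min_prominence minimum peak prominence, AU (> 0).
#' @param baseline_window rolling-minimum window, points (default 20).
#' @param smooth_window moving-average window (points, odd) applied
#'   before peak detection only, to keep single-point noise excursions
#'   below the prominence threshold; the Gaussian fit uses the raw
#'   baseline-corrected signal. Default 5.
#' @param min_distance minimum separation between detected peaks
#'   (minutes); of two maxima closer than this, only the higher is kept.
#'   Default 0.2.
#' @return A `"peak_table"`: `data.frame(position, height, width, area)`
#'   (minutes, AU, minutes s.d., AU*min). If no peak exceeds the
#'   prominence threshold, a zero-row table is returned with a warning.
#' @export
detect_and_integrate_peaks <- function(chromatogram, min_prominence = 0.01,
                                       baseline_window = 20,
                                       smooth_window = 5,
                                       min_distance = 0.2) {
  stopifnot(inherits(chromatogram, "chromatogram"))
  if (!is.numeric(min_prominence) || min_prominence <= 0) {
    stop("min_prominence must be > 0")
  }
  t <- chromatogram$retention_time
  y <- chromatogram$signal
  ydet <- y - rolling_min_baseline(y, baseline_window)
  ys <- if (smooth_window > 1) {
    as.numeric(stats::filter(ydet, rep(1 / smooth_window, smooth_window),
                             sides = 2))
  } else {
    ydet
  }
  ys[is.na(ys)] <- 0
  pk <- find_peaks(ys)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  if (nrow(pk) > 1) {
    # non-maximum suppression within min_distance
    ord <- order(ys[pk$index], decreasing = TRUE)
    kept <- integer(0)
    for (r in ord) {
      if (!length(kept) ||
          all(abs(t[pk$index[r]] - t[pk$index[kept]]) >= min_distance)) {
        kept <- c(kept, r)
      }
    }
    pk <- pk[sort(kept), , drop = FALSE]
  }
  empty <- data.frame(position = numeric(), height = numeric(),
                      width = numeric(), area = numeric())
  class(empty) <- c("peak_table", "data.frame")
  if (nrow(pk) == 0) {
    warning("no peaks above the prominence threshold; returning an empty peak table")
    return(empty)
  }

  # starting values: position at the maximum, width from half-height span
  # of the detection signal
  k <- nrow(pk)
  start_mu <- t[pk$index]
  start_amp <- pmax(ys[pk$index], .Machine$double.eps)
  start_sd <- vapply(seq_len(k), function(j) {
    i <- pk$index[j]; half <- ys[i] / 2
    li <- i; while (li > 1 && ys[li] > half) li <- li - 1
    ri <- i; while (ri < length(ys) && ys[ri] > half) ri <- ri + 1
    max((t[ri] - t[li]) / 2.355, (t[2] - t[1]))
  }, numeric(1))

  gauss_sum <- function(p) {
    amp <- p[seq_len(k)]
    mu <- p[k + seq_len(k)]
    sd <- p[2 * k + seq_len(k)]
    p[3 * k + 1] + rowSums(vapply(seq_len(k), function(j) {
      amp[j] * exp(-0.5 * ((t - mu[j]) / sd[j])^2)
    }, numeric(length(t))))
  }
  start <- c(start_amp, start_mu, start_sd, 0)
  # positions may shift only locally; widths stay near the half-height
  # estimate so no component can degenerate into a broad pseudo-baseline;
  # a constant offset absorbs the trace background
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start,
                       fn = function(p) y - gauss_sum(p),
                       lower = c(rep(0, k), start_mu - min_distance,
                                 pmax(start_sd / 5, (t[2] - t[1]) / 2),
                                 -max(abs(y))),
                       upper = c(rep(Inf, k), start_mu + min_distance,
                                 start_sd * 5, max(abs(y))),
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  p <- if (is.null(fit)) start else fit$par
  amp <- p[seq_len(k)]; mu <- p[k + seq_len(k)]; sdv <- p[2 * k + seq_len(k)]

  out <- data.frame(position = mu, height = amp, width = sdv,
                    area = amp * sdv * sqrt(2 * pi))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Isomer composition from integrated peaks
#'
#' Assigns each detected peak to the retinaloxime species with the
#' nearest mapped retention time (within `tolerance`), applies optional
#' molar-extinction corrections, and normalizes corrected areas to
#' fractions. Fractions are aggregated per isomer (syn + anti).
#'
#' @param peaks a peak table from [detect_and_integrate_peaks()].
#' @param assignment_map named numeric vector: species -> retention time
#'   (minutes). Defaults to [default_retention_map()].
#' @param extinction_corrections named numeric vector of per-species
#'   multiplicative corrections (default: all 1).
#' @param tolerance maximum |peak position - mapped time| for an
#'   assignment, minutes.
#' @param unassigned_threshold fraction of total area above which an
#'   unassignable peak is an error rather than ignored.
#' @return Object of class `"isomer_composition"`: `species` (named
#'   fractions over the six oxime species) and `isomer` (named fractions
#'   over 11-cis / 13-cis / all-trans, summing to 1).
#' @export
compose_fractions <- function(peaks, assignment_map = default_retention_map(),
                              extinction_corrections = NULL,
                              tolerance = 0.5, unassigned_threshold = 0.01) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks) == 0) stop("no peaks to compose fractions from")
  if (is.null(extinction_corrections)) {
    extinction_corrections <- stats::setNames(rep(1, length(assignment_map)),
                                              names(assignment_map))
  }
  total <- sum(peaks$area)
  areas <- stats::setNames(rep(0, length(assignment_map)), names(assignment_map))
  for (r in seq_len(nrow(peaks))) {
    d <- abs(assignment_map - peaks$position[r])
    j <- which.min(d)
    if (d[j] > tolerance) {
      if (peaks$area[r] / total > unassigned_threshold) {
        stop(sprintf("unassigned peak at retention time %.2f min (area %.3g)",
                     peaks$position[r], peaks$area[r]))
      }
      next
    }
    sp <- names(assignment_map)[j]
    areas[sp] <- areas[sp] + peaks$area[r] * extinction_corrections[[sp]]
  }
  if (sum(areas) == 0) stop("no peaks could be assigned to any species")
  species <- areas / sum(areas)
  isomer <- vapply(.isomers, function(iso) {
    sum(species[grep(paste0("^", iso, " "), names(species))])
  }, numeric(1))
  structure(list(species = species, isomer = isomer),
            class = "isomer_composition")
}

#' @export
print.isomer_composition <- function(x, ...) {
  cat("Isomer composition (fraction of total corrected area)\n")
  for (iso in names(x$isomer)) {
    cat(sprintf("  %-10s %6.3f\n", iso, x$isomer[iso]))
  }
  invisible(x)
}

#' Simulate a retinaloxime chromatogram
#'
#' Generates a sum-of-Gaussians trace for a known isomer composition,
#' splitting each isomer between its syn and anti oxime peaks, plus
#' seeded additive Gaussian noise. The fixture generator for testing the
#' detection/integration round trip.
#'
#' @param composition named fractions for `"11-cis"`, `"13-cis"`,
#'   `"all-trans"` (must sum to 1).
#' @param retention_map species retention times; default
#'   [default_retention_map()].
#' @param widths Gaussian s.d. per species, minutes (recycled; default 0.08).
#' @param syn_fraction fraction of each isomer in the syn oxime
#'   (default 0.7).
#' @param total_area total trace area, AU*min.
#' @param noise_sd additive noise s.d., AU.
#' @param seed RNG seed.
#' @param times sampling grid, minutes.
#' @return A [new_chromatogram()]; attribute `"overlapping"` flags any
#'   species pair closer than 2 combined widths.
#' @export
simulate_chromatogram <- function(composition,
                                  retention_map = default_retention_map(),
                                  widths = 0.08, syn_fraction = 0.7,
                                  total_area = 1, noise_sd = 0, seed = 1,
                                  times = seq(0.5, 16, by = 0.02)) {
  if (is.null(names(composition)) ||
      !setequal(names(composition), .isomers)) {
    stop("composition must be named with '11-cis', '13-cis', 'all-trans'")
  }
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-9) {
    stop("composition fractions must be nonnegative and sum to 1")
  }
  widths <- stats::setNames(rep_len(widths, length(retention_map)),
                            names(retention_map))
  areas <- stats::setNames(rep(0, length(retention_map)), names(retention_map))
  for (iso in .isomers) {
    areas[paste(iso, "syn")] <- total_area * composition[[iso]] * syn_fraction
    areas[paste(iso, "anti")] <- total_area * composition[[iso]] * (1 - syn_fraction)
  }
  mus <- retention_map[names(areas)]
  ord <- order(mus)
  gaps <- diff(mus[ord])
  sds <- widths[names(mus)[ord]]
  # flag pairs closer than 2 sigma (combined): unresolvable peaks
  overlap <- any(gaps < (utils::head(sds, -1) + utils::tail(sds, -1)))
  signal <- numeric(length(times))
  for (sp in names(areas)) {
    if (areas[sp] == 0) next
    sd <- widths[sp]
    signal <- signal + areas[sp] / (sd * sqrt(2 * pi)) *
      exp(-0.5 * ((times - retention_map[sp]) / sd)^2)
  }
  if (noise_sd > 0) {
    signal <- with_seed(seed, signal + stats::rnorm(length(times), sd = noise_sd))
  }
  out <- new_chromatogram(times, signal, label = "simulated retinaloxime trace")
  attr(out, "overlapping") <- overlap
  out
}

#' Isomer composition implied by a metarhodopsin fraction
#'
#' Maps the simulator's state composition onto chromophore configuration:
#' the dark-state fraction carries the dark composition (mostly 11-cis
#' with small 13-cis / all-trans contamination), the metarhodopsin
#' fraction is all-trans.
#'
#' @param fraction_meta metarhodopsin fraction in \[0, 1\].
#' @param dark_composition named isomer fractions of the dark state.
#' @return Named isomer composition summing to 1.
#' @export
state_composition <- function(fraction_meta,
                              dark_composition = c("11-cis" = 0.90,
                                                   "13-cis" = 0.04,
                                                   "all-trans" = 0.06)) {
  stopifnot(fraction_meta >= 0, fraction_meta <= 1)
  out <- dark_composition * (1 - fraction_meta)
  out["all-trans"] <- out["all-trans"] + fraction_meta
  out / sum(out)
}
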