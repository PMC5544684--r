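#' Construct a spectrum object
#'
#' A spectrum is the universal currency of the package: a strictly
#' increasing wavelength grid (nm) with absorbance values (arbitrary
#' units, AU). Absorbance is relative throughout; no pathlength or
#' concentration handling is attempted.
#'
#' @param wavelength numeric vector of wavelengths in nm, within
#'   \[200, 800\]. Rows are sorted if given out of order; duplicated
#'   wavelengths are an error.
#' @param absorbance numeric vector of absorbance values (AU), same length.
#' @param label free-text label carried through arithmetic and plots.
#' @return An object of class `"spectrum"`: a list with elements
#'   `wavelength`, `absorbance`, `label`.
#' @examples
#' s <- new_spectrum(300:400, exp(-((300:400 - 350) / 20)^2))
#' print(s)
#' @export
new_spectrum <- function(wavelength, absorbance, label = "") {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance)) {
    stop("wavelength and absorbance must have the same length")
  }
  if (length(wavelength) < 2) {
    stop("a spectrum needs at least 2 points")
  }
  if (anyNA(wavelength) || anyNA(absorbance) ||
      !all(is.finite(wavelength)) || !all(is.finite(absorbance))) {
    stop("spectrum values must be finite")
  }
  if (any(wavelength < 200) || any(wavelength > 800)) {
    stop("wavelengths must lie within [200, 800] nm")
  }
  if (anyDuplicated(wavelength)) {
    dup <- wavelength[duplicated(wavelength)][1]
    stop(sprintf("duplicate wavelength %g nm", dup))
  }
  o <- order(wavelength)
  structure(
    list(wavelength = wavelength[o], absorbance = absorbance[o],
         label = as.character(label)[1]),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  rng <- range(x$wavelength)
  cat(sprintf("<spectrum%s: %d points, %g-%g nm, peak %.4g AU at %g nm>\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$wavelength), rng[1], rng[2],
              max(x$absorbance),
              x$wavelength[which.max(x$absorbance)]))
  invisible(x)
}

#' @export
as.data.frame.spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, absorbance_AU = x$absorbance)
}

#' @export
plot.spectrum <- function(x, ..., xlab = "Wavelength (nm)",
                          ylab = "Absorbance (AU)", type = "l") {
  graphics::plot(x$wavelength, x$absorbance, type = type,
                 xlab = xlab, ylab = ylab, main = x$label, ...)
  invisible(x)
}

#' Wavelength of maximal absorbance
#'
#' @param spectrum a [new_spectrum()] object.
#' @return The grid wavelength (nm) at which absorbance is largest.
#' @export
lambda_max <- function(spectrum) {
  stopifnot(inherits(spectrum, "spectrum"))
  spectrum$wavelength[which.max(spectrum$absorbance)]
}

#' Group generic for spectrum arithmetic
#'
#' `+`, `-` and unary `-` combine spectra on identical grids; `*` and `/`
#' scale by a scalar. Difference-spectrum construction should normally go
#' through [difference()], which resamples and tags the sign convention.
#'
#' @param e1,e2 spectra or scalars.
#' @return A spectrum.
#' @export
Ops.spectrum <- function(e1, e2) {
  if (missing(e2)) {
    if (.Generic == "-") {
      return(new_spectrum(e1$wavelength, -e1$absorbance, e1$label))
    }
    stop(sprintf("unary '%s' not defined for spectra", .Generic))
  }
  if (!.Generic %in% c("+", "-", "*", "/")) {
    stop(sprintf("'%s' not defined for spectra", .Generic))
  }
  if (inherits(e1, "spectrum") && inherits(e2, "spectrum")) {
    if (!.Generic %in% c("+", "-")) {
      stop(sprintf("'%s' between two spectra is not defined", .Generic))
    }
    if (!isTRUE(all.equal(e1$wavelength, e2$wavelength))) {
      stop("spectra are on different grids; resample first")
    }
    ab <- get(.Generic)(e1$absorbance, e2$absorbance)
    return(new_spectrum(e1$wavelength, ab, e1$label))
  }
  if (inherits(e1, "spectrum")) {
    stopifnot(is.numeric(e2), length(e2) == 1)
    return(new_spectrum(e1$wavelength, get(.Generic)(e1$absorbance, e2),
                        e1$label))
  }
  stopifnot(is.numeric(e1), length(e1) == 1)
  new_spectrum(e2$wavelength, get(.Generic)(e1, e2$absorbance), e2$label)
}

#' Canonical wavelength grid
#'
#' The package's default working grid: 1 nm steps from 250 to 700 nm,
#' covering the usual 300-650 nm observation window of bench
#' spectrophotometry with margin.
#'
#' @return Integer-valued numeric vector `250:700`.
#' @export
default_grid <- function() {
  seq(250, 700, by = 1)
}

#' Read a two-column spectrum file
#'
#' Reads delimited text with columns (wavelength nm, absorbance AU).
#' Lines starting with `#` and blank lines are ignored; an optional
#' single non-numeric header row is skipped. Rows given in descending
#' wavelength order are sorted; duplicated wavelengths are an error.
#'
#' @param path file path.
#' @param dialect one of `"auto"` (default), `"comma"`, `"tab"`,
#'   `"whitespace"`; `"auto"` detects the delimiter from the first data row.
#' @param label label for the resulting spectrum; defaults to the file name.
#' @return A [new_spectrum()] object.
#' @export
read_spectrum <- function(path, dialect = c("auto", "comma", "tab", "whitespace"),
                          label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (length(keep) == 0) stop(sprintf("empty input: %s", path))
  lines <- raw[keep]

  split_line <- function(line) {
    if (dialect == "comma" || (dialect == "auto" && grepl(",", line))) {
      fields <- strsplit(line, ",", fixed = TRUE)[[1]]
    } else if (dialect == "tab") {
      fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    } else {
      fields <- strsplit(line, "[[:space:]]+")[[1]]
    }
    trimws(fields[nzchar(trimws(fields))])
  }

  first <- suppressWarnings(as.numeric(split_line(lines[1])))
  start <- 1L
  if (anyNA(first)) start <- 2L  # header row
  if (start > length(lines)) stop(sprintf("empty input: %s", path))

  n <- length(lines) - start + 1L
  wl <- ab <- numeric(n)
  for (i in seq_len(n)) {
    fields <- split_line(lines[start + i - 1L])
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) < 2 || anyNA(vals[1:2])) {
      stop(sprintf("malformed row at line %d of %s: '%s'",
                   keep[start + i - 1L], path, lines[start + i - 1L]))
    }
    wl[i] <- vals[1]
    ab[i] <- vals[2]
  }
  new_spectrum(wl, ab, label = label)
}

#' Write a spectrum to a delimited text file
#'
#' Tab-separated, two columns with a header, values at 6 significant
#' digits. Round-trips through [read_spectrum()] to printed precision.
#'
#' @param spectrum a spectrum.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "spectrum"))
  lines <- c(
    "wavelength_nm\tabsorbance_AU",
    sprintf("%s\t%s",
            formatC(spectrum$wavelength, digits = 6, format = "g"),
            formatC(spectrum$absorbance, digits = 6, format = "g"))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Resample a spectrum onto a new grid
#'
#' Linear interpolation; values at grid points shared with the source
#' grid are returned unchanged. By default the target grid must lie
#' within the source range (no extrapolation).
#'
#' @param spectrum a spectrum.
#' @param grid target wavelength grid (nm), strictly increasing.
#' @param extrapolate if `TRUE`, wavelengths outside the source range are
#'   clamped to the nearest edge value instead of raising an error.
#' @return A spectrum on `grid`.
#' @export
resample <- function(spectrum, grid, extrapolate = FALSE) {
  stopifnot(inherits(spectrum, "spectrum"))
  grid <- as.numeric(grid)
  rng <- range(spectrum$wavelength)
  if (!extrapolate && (min(grid) < rng[1] || max(grid) > rng[2])) {
    stop(sprintf(
      "target grid [%g, %g] outside source range [%g, %g]; set extrapolate = TRUE to clamp",
      min(grid), max(grid), rng[1], rng[2]))
  }
  ab <- stats::approx(spectrum$wavelength, spectrum$absorbance,
                      xout = grid, method = "linear", rule = 2)$y
  out <- new_spectrum(grid, ab, spectrum$label)
  if (inherits(spectrum, "difference_spectrum")) {
    out <- as_difference(out, attr(spectrum, "convention"))
  }
  out
}

as_difference <- function(spectrum, convention) {
  convention <- match.arg(convention,
                          c("after_minus_before", "before_minus_after"))
  class(spectrum) <- c("difference_spectrum", "spectrum")
  attr(spectrum, "convention") <- convention
  spectrum
}

#' Photoconversion difference spectrum
#'
#' Pointwise subtraction `after - before`, tagged with the explicit sign
#' convention `"after_minus_before"`. Spectra on different grids are
#' resampled onto the intersection of their ranges (the `after` grid
#' restricted to the overlap) before subtraction.
#'
#' @param after spectrum measured after irradiation.
#' @param before spectrum measured before irradiation.
#' @return A `"difference_spectrum"` (subclass of `"spectrum"`) with
#'   attribute `convention = "after_minus_before"`.
#' @export
difference <- function(after, before) {
  stopifnot(inherits(after, "spectrum"), inherits(before, "spectrum"))
  lo <- max(min(after$wavelength), min(before$wavelength))
  hi <- min(max(after$wavelength), max(before$wavelength))
  if (lo >= hi) stop("spectra have disjoint wavelength ranges")
  grid <- after$wavelength[after$wavelength >= lo & after$wavelength <= hi]
  if (length(grid) < 2) stop("spectra have disjoint wavelength ranges")
  a <- resample(after, grid)
  b <- resample(before, grid)
  d <- new_spectrum(grid, a$absorbance - b$absorbance,
                    label = sprintf("%s - %s", after$label, before$label))
  as_difference(d, "after_minus_before")
}

#' Flip the sign convention of a difference spectrum
#'
#' @param diff a difference spectrum.
#' @return The negated difference spectrum with the opposite convention tag.
#' @export
flip_convention <- function(diff) {
  stopifnot(inherits(diff, "difference_spectrum"))
  conv <- attr(diff, "convention")
  out <- new_spectrum(diff$wavelength, -diff$absorbance, diff$label)
  as_difference(out, setdiff(c("after_minus_before", "before_minus_after"),
                             conv))
}

#' Normalize a difference spectrum at an extremum
#'
#' Rescales so that the absolute value at the selected extremum equals
#' 1.0, the convention used when overlaying difference spectra from
#' different preparations.
#'
#' @param diff a difference spectrum (plain spectra are also accepted).
#' @param which `"negative_max"` (the most negative point) or
#'   `"positive_max"`.
#' @return The scaled spectrum, with the applied scale factor in
#'   attribute `"scale"` (old values times `scale` give the new ones).
#' @export
normalize_at_extremum <- function(diff, which = c("negative_max", "positive_max")) {
  which <- match.arg(which)
  stopifnot(inherits(diff, "spectrum"))
  if (all(diff$absorbance == 0)) {
    stop("degenerate input: all-zero difference spectrum cannot be normalized")
  }
  ext <- if (which == "negative_max") min(diff$absorbance) else max(diff$absorbance)
  if (ext == 0 || (which == "negative_max" && ext > 0) ||
      (which == "positive_max" && ext < 0)) {
    stop(sprintf("selected extremum (%s) is not present or zero", which))
  }
  scale <- 1 / abs(ext)
  out <- diff
  out$absorbance <- diff$absorbance * scale
  attr(out, "scale") <- scale
  out
}
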