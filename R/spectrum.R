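#' Construct an XAS spectrum
#'
#' The basic currency of the package: an absorption (or difference) spectrum
#' on a strictly increasing energy grid in absolute eV. Intensities are in
#' arbitrary units and may be negative (difference spectra); energies and
#' intensities must be finite and of equal length.
#'
#' @param energies Numeric vector of energies (eV), strictly increasing.
#' @param intensities Numeric vector of intensities, same length.
#' @param meta Named list of free-form labels. Conventional keys are
#'   `state` (`"S1"`, `"S2"` or `"unknown"`), `treatment` (`"native"`,
#'   `"NH3"` or `"synthetic"`) and `provenance`.
#' @return An object of class `"xas_spectrum"`.
#' @examples
#' s <- xas_spectrum(seq(6535, 6545, by = 0.1), rexp(101))
#' s
#' @export
xas_spectrum <- function(energies, intensities, meta = list()) {
  energies <- as.numeric(energies)
  intensities <- as.numeric(intensities)
  if (length(energies) != length(intensities))
    stop("energies and intensities must have equal length")
  if (length(energies) < 1L) stop("spectrum must contain at least one point")
  if (!all(is.finite(energies)) || !all(is.finite(intensities)))
    stop("all energies and intensities must be finite")
  if (length(energies) > 1L && any(diff(energies) <= 0))
    stop("energies must be strictly increasing")
  if (!is.list(meta)) stop("meta must be a list")
  structure(list(energies = energies, intensities = intensities, meta = meta),
            class = "xas_spectrum")
}

#' @export
print.xas_spectrum <- function(x, ...) {
  cat(sprintf("<xas_spectrum> %d points, %.2f-%.2f eV\n",
              length(x$energies), min(x$energies), max(x$energies)))
  lab <- x$meta[vapply(x$meta, function(v) is.character(v) || is.numeric(v), TRUE)]
  if (length(lab))
    cat("  meta:", paste(names(lab), unlist(lab), sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
format.xas_spectrum <- function(x, ...) {
  sprintf("<xas_spectrum> %d pts [%.2f, %.2f] eV", length(x$energies),
          min(x$energies), max(x$energies))
}

is_xas_spectrum <- function(x) inherits(x, "xas_spectrum")

#' Resample a spectrum onto a new energy grid
#'
#' Piecewise-linear interpolation onto `grid`. No extrapolation is ever
#' performed: every grid point must lie within the span of the input.
#'
#' @param s An [xas_spectrum()].
#' @param grid Strictly increasing numeric vector of energies (eV) inside
#'   the span of `s`.
#' @return An `xas_spectrum` on `grid`; metadata is preserved.
#' @export
resample <- function(s, grid) {
  stopifnot(is_xas_spectrum(s))
  grid <- as.numeric(grid)
  if (any(!is.finite(grid))) stop("grid must be finite")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  span <- range(s$energies)
  if (min(grid) < span[1] || max(grid) > span[2])
    stop(sprintf("grid [%g, %g] outside spectrum span [%g, %g]: extrapolation is not supported",
                 min(grid), max(grid), span[1], span[2]))
  y <- stats::approx(s$energies, s$intensities, xout = grid, method = "linear",
                     ties = "ordered")$y
  xas_spectrum(grid, y, s$meta)
}

#' Boxcar (moving-average) binning
#'
#' Centred moving average with an odd window; at the edges the window is
#' truncated to the available points (e.g. `c(0,1,2,3,4)` with `window = 3`
#' becomes `c(0.5, 1, 2, 3, 3.5)`). The energy grid is unchanged, so binned
#' and raw spectra stay directly comparable.
#'
#' @param s An [xas_spectrum()].
#' @param window Odd positive integer, at most the number of points.
#' @return The binned `xas_spectrum`.
#' @export
boxcar_bin <- function(s, window) {
  stopifnot(is_xas_spectrum(s))
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L)
    stop("window must be a positive integer")
  if (window %% 2L == 0L) stop("window must be odd")
  n <- length(s$intensities)
  if (window > n) stop("window larger than the spectrum")
  h <- (window - 1L) %/% 2L
  if (h == 0L) return(s)
  # cumulative-sum trick: mean over [max(1, i-h), min(n, i+h)]
  cs <- c(0, cumsum(s$intensities))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  y <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  xas_spectrum(s$energies, y, s$meta)
}

#' Trapezoidal area of a spectrum over an energy region
#'
#' Integrates the intensities by the trapezoid rule on the native grid.
#' Region endpoints falling between grid points are included by linear
#' interpolation.
#'
#' @param s An [xas_spectrum()].
#' @param region Numeric length-2 vector `c(lo, hi)` in eV, `lo < hi`, inside
#'   the span of `s`.
#' @return The integral (intensity x eV), a scalar.
#' @export
spec_area <- function(s, region) {
  stopifnot(is_xas_spectrum(s))
  region <- as.numeric(region)
  if (length(region) != 2L || !all(is.finite(region)))
    stop("region must be c(lo, hi)")
  if (region[1] >= region[2]) stop("region must satisfy lo < hi")
  span <- range(s$energies)
  if (region[1] < span[1] || region[2] > span[2])
    stop("region outside the spectrum span")
  inner <- s$energies[s$energies > region[1] & s$energies < region[2]]
  x <- c(region[1], inner, region[2])
  y <- stats::approx(s$energies, s$intensities, xout = x, ties = "ordered")$y
  pracma::trapz(x, y)
}

#' Scale a spectrum so a region integrates to a target area
#'
#' Multiplies all intensities by `target_area / spec_area(s, region)`. This is
#' the area-normalisation step used to put pre-edge scans of different samples
#' on a common intensity scale; the operation is idempotent.
#'
#' @inheritParams spec_area
#' @param target_area Positive scalar; the area the region should have after
#'   scaling.
#' @return The rescaled `xas_spectrum`; `meta$normalized_area` records the
#'   target.
#' @export
area_normalize <- function(s, region, target_area = 1) {
  if (!is.numeric(target_area) || length(target_area) != 1L || target_area <= 0)
    stop("target_area must be a positive scalar")
  a <- spec_area(s, region)
  if (a <= 0) stop(sprintf("region area is %g; cannot normalize a non-positive area", a))
  out <- xas_spectrum(s$energies, s$intensities * (target_area / a), s$meta)
  out$meta$normalized_area <- target_area
  out
}

#' Pointwise difference of two spectra
#'
#' Computes `a - b`. If the grids differ, `b` is first resampled onto the grid
#' of `a` (which must lie inside the span of `b`). The result is a difference
#' spectrum and may be negative.
#'
#' @param a,b [xas_spectrum()] objects.
#' @return An `xas_spectrum` on the grid of `a`, carrying `a`'s metadata plus
#'   `kind = "difference"`.
#' @export
subtract_spectra <- function(a, b) {
  stopifnot(is_xas_spectrum(a), is_xas_spectrum(b))
  if (!isTRUE(all.equal(a$energies, b$energies, tolerance = 1e-12))) {
    if (min(a$energies) < min(b$energies) || max(a$energies) > max(b$energies))
      stop("grids do not overlap over the full span of the first spectrum")
    b <- resample(b, a$energies)
  }
  meta <- a$meta
  meta$kind <- "difference"
  xas_spectrum(a$energies, a$intensities - b$intensities, meta)
}

#' Pointwise sum of several spectra
#'
#' Used to combine the four per-site calculated spectra (Mn1-Mn4) into one
#' model spectrum. All spectra must share one grid; spectra on different grids
#' are resampled onto the grid of the first.
#'
#' @param parts Non-empty list of [xas_spectrum()] objects.
#' @return The summed `xas_spectrum` (metadata of the first part).
#' @export
sum_spectra <- function(parts) {
  if (!is.list(parts) || length(parts) == 0L)
    stop("parts must be a non-empty list of spectra")
  if (!all(vapply(parts, is_xas_spectrum, TRUE)))
    stop("all parts must be xas_spectrum objects")
  ref <- parts[[1L]]
  y <- ref$intensities
  for (p in parts[-1L]) {
    if (!isTRUE(all.equal(ref$energies, p$energies, tolerance = 1e-12)))
      p <- resample(p, ref$energies)
    y <- y + p$intensities
  }
  xas_spectrum(ref$energies, y, ref$meta)
}
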