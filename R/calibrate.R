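#' Global calibration parameters for calculated spectra
#'
#' TD-DFT transition energies carry a large systematic offset and their
#' intensities an arbitrary unit; a single global energy shift (added to the
#' calculated energies) and intensity scale (multiplying the calculated
#' intensities) maps every calculated spectrum onto the experimental axis.
#' The calibration is fitted once against the untreated reference and then
#' applied unchanged to every candidate model, so that models are compared on
#' a common footing.
#'
#' @param shift Energy shift (eV).
#' @param scale Intensity scale, > 0.
#' @return An object of class `"xas_calibration"`.
#' @export
xas_calibration <- function(shift, scale) {
  if (!is.numeric(shift) || length(shift) != 1L || !is.finite(shift))
    stop("shift must be a finite scalar (eV)")
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) || scale <= 0)
    stop("scale must be a positive scalar")
  structure(list(shift = shift, scale = scale), class = "xas_calibration")
}

#' @export
print.xas_calibration <- function(x, ...) {
  cat(sprintf("<xas_calibration> shift %+.4g eV, scale %.4g\n", x$shift, x$scale))
  invisible(x)
}

#' Invert a calibration
#'
#' @param p An [xas_calibration()].
#' @return The inverse calibration `(-shift, 1/scale)`.
#' @export
invert_calibration <- function(p) {
  stopifnot(inherits(p, "xas_calibration"))
  xas_calibration(-p$shift, 1 / p$scale)
}

#' Apply a calibration to a spectrum, stick spectrum or model
#'
#' Adds `p$shift` to all energies and multiplies all intensities by
#' `p$scale`. For a [model_entry()] the calibration is applied to all four
#' site stick spectra.
#'
#' @param x An [xas_spectrum()], [stick_spectrum()] or [model_entry()].
#' @param p An [xas_calibration()].
#' @return An object of the same class as `x`.
#' @export
apply_calibration <- function(x, p) {
  stopifnot(inherits(p, "xas_calibration"))
  UseMethod("apply_calibration")
}

#' @export
apply_calibration.xas_spectrum <- function(x, p) {
  meta <- x$meta
  meta$calibration <- c(shift = p$shift, scale = p$scale)
  xas_spectrum(x$energies + p$shift, x$intensities * p$scale, meta)
}

#' @export
apply_calibration.stick_spectrum <- function(x, p) {
  stick_spectrum(x$site, x$energies + p$shift, x$intensities * p$scale)
}

#' @export
apply_calibration.model_entry <- function(x, p) {
  model_entry(x$model_id, lapply(x$sites, apply_calibration, p = p),
              x$binding_mode_class)
}

#' Fit the global shift/scale calibration against a reference spectrum
#'
#' Minimises the root-mean-square residual between the shifted-and-scaled
#' calculated spectrum and the experimental reference over `region`. The
#' search is deterministic: a coarse grid scan over the shift (step
#' `coarse_step`, default 0.05 eV) with the optimal scale at each shift given
#' in closed form by least squares,
#' `scale* = sum(y_exp * y_calc) / sum(y_calc^2)` on the common grid,
#' followed by golden-section refinement of the shift around the best grid
#' node.
#'
#' @param calc Calculated [xas_spectrum()] (un-calibrated axis).
#' @param exp_ref Experimental reference [xas_spectrum()].
#' @param region `c(lo, hi)` (eV) on the experimental axis over which the
#'   residual is evaluated.
#' @param shift_bounds `c(lo, hi)` (eV) search interval for the shift;
#'   `calc` must still span `region` after any shift in bounds.
#' @param coarse_step Grid-scan step (eV).
#' @param transform Optional function applied to the shifted calculated
#'   spectrum (an `xas_spectrum` on the experimental axis) before the
#'   residual is evaluated. Passing the same processing operator the
#'   experimental reference went through (e.g. background removal) makes the
#'   two branches commensurable and removes processing-induced bias from the
#'   fitted parameters.
#' @return An [xas_calibration()] with attributes `rms` (residual at the
#'   optimum) and `region`.
#' @export
fit_calibration <- function(calc, exp_ref, region = c(6538, 6544.5),
                            shift_bounds = c(30, 40), coarse_step = 0.05,
                            transform = NULL) {
  stopifnot(is_xas_spectrum(calc), is_xas_spectrum(exp_ref))
  if (shift_bounds[1] >= shift_bounds[2]) stop("shift_bounds must be c(lo, hi)")
  sel <- exp_ref$energies >= region[1] & exp_ref$energies <= region[2]
  if (sum(sel) < 2L) stop("reference spectrum has too few points inside region")
  xe <- exp_ref$energies[sel]; ye <- exp_ref$intensities[sel]
  span <- range(calc$energies)
  if (span[1] + shift_bounds[1] > region[1] || span[2] + shift_bounds[2] < region[2])
    stop("calculated spectrum cannot span the region for every shift in bounds")
  scale_rms <- function(shift) {
    if (is.null(transform)) {
      yc <- stats::approx(calc$energies + shift, calc$intensities, xout = xe,
                          ties = "ordered")$y
    } else {
      shifted <- xas_spectrum(calc$energies + shift, calc$intensities)
      proc <- transform(shifted)
      yc <- stats::approx(proc$energies, proc$intensities, xout = xe,
                          ties = "ordered")$y
    }
    if (anyNA(yc)) return(list(scale = NA_real_, rms = Inf))
    d <- sum(yc * yc)
    if (d <= 0) return(list(scale = NA_real_, rms = Inf))
    sc <- sum(ye * yc) / d
    list(scale = sc, rms = sqrt(mean((sc * yc - ye)^2)))
  }
  shifts <- seq(shift_bounds[1], shift_bounds[2], by = coarse_step)
  rms <- vapply(shifts, function(s) scale_rms(s)$rms, 0)
  if (!any(is.finite(rms)))
    stop("degenerate calculated spectrum: no shift gives signal inside the region")
  best <- shifts[which.min(rms)]
  lo <- max(shift_bounds[1], best - coarse_step)
  hi <- min(shift_bounds[2], best + coarse_step)
  opt <- stats::optimize(function(s) scale_rms(s)$rms, c(lo, hi), tol = 1e-8)
  shift <- opt$minimum
  sr <- scale_rms(shift)
  if (!is.finite(sr$rms) || !is.finite(sr$scale) || sr$scale <= 0)
    stop("calibration fit failed: degenerate scale at the optimal shift")
  out <- xas_calibration(shift, sr$scale)
  attr(out, "rms") <- sr$rms
  attr(out, "region") <- region
  out
}
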