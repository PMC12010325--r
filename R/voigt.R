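# Faddeeva function w(z) = exp(-z^2) erfc(-iz) on the closed upper half-plane,
# by Weideman's rational approximation (SIAM J. Numer. Anal. 31, 1994) with
# N = 64 terms; relative accuracy ~1e-13 uniformly for Im(z) >= 0.
.faddeeva_env <- new.env(parent = emptyenv())

faddeeva_coef <- function(N = 64L) {
  M <- 2L * N; M2 <- 2L * M
  k <- seq(-M + 1L, M - 1L)
  L <- sqrt(N / sqrt(2))
  theta <- k * pi / M
  t <- L * tan(theta / 2)
  f <- c(0, exp(-t^2) * (L^2 + t^2))
  a <- Re(stats::fft(f[c((M + 1L):M2, 1L:M)])) / M2  # fftshift then FFT
  list(a = rev(a[2:(N + 1L)]), L = L)
}

faddeeva_w <- function(z) {
  if (is.null(.faddeeva_env$coef)) .faddeeva_env$coef <- faddeeva_coef(64L)
  cf <- .faddeeva_env$coef
  L <- cf$L
  Z <- (L + 1i * z) / (L - 1i * z)
  p <- 0 + 0i
  for (ak in cf$a) p <- p * Z + ak
  2 * p / (L - 1i * z)^2 + (1 / sqrt(pi)) / (L - 1i * z)
}

#' Construct a Voigt peak
#'
#' One component of the pre-edge deconvolution: a Voigt profile (convolution
#' of a Gaussian of standard deviation `sigma` with a Lorentzian of half-width
#' `gamma`), with `amplitude` equal to its integrated area. Either width may
#' be zero (degenerating to a pure Lorentzian or Gaussian) but not both.
#'
#' @param center Peak centre (eV).
#' @param sigma Gaussian standard deviation (eV), >= 0.
#' @param gamma Lorentzian half-width at half maximum (eV), >= 0.
#' @param amplitude Integrated peak area, >= 0.
#' @return An object of class `"voigt_peak"`.
#' @export
voigt_peak <- function(center, sigma, gamma, amplitude) {
  vals <- c(center = center, sigma = sigma, gamma = gamma, amplitude = amplitude)
  if (!all(is.finite(vals))) stop("all Voigt parameters must be finite")
  if (sigma < 0 || gamma < 0) stop("sigma and gamma must be non-negative")
  if (sigma + gamma <= 0) stop("sigma + gamma must be positive")
  if (amplitude < 0) stop("amplitude must be non-negative")
  structure(as.list(vals), class = "voigt_peak")
}

#' Evaluate a Voigt peak
#'
#' Computes `amplitude` times the unit-area Voigt density at the energies `E`,
#' via the Faddeeva function `w(z)` with `z = ((E - center) + i gamma) /
#' (sigma sqrt(2))`. The degenerate limits `gamma = 0` (Gaussian) and
#' `sigma = 0` (Lorentzian) are evaluated in closed form.
#'
#' @param E Numeric vector of energies (eV).
#' @param p A [voigt_peak()].
#' @return Numeric vector of intensities.
#' @export
voigt_value <- function(E, p) {
  stopifnot(inherits(p, "voigt_peak"))
  E <- as.numeric(E)
  if (p$sigma == 0)
    return(p$amplitude * (p$gamma / pi) / ((E - p$center)^2 + p$gamma^2))
  if (p$gamma == 0)
    return(p$amplitude * stats::dnorm(E, p$center, p$sigma))
  z <- ((E - p$center) + 1i * p$gamma) / (p$sigma * sqrt(2))
  p$amplitude * Re(faddeeva_w(z)) / (p$sigma * sqrt(2 * pi))
}

#' Construct a Voigt peak set
#'
#' The result of (or initial guess for) a multi-peak deconvolution: peaks are
#' stored sorted by centre, with the fit region and the root-mean-square
#' residual of the fit.
#'
#' @param peaks List of [voigt_peak()] objects.
#' @param fit_region Optional `c(lo, hi)` (eV) over which the fit was done.
#' @param residual_rms RMS of the fit residual (>= 0).
#' @param converged Logical convergence flag.
#' @param message Optimiser diagnostic string.
#' @param baseline Linear residual-baseline coefficients `c(a, b)`:
#'   `a + b * (E - baseline_origin)` is added to the peak sum (absorbs any
#'   smooth remnant the edge-background stage left behind). Default none.
#' @param baseline_origin Energy origin (eV) of the baseline term.
#' @return An object of class `"voigt_peakset"`.
#' @export
voigt_peakset <- function(peaks, fit_region = NULL, residual_rms = 0,
                          converged = TRUE, message = "",
                          baseline = c(0, 0), baseline_origin = 0) {
  if (!is.list(peaks) || (length(peaks) && !all(vapply(peaks, inherits, TRUE, "voigt_peak"))))
    stop("peaks must be a (possibly empty) list of voigt_peak objects")
  if (residual_rms < 0) stop("residual_rms must be non-negative")
  if (length(peaks))
    peaks <- peaks[order(vapply(peaks, `[[`, 0, "center"))]
  stopifnot(is.numeric(baseline), length(baseline) == 2L)
  structure(list(peaks = peaks, fit_region = fit_region,
                 residual_rms = residual_rms, converged = converged,
                 message = message, baseline = baseline,
                 baseline_origin = baseline_origin),
            class = "voigt_peakset")
}

#' @export
print.voigt_peakset <- function(x, ...) {
  cat(sprintf("<voigt_peakset> %d peaks, residual RMS %.4g%s\n", length(x$peaks),
              x$residual_rms, if (x$converged) "" else " [NOT CONVERGED]"))
  for (p in x$peaks)
    cat(sprintf("  center %8.3f eV  sigma %6.4f  gamma %6.4f  area %8.4g\n",
                p$center, p$sigma, p$gamma, p$amplitude))
  invisible(x)
}

#' Reconstruct the fitted spectrum from a peak set
#'
#' Sums [voigt_value()] over all peaks on `grid`. This noise-free
#' reconstruction is what downstream difference-spectrum construction
#' consumes, so that subtracting two spectra does not amplify noise.
#'
#' @param p A [voigt_peakset()]; an empty set gives the zero spectrum.
#' @param grid Strictly increasing energy grid (eV).
#' @param include_baseline Include the fitted linear baseline term (default
#'   `TRUE`). With `FALSE` only the peak sum is returned: the peaks-only
#'   reconstruction is the cleanest estimate of the pre-edge signal itself,
#'   since the baseline holds whatever smooth remnant the edge-background
#'   stage left behind.
#' @return An `xas_spectrum`.
#' @export
evaluate_peakset <- function(p, grid, include_baseline = TRUE) {
  stopifnot(inherits(p, "voigt_peakset"))
  grid <- as.numeric(grid)
  bl <- if (!include_baseline || is.null(p$baseline)) c(0, 0) else p$baseline
  y <- bl[1L] + bl[2L] * (grid - (p$baseline_origin %||% 0))
  for (pk in p$peaks) y <- y + voigt_value(grid, pk)
  xas_spectrum(grid, y, list(kind = "voigt_reconstruction"))
}

# flatten / unflatten peak parameters for the optimiser
.peaks_to_par <- function(peaks) {
  unlist(lapply(peaks, function(p) c(p$center, p$sigma, p$gamma, p$amplitude)))
}
.par_to_peaks <- function(par) {
  lapply(seq_len(length(par) %/% 4L), function(i) {
    q <- par[(4L * (i - 1L) + 1L):(4L * i)]
    voigt_peak(q[1], max(q[2], 0), max(q[3], 0), max(q[4], 0))
  })
}

#' Fit a sum of Voigt peaks to a background-corrected spectrum
#'
#' Bounded Levenberg-Marquardt least squares (via [minpack.lm::nls.lm()]) over
#' `{center, sigma, gamma, amplitude}` per peak. The fit is deterministic:
#' with no `init`, centres start equally spaced across the fit region, both
#' widths at 0.3 eV, and amplitudes from the local spectrum height; there are
#' no random restarts. Centres are bounded to the fit region, Gaussian
#' widths to `[width_floor, Inf)` and amplitudes to `[0, Inf)`.
#'
#' @param s A background-corrected [xas_spectrum()].
#' @param n_peaks Number of Voigt components (default 3).
#' @param init Optional [voigt_peakset()] initial guess (overrides `n_peaks`).
#' @param fit_region `c(lo, hi)` (eV); defaults to the spectrum span.
#' @param max_iter Maximum optimiser iterations.
#' @param width_floor Lower bound (eV) on the Gaussian sigma of every
#'   component (default 0.05). Keeps the fit from chasing single noise
#'   points with needle-thin peaks; set it below the narrowest physical
#'   feature expected (instrumental resolution is ~0.3 eV sigma).
#' @param baseline If `TRUE`, a free linear baseline is fitted together with
#'   the peaks. The peak sum is bounded below by zero, so it cannot follow a
#'   background-subtraction remnant that dips negative; the baseline term
#'   absorbs such remnants instead of biasing the peaks.
#' @param fix_widths If `TRUE` (requires `init`), sigma and gamma of every
#'   component are frozen at their `init` values and only centres,
#'   amplitudes (and the baseline) are refined. Fitting a treated spectrum
#'   with the line widths of the native fit constrains the difference of the
#'   two reconstructions to the low-dimensional family of amplitude and
#'   position changes, which both suppresses noise and mirrors how paired
#'   difference spectra are analysed.
#' @return A [voigt_peakset()] with `residual_rms`, `converged` and the
#'   optimiser `message`. Non-convergence is flagged (with a warning), never
#'   silent.
#' @export
fit_voigt_peaks <- function(s, n_peaks = 3L, init = NULL, fit_region = NULL,
                            max_iter = 400L, width_floor = 0.05,
                            baseline = FALSE, fix_widths = FALSE) {
  stopifnot(is_xas_spectrum(s))
  if (is.null(fit_region)) fit_region <- range(s$energies)
  sel <- s$energies >= fit_region[1] & s$energies <= fit_region[2]
  x <- s$energies[sel]; y <- s$intensities[sel]
  if (length(x) < 8L) stop("too few points inside fit_region")
  if (!is.null(init)) {
    stopifnot(inherits(init, "voigt_peakset"))
    peaks0 <- init$peaks
    n_peaks <- length(peaks0)
  } else {
    n_peaks <- as.integer(n_peaks)
    if (n_peaks < 1L) stop("n_peaks must be >= 1")
    centers <- fit_region[1] + diff(fit_region) * seq_len(n_peaks) / (n_peaks + 1)
    unit_height <- voigt_value(0, voigt_peak(0, 0.3, 0.3, 1))
    h <- stats::approx(x, y, xout = centers, ties = "ordered")$y
    amp <- pmax(h, 1e-3 * max(abs(y))) / unit_height
    peaks0 <- lapply(seq_len(n_peaks),
                     function(i) voigt_peak(centers[i], 0.3, 0.3, amp[i]))
  }
  par0 <- .peaks_to_par(peaks0)
  lower <- rep(c(fit_region[1], width_floor, 0, 0), n_peaks)
  upper <- rep(c(fit_region[2], Inf, Inf, Inf), n_peaks)
  par0 <- pmin(pmax(par0, lower), upper)
  origin <- mean(fit_region)
  if (baseline) {
    par0 <- c(par0, min(y), 0)
    lower <- c(lower, -Inf, -Inf)
    upper <- c(upper, Inf, Inf)
  }
  np <- 4L * n_peaks
  if (fix_widths && is.null(init))
    stop("fix_widths requires an init peak set")
  free <- rep(TRUE, length(par0))
  if (fix_widths)  # per peak: centre free, sigma/gamma frozen, amplitude free
    free[seq_len(np)] <- rep(c(TRUE, FALSE, FALSE, TRUE), n_peaks)
  template <- par0
  expand <- function(parf) { full <- template; full[free] <- parf; full }
  resid_fn_full <- function(par) {
    yhat <- if (baseline) par[np + 1L] + par[np + 2L] * (x - origin) else rep(0, length(x))
    for (pk in .par_to_peaks(par[seq_len(np)])) yhat <- yhat + voigt_value(x, pk)
    yhat - y
  }
  # nls.lm emits its own warning on maxiter; we raise a structured one below
  fit <- suppressWarnings(
    minpack.lm::nls.lm(par = par0[free], lower = lower[free],
                       upper = upper[free],
                       fn = function(parf) resid_fn_full(expand(parf)),
                       control = minpack.lm::nls.lm.control(
                         maxiter = max_iter, maxfev = 100L * max_iter,
                         ftol = 1e-12, ptol = 1e-12)))
  converged <- fit$info %in% c(1L, 2L, 3L, 4L)
  if (!converged)
    warning(sprintf("Voigt fit did not converge: %s", fit$message))
  par_full <- expand(fit$par)
  r <- resid_fn_full(par_full)
  voigt_peakset(.par_to_peaks(par_full[seq_len(np)]), fit_region = fit_region,
                residual_rms = sqrt(mean(r^2)), converged = converged,
                message = fit$message,
                baseline = if (baseline) par_full[np + 1:2] else c(0, 0),
                baseline_origin = if (baseline) origin else 0)
}
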