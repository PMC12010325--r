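# Independent oracles and small fixture builders used across the suite.

# random spectrum on a sorted random grid
random_spectrum <- function(n = 20L, e_range = c(6535, 6545)) {
  e <- sort(stats::runif(n, e_range[1], e_range[2]))
  while (any(diff(e) <= 0)) e <- sort(stats::runif(n, e_range[1], e_range[2]))
  xas_spectrum(e, stats::rnorm(n))
}

# brute-force two-point linear interpolation, coded independently of approx()
interp_oracle <- function(x, y, q) {
  vapply(q, function(qi) {
    j <- max(which(x <= qi))
    if (x[j] == qi) return(y[j])
    w <- (qi - x[j]) / (x[j + 1L] - x[j])
    (1 - w) * y[j] + w * y[j + 1L]
  }, 0)
}

# fine Riemann-sum integral of a piecewise-linear spectrum over a region
riemann_area_oracle <- function(s, region, n = NULL) {
  if (is.null(n)) n <- 100L * length(s$energies)
  h <- diff(region) / n
  mid <- region[1] + (seq_len(n) - 0.5) * h
  sum(stats::approx(s$energies, s$intensities, xout = mid)$y) * h
}

# numerical Gaussian (x) Lorentzian convolution on a fine grid
voigt_convolution_oracle <- function(x, center, sigma, gamma,
                                     span = 60, step = 5e-4) {
  t <- seq(-span, span, by = step)
  g <- stats::dnorm(t, 0, sigma)
  vapply(x, function(xi)
    sum(g * (gamma / pi) / ((xi - center - t)^2 + gamma^2)) * step, 0)
}

# a three-band pre-edge-like spectrum built from explicit Voigt peaks
three_peak_spectrum <- function(grid, centers = c(6539.5, 6541.3, 6543.2),
                                sigma = 0.35, gamma = 0.25,
                                amps = c(12, 20, 9)) {
  peaks <- lapply(seq_along(centers),
                  function(i) voigt_peak(centers[i], sigma, gamma, amps[i]))
  list(peaks = voigt_peakset(peaks),
       spectrum = evaluate_peakset(voigt_peakset(peaks), grid))
}
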