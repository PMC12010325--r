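SITE_LABELS <- c("Mn1", "Mn2", "Mn3", "Mn4")

#' Construct a stick spectrum
#'
#' A list of discrete calculated transitions (energy, intensity) for one Mn
#' site, as summarised from upstream electronic-structure (TD-DFT) output.
#' Transitions are sorted by energy; intensities are oscillator-strength-like
#' and must be non-negative.
#'
#' @param site Site label, one of `"Mn1"`, `"Mn2"`, `"Mn3"`, `"Mn4"`.
#' @param energies Transition energies (eV).
#' @param intensities Non-negative transition intensities (arbitrary units).
#' @return An object of class `"stick_spectrum"`.
#' @export
stick_spectrum <- function(site, energies, intensities) {
  site <- as.character(site)
  if (length(site) != 1L || !(site %in% SITE_LABELS))
    stop(sprintf("site must be one of %s", paste(SITE_LABELS, collapse = ", ")))
  energies <- as.numeric(energies)
  intensities <- as.numeric(intensities)
  if (length(energies) != length(intensities))
    stop("energies and intensities must have equal length")
  if (!all(is.finite(energies)) || !all(is.finite(intensities)))
    stop("transition energies and intensities must be finite")
  if (any(intensities < 0)) stop("stick intensities must be non-negative")
  o <- order(energies)
  structure(list(site = site, energies = energies[o], intensities = intensities[o]),
            class = "stick_spectrum")
}

#' @export
print.stick_spectrum <- function(x, ...) {
  cat(sprintf("<stick_spectrum> site %s, %d transitions", x$site, length(x$energies)))
  if (length(x$energies))
    cat(sprintf(" in [%.2f, %.2f] eV", min(x$energies), max(x$energies)))
  cat("\n")
  invisible(x)
}

is_stick_spectrum <- function(x) inherits(x, "stick_spectrum")

#' Define a broadening kernel
#'
#' Unit-area line-shape applied to each calculated transition when a stick
#' spectrum is turned into a continuous curve. The Gaussian default with
#' 1.0 eV FWHM reflects the combined instrumental resolution (~0.7 eV for a
#' HERFD spectrometer) and residual lifetime broadening; the width is a free
#' parameter and every ranking report records the value used.
#'
#' @param shape `"gaussian"`, `"lorentzian"` or `"pseudo_voigt"`.
#' @param fwhm Full width at half maximum (eV), > 0.
#' @param mixing Lorentzian fraction in `[0, 1]` (pseudo-Voigt only).
#' @return An object of class `"broadening_kernel"`.
#' @export
broadening_kernel <- function(shape = c("gaussian", "lorentzian", "pseudo_voigt"),
                              fwhm = 1.0, mixing = 0.5) {
  shape <- match.arg(shape)
  if (!is.numeric(fwhm) || length(fwhm) != 1L || !is.finite(fwhm) || fwhm <= 0)
    stop("fwhm must be a positive scalar (eV)")
  if (!is.numeric(mixing) || length(mixing) != 1L || mixing < 0 || mixing > 1)
    stop("mixing must lie in [0, 1]")
  structure(list(shape = shape, fwhm = fwhm, mixing = mixing),
            class = "broadening_kernel")
}

# unit-area kernel density at offsets x from the line centre
kernel_profile <- function(kernel, x) {
  stopifnot(inherits(kernel, "broadening_kernel"))
  sg <- kernel$fwhm / (2 * sqrt(2 * log(2)))
  hw <- kernel$fwhm / 2
  switch(kernel$shape,
    gaussian     = stats::dnorm(x, 0, sg),
    lorentzian   = (hw / pi) / (x^2 + hw^2),
    pseudo_voigt = kernel$mixing * (hw / pi) / (x^2 + hw^2) +
                   (1 - kernel$mixing) * stats::dnorm(x, 0, sg))
}

#' Broaden a stick spectrum into a continuous curve
#'
#' Each transition contributes `intensity` times the unit-area kernel centred
#' at its energy, evaluated on `grid`. Because the kernel has unit area, the
#' integral of the curve over a region enclosing all sticks equals the total
#' stick intensity (up to grid-resolution error); a grid step of at most
#' `fwhm / 10` keeps that error below 1e-4 relative.
#'
#' @param sticks A [stick_spectrum()]. An empty transition list yields the
#'   zero spectrum.
#' @param kernel A [broadening_kernel()].
#' @param grid Strictly increasing energy grid (eV); should span the sticks
#'   by about 5 FWHM on each side if intensity conservation matters.
#' @return An `xas_spectrum` on `grid` with `meta$site` set.
#' @export
broaden_sticks <- function(sticks, kernel, grid) {
  stopifnot(is_stick_spectrum(sticks), inherits(kernel, "broadening_kernel"))
  grid <- as.numeric(grid)
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  if (length(sticks$energies) == 0L)
    return(xas_spectrum(grid, rep(0, length(grid)), list(site = sticks$site)))
  # rows: grid points, cols: transitions
  offs <- outer(grid, sticks$energies, "-")
  y <- as.vector(kernel_profile(kernel, offs) %*% sticks$intensities)
  xas_spectrum(grid, y, list(site = sticks$site,
                             kernel = kernel$shape, fwhm = kernel$fwhm))
}

#' Construct a candidate structural model entry
#'
#' A candidate model of the (possibly ligand-bound) Mn4CaO5 cluster is
#' represented by its four per-site stick spectra plus a binding-mode class
#' label (e.g. O5-substitution, W1-substitution, W2-substitution,
#' Mn4-addition, Mn1-addition).
#'
#' @param model_id Unique model label (e.g. `"C2"`).
#' @param sites List of exactly four [stick_spectrum()] objects covering
#'   Mn1-Mn4 (any order; stored named by site).
#' @param binding_mode_class Free-form class label.
#' @return An object of class `"model_entry"`.
#' @export
model_entry <- function(model_id, sites, binding_mode_class = "unknown") {
  model_id <- as.character(model_id)
  if (length(model_id) != 1L || !nzchar(model_id)) stop("model_id must be a non-empty string")
  if (!is.list(sites) || length(sites) != 4L)
    stop("sites must be a list of exactly four stick_spectrum objects")
  if (!all(vapply(sites, is_stick_spectrum, TRUE)))
    stop("every site entry must be a stick_spectrum")
  labs <- vapply(sites, function(s) s$site, "")
  if (!setequal(labs, SITE_LABELS))
    stop("sites must cover Mn1, Mn2, Mn3 and Mn4 exactly once")
  sites <- sites[order(match(labs, SITE_LABELS))]
  names(sites) <- SITE_LABELS
  structure(list(model_id = model_id, sites = sites,
                 binding_mode_class = as.character(binding_mode_class)),
            class = "model_entry")
}

#' @export
print.model_entry <- function(x, ...) {
  cat(sprintf("<model_entry> %s (%s): %s transitions per site\n", x$model_id,
              x$binding_mode_class,
              paste(vapply(x$sites, function(s) length(s$energies), 0L), collapse = "/")))
  invisible(x)
}
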