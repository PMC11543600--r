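#' Spectral detector binning
#'
#' Uniform wavelength binning of a spectral detector array. The default
#' mirrors a 16-channel grating detector with 12.5 nm channels covering
#' roughly 570-770 nm, the window used to record red-dye emission spectra.
#'
#' @param bin_centers bin center wavelengths in nm, strictly increasing and
#'   uniformly spaced.
#' @param bin_width channel width in nm (> 0).
#' @return a `spectral_binning` object.
#' @export
spectral_binning <- function(bin_centers = seq(575, by = 12.5,
                                               length.out = 16),
                             bin_width = NULL) {
  if (length(bin_centers) < 2L || any(diff(bin_centers) <= 0))
    stopf("bin_centers must be strictly increasing (>= 2 bins)")
  steps <- diff(bin_centers)
  if (max(steps) - min(steps) > 1e-9 * mean(steps))
    stopf("bin_centers must be uniformly spaced")
  if (is.null(bin_width)) bin_width <- steps[1L]
  if (!is.finite(bin_width) || bin_width <= 0)
    stopf("bin_width must be > 0 (zero-width bins are not a binning)")
  structure(list(bin_centers = as.numeric(bin_centers),
                 bin_width = as.numeric(bin_width)),
            class = "spectral_binning")
}

#' Asymmetric log-normal emission component
#'
#' Parameterizes one emission band by its peak counts (`amplitude`), peak
#' wavelength `lambda_max` (nm), approximate full width at half maximum `w`
#' (nm) and asymmetry `a` (dimensionless; 0.24 is a typical red-dye value and
#' the Gaussian shape is recovered as `a -> 0`).
#'
#' @param amplitude peak intensity (counts, >= 0).
#' @param lambda_max peak wavelength (nm).
#' @param w approximate FWHM (nm, > 0).
#' @param a asymmetry parameter.
#' @return a `lognormal_component` object.
#' @export
lognormal_component <- function(amplitude, lambda_max, w, a = 0.24) {
  if (!is.finite(amplitude) || amplitude < 0) stopf("amplitude must be >= 0")
  if (!is.finite(lambda_max)) stopf("lambda_max must be finite")
  if (!is.finite(w) || w <= 0) stopf("w must be > 0")
  if (!is.finite(a)) stopf("a must be finite")
  structure(list(amplitude = amplitude, lambda_max = lambda_max,
                 w = w, a = a),
            class = "lognormal_component")
}

#' Asymmetric log-normal line shape
#'
#' \deqn{I(\lambda) = A \exp\!\left(-\ln 2
#'   \left[\frac{\ln\!\big(1 + 2a(\lambda-\lambda_{max})/w\big)}{a}\right]^2
#'   \right)}
#' for `1 + 2a(lambda - lambda_max)/w > 0` and 0 outside that support. At
#' `lambda = lambda_max` the shape equals `amplitude`; as `a -> 0` it tends
#' to a Gaussian with FWHM `w`. `|a|` below 1e-6 is evaluated through the
#' Gaussian limit for numerical stability.
#'
#' @param lambda wavelength(s) in nm, finite.
#' @param c a [lognormal_component()].
#' @return intensity at `lambda` (same length as `lambda`).
#' @export
lognormal_shape <- function(lambda, c) {
  stopifnot(inherits(c, "lognormal_component"))
  if (!all(is.finite(lambda))) stopf("lambda must be finite")
  u <- 2 * (lambda - c$lambda_max) / c$w
  if (abs(c$a) < 1e-6) {
    # Gaussian limit: ln(1 + a u)/a -> u
    return(c$amplitude * exp(-log(2) * u^2))
  }
  arg <- 1 + c$a * u
  out <- numeric(length(lambda))
  ok <- arg > 0
  out[ok] <- c$amplitude * exp(-log(2) * (log(arg[ok]) / c$a)^2)
  out
}

# Expected per-bin counts of one component: midpoint rule over the bin
# (channel width 12.5 nm is small against line widths of ~50 nm).
component_bin_counts <- function(c, bins) {
  lognormal_shape(bins$bin_centers, c) * bins$bin_width
}

# Bin-integrated area of a component over the recorded window.
component_area <- function(c, bins) sum(component_bin_counts(c, bins))

#' Synthesize a binned emission spectrum
#'
#' Builds the expected channel counts of one or more log-normal components on
#' a uniform binning (midpoint rule), optionally rescales the total to
#' `total_counts`, and optionally applies Poisson photon noise.
#'
#' @param components a single [lognormal_component()] or a list of them.
#' @param bins a [spectral_binning()].
#' @param total_counts if non-NULL, scale the summed expectation so the
#'   spectrum totals this many counts. NULL keeps the component amplitudes'
#'   native scale (the spectrum is then linear in its components).
#' @param noise_seed integer seed for Poisson noise; NULL returns the
#'   noiseless expectation.
#' @param excitation_nm excitation wavelength label (metadata only).
#' @param background_level constant per-bin background added before noise.
#' @return an `emission_spectrum` object with fields `binning`, `counts`,
#'   `excitation_nm`, `background_level`.
#' @export
synth_spectrum <- function(components, bins = spectral_binning(),
                           total_counts = NULL, noise_seed = NULL,
                           excitation_nm = NA_real_, background_level = 0) {
  if (inherits(components, "lognormal_component"))
    components <- list(components)
  if (length(components) < 1L)
    stopf("need at least one spectral component")
  stopifnot(inherits(bins, "spectral_binning"))
  expected <- Reduce(`+`, lapply(components, component_bin_counts, bins = bins))
  if (!is.null(total_counts)) {
    if (sum(expected) <= 0) stopf("components carry no intensity in window")
    expected <- expected * (total_counts / sum(expected))
  }
  expected <- expected + background_level
  counts <- if (is.null(noise_seed)) expected else
    with_seed(noise_seed, rpois(length(expected), expected))
  emission_spectrum(bins, counts, excitation_nm = excitation_nm,
                    background_level = background_level)
}

#' Construct an emission spectrum object
#'
#' @param binning a [spectral_binning()].
#' @param counts non-negative per-bin counts (same length as bin centers).
#' @param excitation_nm excitation wavelength label.
#' @param background_level known or estimated constant background per bin.
#' @return an `emission_spectrum` object.
#' @export
emission_spectrum <- function(binning, counts, excitation_nm = NA_real_,
                              background_level = 0) {
  stopifnot(inherits(binning, "spectral_binning"))
  if (length(counts) != length(binning$bin_centers))
    stopf("counts length (%d) != number of bins (%d)",
          length(counts), length(binning$bin_centers))
  if (!all(is.finite(counts)) || any(counts < 0))
    stopf("spectrum counts must be finite and >= 0")
  structure(list(binning = binning, counts = as.numeric(counts),
                 excitation_nm = excitation_nm,
                 background_level = background_level),
            class = "emission_spectrum")
}
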