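#' Two-dimensional anomalous diffusion FCS model
#'
#' \deqn{G(\tau) = \frac{1}{N}\left(1 + (\tau/\tau_D)^{\alpha}\right)^{-1}}
#' where `N` is the average number of fluorescent particles in the focal
#' spot, `tau_D` the average transit time and `alpha` the anomaly parameter.
#' Appropriate for dyes diffusing in a (2D) membrane.
#'
#' @param tau lag time(s), s, >= 0.
#' @param N average molecule number in the focal spot (> 0).
#' @param tau_D average transit time (s, > 0).
#' @param alpha anomaly parameter (0 < alpha <= 2); 1 is free diffusion.
#' @return G(tau).
#' @export
model_diffusion_2d <- function(tau, N, tau_D, alpha = 1) {
  check_fcs_params(N, tau_D, alpha)
  if (any(tau < 0)) stopf("lag times must be >= 0")
  (1 / N) / (1 + (tau / tau_D)^alpha)
}

#' 2D diffusion FCS model with triplet blinking
#'
#' \deqn{G(\tau) = \frac{1}{N}\left(1 + (\tau/\tau_D)^{\alpha}\right)^{-1}
#'   \left(1 - T + T e^{-\tau/\tau_{triplet}}\right)}
#' with `T` the triplet-state fraction and `tau_triplet` the triplet
#' correlation time. At `T = 0` this reduces to [model_diffusion_2d()]; for
#' red-excitation membrane measurements `tau_triplet` is typically frozen at
#' an independently determined value (5 us).
#'
#' @inheritParams model_diffusion_2d
#' @param T triplet fraction, in [0, 1).
#' @param tau_triplet triplet correlation time (s, > 0).
#' @return G(tau).
#' @export
model_with_triplet <- function(tau, N, tau_D, alpha = 1, T = 0,
                               tau_triplet = 5e-6) {
  check_fcs_params(N, tau_D, alpha, T, tau_triplet)
  if (any(tau < 0)) stopf("lag times must be >= 0")
  model_diffusion_2d(tau, N, tau_D, alpha) *
    (1 - T + T * exp(-tau / tau_triplet))
}

check_fcs_params <- function(N, tau_D, alpha = 1, T = 0, tau_triplet = 5e-6) {
  if (!is.finite(N) || N <= 0) stopf("N must be > 0")
  if (!is.finite(tau_D) || tau_D <= 0) stopf("tau_D must be > 0")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 2)
    stopf("alpha must be in (0, 2]")
  if (!is.finite(T) || T < 0 || T >= 1) stopf("T must be in [0, 1)")
  if (!is.finite(tau_triplet) || tau_triplet <= 0)
    stopf("tau_triplet must be > 0")
  invisible(TRUE)
}

#' Molecular brightness (counts per molecule)
#'
#' Divides the average detected count rate of a measurement by the average
#' number of molecules in the observation spot.
#'
#' @param mean_rate average count rate (Hz).
#' @param N average molecule number (> 0).
#' @return brightness Q in counts s^-1 molecule^-1.
#' @export
brightness <- function(mean_rate, N) {
  if (!all(is.finite(N)) || any(N <= 0)) stopf("N must be > 0")
  mean_rate / N
}

#' Molecule percentage relative to the initial red-channel count
#'
#' @param N_t molecule number at the current time point.
#' @param N0_red initial molecule number from the red detection channel
#'   (> 0).
#' @return 100 * N_t / N0_red (percent).
#' @export
molecule_percentage <- function(N_t, N0_red) {
  if (!all(is.finite(N0_red)) || any(N0_red <= 0))
    stopf("initial red-channel N must be > 0")
  100 * N_t / N0_red
}

#' Apparent STED spot size from diffusion-time calibration
#'
#' \deqn{\omega_{0,STED} = \omega_{0,conf}
#'   \sqrt{\tau_{D,STED} / \tau_{D,conf}}}
#' where `omega0` is the 1/e^2 radius of the Gaussian observation spot and
#' the `tau_D` are the transit times measured at a given STED power and in
#' confocal mode on the same (membrane) sample.
#'
#' @param tau_D_sted transit time under STED (s, > 0).
#' @param tau_D_conf confocal transit time (s, > 0).
#' @param omega0_conf confocal 1/e^2 beam radius (nm, > 0).
#' @return apparent STED spot radius (nm). Warns when it exceeds the
#'   confocal radius.
#' @export
sted_spot_size <- function(tau_D_sted, tau_D_conf, omega0_conf) {
  vals <- c(tau_D_sted, tau_D_conf, omega0_conf)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stopf("all spot-size inputs must be > 0")
  out <- omega0_conf * sqrt(tau_D_sted / tau_D_conf)
  if (any(out > omega0_conf))
    warning("apparent STED spot larger than confocal spot", call. = FALSE)
  out
}
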