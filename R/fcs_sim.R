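#' Configuration for a 2D Brownian FCS trace simulation
#'
#' Emitters diffuse in a periodic square box and are observed through a 2D
#' Gaussian detection profile centered in the box, the standard picture for
#' dyes in a supported lipid bilayer under a confocal or STED spot.
#'
#' @param n_molecules target average molecule number in the observation spot
#'   (effective N); the simulated box holds
#'   `n_molecules * box_size^2 / (pi * omega0^2)` molecules, since the
#'   effective Gaussian detection area is `pi * omega0^2`.
#' @param omega0 1/e^2 Gaussian beam radius (nm); must be < box_size / 4 so
#'   periodic images carry no intensity. The slowest periodic diffusion mode
#'   relaxes on `box_size^2 / (4 pi^2 D)`, which truncates the correlation
#'   tail; the default box keeps that cutoff at `(box_size / (pi omega0))^2
#'   ~ 60` diffusion times so the infinite-membrane model fits without
#'   noticeable bias.
#' @param diffusion_coeff lateral diffusion coefficient (um^2/s); typical
#'   lipid analogues in fluid bilayers show ~1 um^2/s.
#' @param box_size periodic box edge (nm).
#' @param T stationary triplet (dark-state) fraction, in [0, 1).
#' @param tau_triplet triplet correlation time (s); resolve it with
#'   `bin_time <= tau_triplet / 4` or leave `T = 0`.
#' @param counts_per_molecule detected photons/s for a molecule at the beam
#'   center.
#' @param bin_time trace bin duration (s).
#' @param duration trace length (s); must be an integer multiple (>= 2) of
#'   `bin_time`.
#' @param positions optional fixed starting positions (matrix with columns
#'   x, y in nm, origin at the box center); overrides random placement and
#'   the molecule count.
#' @return a `trace_sim_config`.
#' @export
trace_sim_config <- function(n_molecules = 5, omega0 = 240,
                             diffusion_coeff = 1, box_size = 6000,
                             T = 0, tau_triplet = 5e-6,
                             counts_per_molecule = 3e4,
                             bin_time = 4e-4, duration = 60,
                             positions = NULL) {
  if (!is.finite(omega0) || omega0 <= 0 || !is.finite(box_size) ||
      box_size <= 0 || omega0 >= box_size / 4)
    stopf("need 0 < omega0 < box_size / 4 (got omega0 = %g, box = %g)",
          omega0, box_size)
  n_bins <- duration / bin_time
  if (!is.finite(n_bins) || n_bins < 2 || abs(n_bins - round(n_bins)) > 1e-6)
    stopf("duration / bin_time must be an integer >= 2")
  if (!is.finite(T) || T < 0 || T >= 1) stopf("T must be in [0, 1)")
  if (!is.finite(tau_triplet) || tau_triplet <= 0)
    stopf("tau_triplet must be > 0")
  if (diffusion_coeff < 0) stopf("diffusion_coeff must be >= 0")
  if (counts_per_molecule < 0) stopf("counts_per_molecule must be >= 0")
  if (n_molecules <= 0 && is.null(positions))
    stopf("n_molecules must be > 0")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (ncol(positions) != 2L) stopf("positions must have two columns (x, y)")
  }
  structure(list(n_molecules = n_molecules, omega0 = omega0,
                 diffusion_coeff = diffusion_coeff, box_size = box_size,
                 T = T, tau_triplet = tau_triplet,
                 counts_per_molecule = counts_per_molecule,
                 bin_time = bin_time, duration = duration,
                 n_bins = as.integer(round(n_bins)),
                 positions = positions),
            class = "trace_sim_config")
}

#' Effective molecule number of a simulation configuration
#'
#' For a 2D Gaussian detection profile `exp(-2 r^2 / omega0^2)` the FCS
#' amplitude corresponds to an effective detection area `pi * omega0^2`, so
#' the expected fitted N equals the molecule density times that area.
#'
#' @param cfg a [trace_sim_config()].
#' @return expected fitted molecule number.
#' @export
effective_n <- function(cfg) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  if (!is.null(cfg$positions))
    return(nrow(cfg$positions) * pi * cfg$omega0^2 / cfg$box_size^2)
  cfg$n_molecules
}

# expected molecule count in the box; the realized count is a Poisson draw
# (the box is a patch of an infinite membrane)
sim_molecule_count <- function(cfg) {
  cfg$n_molecules * cfg$box_size^2 / (pi * cfg$omega0^2)
}

#' Simulate an FCS intensity trace from 2D Brownian diffusers
#'
#' Molecules perform Brownian motion in a periodic box; the per-bin expected
#' photon count of each molecule is
#' `counts_per_molecule * bin_time * exp(-2 r^2 / omega0^2)` with `r` its
#' distance from the beam center, gated by a two-state bright/triplet
#' telegraph chain with stationary dark fraction `T` and correlation time
#' `tau_triplet`. Detected counts are Poisson draws around the summed
#' expectation. Fully reproducible under `seed`.
#'
#' @param cfg a [trace_sim_config()].
#' @param seed integer seed (NULL uses the current RNG stream).
#' @return an [intensity_trace()]. The noiseless expected intensity (Hz) is
#'   attached as attribute `expected_rate`.
#' @export
simulate_fcs_trace <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "trace_sim_config"))
  with_seed(seed, {
    n_bins <- cfg$n_bins
    half <- cfg$box_size / 2
    pos <- cfg$positions
    n_mol <- if (!is.null(pos)) nrow(pos) else
      rpois(1L, sim_molecule_count(cfg))
    if (is.null(pos))
      pos <- cbind(runif(n_mol, -half, half), runif(n_mol, -half, half))
    step_sd <- sqrt(2 * cfg$diffusion_coeff * 1e6 * cfg$bin_time) # nm
    relax <- exp(-cfg$bin_time / cfg$tau_triplet)
    peak <- cfg$counts_per_molecule * cfg$bin_time
    intensity <- if (n_mol > 0)
      .fcs_trace_core(pos, n_bins, step_sd, cfg$omega0, peak, cfg$box_size,
                      cfg$T, relax)
    else numeric(n_bins)
    counts <- rpois(n_bins, intensity)
    out <- intensity_trace(counts, cfg$bin_time)
    attr(out, "expected_rate") <- intensity / cfg$bin_time
    out
  })
}
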