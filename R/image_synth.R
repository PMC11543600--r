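#' Synthesize a two-channel ratiometric membrane image stack
#'
#' Generates an illumination series of two-channel (b = 580-630 nm,
#' r = 650-700 nm) images of a membrane structure with known ground-truth
#' GP. The original probe splits its emission between the channels according
#' to `gp_true`; photoblueing converts a fraction `f_blue(frame)` of the
#' probe pool (from [simulate_photoconversion()]) into a species emitting
#' entirely in the b band with relative brightness
#' `kinetics$brightness_ratio_blue`, so the apparent per-pixel GP at frame t
#' is
#' \deqn{GP_{app} = \frac{f_{red}\,GP_{true} + \beta f_{blue}}
#'                      {f_{red} + \beta f_{blue}} \ge GP_{true}.}
#' In replenishment (exchangeable-dye) mode the pool is reset every frame
#' and the apparent GP stays at `gp_true`. Background pixels receive
#' `background_fraction` of the membrane counts, split evenly between the
#' channels.
#'
#' @param gp_true ground-truth GP: a scalar or a matrix in [-1, 1].
#' @param mask logical matrix marking membrane pixels; if NULL, a horizontal
#'   membrane stripe through the image center is used. Its shape defines the
#'   image shape when `gp_true` is scalar.
#' @param kinetics a [photo_kinetics()] object.
#' @param n_frames number of illumination frames after frame 0.
#' @param counts expected summed two-channel counts of an unconverted
#'   membrane pixel per frame.
#' @param saturation saturation count value.
#' @param background_fraction background level relative to `counts`.
#' @param dims image dimensions used when neither `gp_true` nor `mask` is a
#'   matrix.
#' @param pixel_size pixel edge (nm).
#' @param seed integer seed for Poisson shot noise; NULL returns the
#'   noiseless expectation (real-valued counts, no noise).
#' @return a `two_channel_stack`: list of 3D arrays `I_b`, `I_r`
#'   (x, y, frame), `saturation_value`, `pixel_size`, plus the ground truth
#'   in `gp_true`, `mask_true` and the kinetic trajectory in `trajectory`.
#' @export
synth_two_channel_stack <- function(gp_true, mask = NULL,
                                    kinetics = photo_kinetics(),
                                    n_frames = 30, counts = 500,
                                    saturation = 65535,
                                    background_fraction = 0.02,
                                    dims = c(48L, 48L), pixel_size = 40,
                                    seed = NULL) {
  if (is.matrix(gp_true)) dims <- dim(gp_true)
  else if (is.matrix(mask)) dims <- dim(mask)
  if (is.null(mask)) {
    mask <- matrix(FALSE, dims[1L], dims[2L])
    stripe <- seq.int(max(1L, dims[1L] %/% 2 - dims[1L] %/% 8),
                      min(dims[1L], dims[1L] %/% 2 + dims[1L] %/% 8))
    mask[stripe, ] <- TRUE
  }
  mask <- as.matrix(mask)
  if (!is.matrix(gp_true)) gp_true <- matrix(gp_true, dims[1L], dims[2L])
  if (!identical(dim(gp_true), dim(mask)))
    stopf("gp_true and mask shapes differ")
  if (any(!is.finite(gp_true)) || any(abs(gp_true) > 1))
    stopf("gp_true values must lie in [-1, 1]")
  stopifnot(inherits(kinetics, "photo_kinetics"))
  traj <- simulate_photoconversion(kinetics, n_frames)
  beta <- kinetics$brightness_ratio_blue
  nf <- n_frames + 1L
  I_b <- array(0, c(dim(mask), nf))
  I_r <- array(0, c(dim(mask), nf))
  bg <- counts * background_fraction / 2
  for (t in seq_len(nf)) {
    f_red <- traj$f_red[t]
    f_blue <- traj$f_blue[t]
    eb <- counts * (f_red * (1 + gp_true) / 2 + beta * f_blue)
    er <- counts * (f_red * (1 - gp_true) / 2)
    eb[!mask] <- bg
    er[!mask] <- bg
    I_b[, , t] <- eb
    I_r[, , t] <- er
  }
  if (!is.null(seed)) {
    I_b <- with_seed(derive_seed(seed, 1L),
                     array(rpois(length(I_b), I_b), dim(I_b)))
    I_r <- with_seed(derive_seed(seed, 2L),
                     array(rpois(length(I_r), I_r), dim(I_r)))
  }
  I_b <- pmin(I_b, saturation)
  I_r <- pmin(I_r, saturation)
  structure(list(I_b = I_b, I_r = I_r, saturation_value = saturation,
                 pixel_size = pixel_size, gp_true = gp_true,
                 mask_true = mask, trajectory = traj),
            class = "two_channel_stack")
}
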