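#' Generalized polarization of a pixel
#'
#' \deqn{GP = (I_b - I_r) / (I_b + I_r)}
#' with `I_b` and `I_r` the intensities in the blue-shifted (580-630 nm) and
#' red-shifted (650-700 nm) detection bands. Returns `NA` where both
#' channels are zero (the ratio is undefined there and such pixels are
#' masked rather than set to 0, which would bias ROI means).
#'
#' @param I_b,I_r non-negative channel intensities (vectors or matrices of
#'   identical shape).
#' @return GP values in [-1, 1], `NA` where `I_b + I_r = 0`.
#' @export
gp_pixel <- function(I_b, I_r) {
  if (any(I_b < 0, na.rm = TRUE) || any(I_r < 0, na.rm = TRUE))
    stopf("channel intensities must be >= 0")
  if (length(I_b) != length(I_r)) stopf("channel shapes differ")
  tot <- I_b + I_r
  out <- (I_b - I_r) / tot
  out[tot == 0] <- NA_real_
  out
}

#' Two-channel ratiometric image
#'
#' @param I_b,I_r integer count matrices of identical shape for the
#'   580-630 nm (b) and 650-700 nm (r) bands.
#' @param saturation_value maximum representable count (default 65535).
#' @param pixel_size pixel edge (nm).
#' @return a `two_channel_image`.
#' @export
two_channel_image <- function(I_b, I_r, saturation_value = 65535,
                              pixel_size = 40) {
  I_b <- as.matrix(I_b); I_r <- as.matrix(I_r)
  if (!identical(dim(I_b), dim(I_r)))
    stopf("channel shapes differ: %s vs %s",
          paste(dim(I_b), collapse = "x"), paste(dim(I_r), collapse = "x"))
  if (any(I_b < 0) || any(I_r < 0)) stopf("counts must be >= 0")
  if (any(I_b > saturation_value) || any(I_r > saturation_value))
    stopf("counts exceed the saturation value")
  structure(list(I_b = I_b, I_r = I_r,
                 saturation_value = saturation_value,
                 pixel_size = pixel_size),
            class = "two_channel_image")
}

#' Membrane mask by summed-intensity threshold
#'
#' A pixel is part of the membrane mask iff its summed two-channel intensity
#' reaches `threshold_fraction` of the maximum summed intensity in the image
#' AND neither channel is saturated (saturated pixels are excluded
#' unconditionally).
#'
#' @param img a [two_channel_image()].
#' @param threshold_fraction fraction of the maximum summed intensity, in
#'   (0, 1).
#' @return logical matrix; attribute `empty` flags an all-FALSE mask.
#' @export
membrane_mask <- function(img, threshold_fraction = 0.2) {
  stopifnot(inherits(img, "two_channel_image"))
  if (!is.finite(threshold_fraction) || threshold_fraction <= 0 ||
      threshold_fraction >= 1)
    stopf("threshold_fraction must be in (0, 1)")
  tot <- img$I_b + img$I_r
  mask <- tot >= threshold_fraction * max(tot) &
    img$I_b < img$saturation_value & img$I_r < img$saturation_value
  if (!any(mask))
    warning("membrane mask is empty", call. = FALSE)
  structure(mask, empty = !any(mask))
}

#' Per-pixel GP map and ROI mean
#'
#' @param img a [two_channel_image()].
#' @param mask logical matrix of included pixels (e.g. [membrane_mask()]).
#' @return a `gp_map`: list with `gp` (per-pixel GP, `NA` off-mask or where
#'   undefined), `mask`, `mean_gp` (unweighted mean of per-pixel GP over the
#'   mask) and `n_pixels_used`.
#' @export
gp_map <- function(img, mask) {
  stopifnot(inherits(img, "two_channel_image"))
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(img$I_b))) stopf("mask shape differs")
  gp <- gp_pixel(img$I_b, img$I_r)
  gp[!mask] <- NA_real_
  used <- sum(is.finite(gp))
  if (used == 0L) warning("no usable pixels for GP", call. = FALSE)
  structure(list(gp = gp, mask = mask,
                 mean_gp = if (used) mean(gp, na.rm = TRUE) else NA_real_,
                 n_pixels_used = used),
            class = "gp_map")
}

#' GP time series over an illumination image stack
#'
#' Masks the membrane on frame 0 and reuses that mask for every later frame
#' (so bleaching-driven mask shrinkage cannot bias the series), then reports
#' the per-frame ROI mean GP and its change relative to frame 0.
#'
#' @param stack a `two_channel_stack` (see [synth_two_channel_stack()]).
#' @param threshold_fraction passed to [membrane_mask()] on frame 0.
#' @return a `gp_time_series` data.frame with columns `frame`, `mean_gp`,
#'   `delta_gp`, `n_pixels`.
#' @export
gp_change_series <- function(stack, threshold_fraction = 0.2) {
  stopifnot(inherits(stack, "two_channel_stack"))
  n_frames <- dim(stack$I_b)[3L]
  if (n_frames < 2L) stopf("need at least 2 frames")
  f0 <- stack_frame(stack, 1L)
  mask <- membrane_mask(f0, threshold_fraction)
  if (attr(mask, "empty")) stopf("frame-0 membrane mask is empty")
  res <- lapply(seq_len(n_frames), function(i)
    gp_map(stack_frame(stack, i), mask))
  mean_gp <- vapply(res, `[[`, 0, "mean_gp")
  out <- data.frame(frame = seq_len(n_frames) - 1L, mean_gp = mean_gp,
                    delta_gp = mean_gp - mean_gp[1L],
                    n_pixels = vapply(res, `[[`, 0L, "n_pixels_used"))
  class(out) <- c("gp_time_series", "data.frame")
  out
}

#' Extract one frame of a two-channel stack
#'
#' @param stack a `two_channel_stack`.
#' @param i frame index (1-based).
#' @return a [two_channel_image()].
#' @export
stack_frame <- function(stack, i) {
  stopifnot(inherits(stack, "two_channel_stack"))
  two_channel_image(stack$I_b[, , i], stack$I_r[, , i],
                    saturation_value = stack$saturation_value,
                    pixel_size = stack$pixel_size)
}
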