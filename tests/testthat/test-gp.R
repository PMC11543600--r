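test_that("GP of a pixel is the printed ratio with its boundary cases", {
  expect_identical(gp_pixel(3, 1), 0.5)
  expect_identical(gp_pixel(5, 5), 0)
  expect_identical(gp_pixel(4, 0), 1)
  expect_true(is.na(gp_pixel(0, 0)))
  expect_error(gp_pixel(-1, 2), ">= 0")
})

test_that("GP is antisymmetric under channel swap and scale invariant", {
  set.seed(51)
  I_b <- matrix(rpois(400, 200), 20)
  I_r <- matrix(rpois(400, 120), 20)
  expect_equal(gp_pixel(I_b, I_r), -gp_pixel(I_r, I_b))
  expect_equal(gp_pixel(3.7 * I_b, 3.7 * I_r), gp_pixel(I_b, I_r),
               tolerance = 1e-12)
})

test_that("membrane masking thresholds and excludes saturated pixels", {
  img <- two_channel_image(matrix(100, 8, 8), matrix(100, 8, 8))
  expect_true(all(membrane_mask(img, 0.5)))
  I_b <- matrix(100, 8, 8)
  I_b[3, 3] <- 65535
  img2 <- two_channel_image(I_b, matrix(100, 8, 8))
  m <- membrane_mask(img2, 0.0001)
  expect_false(m[3, 3])
  expect_equal(sum(m), 63)
  # a noiseless membrane stripe at 10x background is recovered exactly
  stack <- synth_two_channel_stack(0.3, n_frames = 1, counts = 1000,
                                   background_fraction = 0.1)
  m2 <- membrane_mask(stack_frame(stack, 1), 0.5)
  expect_identical(unclass(m2)[, ], stack$mask_true)
  # empty mask is flagged, not silent
  dark <- two_channel_image(matrix(65535, 4, 4), matrix(0, 4, 4))
  expect_warning(m3 <- membrane_mask(dark, 0.5), "empty")
  expect_true(attr(m3, "empty"))
})

test_that("GP maps invert the noiseless construction and average honestly", {
  stack <- synth_two_channel_stack(0.2, n_frames = 1)
  img <- stack_frame(stack, 1)
  gm <- gp_map(img, stack$mask_true)
  expect_equal(gm$mean_gp, 0.2, tolerance = 1e-12)
  # homogeneous truth: restricting the mask leaves the mean unchanged
  half <- stack$mask_true
  half[, 1:24] <- FALSE
  expect_equal(gp_map(img, half)$mean_gp, 0.2, tolerance = 1e-12)
  # mixture mean lies between the per-region truths
  gp_true <- matrix(0.1, 48, 48)
  gp_true[1:24, ] <- 0.5
  stack2 <- synth_two_channel_stack(gp_true, mask = matrix(TRUE, 48, 48),
                                    n_frames = 1)
  mix <- gp_map(stack_frame(stack2, 1), matrix(TRUE, 48, 48))$mean_gp
  expect_gt(mix, 0.1)
  expect_lt(mix, 0.5)
})

test_that("Poisson shot noise keeps the ROI mean within the delta bound", {
  stack <- synth_two_channel_stack(0.2, mask = matrix(TRUE, 32, 32),
                                   n_frames = 1, counts = 500, seed = 99)
  gm <- gp_map(stack_frame(stack, 1), matrix(TRUE, 32, 32))
  expect_gt(gm$n_pixels_used, 1000)
  expect_lt(abs(gm$mean_gp - 0.2), 0.01)
})

test_that("photoblueing inflates apparent GP; replenishment does not", {
  pk_on <- photo_kinetics(k_blue = 0.04, k_bleach_red = 0.03,
                          k_bleach_blue = 0.01, brightness_ratio_blue = 1)
  noiseless <- synth_two_channel_stack(0.2, kinetics = pk_on, n_frames = 30)
  ser <- gp_change_series(noiseless)
  expect_identical(ser$delta_gp[1], 0)
  expect_true(all(diff(ser$delta_gp) > 0))
  # apparent GP exceeds the truth as soon as emission moves into the b band
  expect_true(all(ser$mean_gp[-1] > 0.2))
  pk_off <- photo_kinetics()
  flat <- gp_change_series(synth_two_channel_stack(0.2, kinetics = pk_off,
                                                   n_frames = 10, seed = 4))
  expect_true(all(abs(flat$delta_gp) < 0.01))
  pk_ex <- photo_kinetics(k_blue = 0.04, k_bleach_red = 0.03,
                          brightness_ratio_blue = 1, replenishment = TRUE)
  ex <- gp_change_series(synth_two_channel_stack(0.2, kinetics = pk_ex,
                                                 n_frames = 30, seed = 4))
  expect_lt(abs(ex$delta_gp[31]), 0.01)
})

test_that("apparent GP bias grows monotonically with the conversion rate", {
  bias <- vapply(c(0.01, 0.02, 0.04, 0.06, 0.09), function(kb) {
    pk <- photo_kinetics(k_blue = kb, k_bleach_red = 0.03,
                         brightness_ratio_blue = 1)
    st <- synth_two_channel_stack(0.2, kinetics = pk, n_frames = 10)
    gp_change_series(st)$delta_gp[11]
  }, 0)
  expect_true(all(diff(bias) > 0))
})

test_that("invalid image inputs are rejected", {
  expect_error(synth_two_channel_stack(1.2), "gp_true")
  expect_error(two_channel_image(matrix(1, 2, 2), matrix(1, 3, 3)), "shapes")
  expect_error(membrane_mask(two_channel_image(matrix(1, 2, 2),
                                               matrix(1, 2, 2)), 1.5),
               "threshold")
})
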