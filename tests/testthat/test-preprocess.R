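frame_nc <- function(fr) {
  seg <- segment_frame(fr)
  nc_ratio(seg, roi_from_mask_like(fr))$nc_ratio
}

roi_from_mask_like <- function(fr) {
  structure(list(mask = hrme:::frame_roi(fr)), class = "roi_mask")
}

test_that("a full-FOV ROI reproduces the unmasked analysis", {
  r <- render_small(0.12, seed = 41)
  fr <- preprocess_frame(r$frame)                 # default full-FOV ROI
  fr2 <- preprocess_frame(r$frame, roi = roi_full(r$frame))
  expect_identical(fr$pixels, fr2$pixels)
  expect_identical(frame_nc(fr), frame_nc(fr2))
})

test_that("restricting the ROI to half the FOV preserves N/C within 0.01", {
  r <- render_small(0.12, seed = 42)
  fov <- r$frame$fov
  half <- matrix(FALSE, nrow(fov), ncol(fov))
  half[, seq_len(ncol(fov) / 2)] <- TRUE
  roi <- roi_from_mask(r$frame, half)
  # oracle: ground-truth pixel counts restricted to the half
  np <- sum(r$truth$nuclear_mask & roi$mask)
  nc_true_half <- np / (sum(roi$mask) - np)
  fr <- preprocess_frame(r$frame, roi = roi)
  seg <- segment_frame(fr)
  est <- nc_ratio(seg, roi)$nc_ratio
  expect_lt(abs(est - nc_true_half), 0.01)
})

test_that("an ROI excluding a saturated blob excludes it from nuclear area", {
  r <- render_small(0.08, seed = 43)
  img <- r$frame$pixels
  blob <- matrix(FALSE, nrow(img), ncol(img))
  blob[100:140, 100:140] <- TRUE
  img[blob] <- 1
  fr0 <- hrme_frame(img, 1, r$frame$fov)
  roi <- roi_from_mask(fr0, r$frame$fov & !blob)
  fr <- preprocess_frame(fr0, roi = roi)
  seg <- segment_frame(fr)
  expect_equal(sum(seg$binary_mask & blob), 0L)
})

test_that("empty and mismatched ROIs are rejected", {
  r <- render_small(0.05, seed = 44)
  expect_error(roi_from_mask(r$frame,
                             matrix(FALSE, nrow(r$frame$pixels),
                                    ncol(r$frame$pixels))), "empty ROI")
  expect_error(apply_roi(r$frame,
                         structure(list(mask = matrix(TRUE, 2, 2)),
                                   class = "roi_mask")), "shape")
})

test_that("polygon ROIs rasterize in the 0-based pixel convention", {
  fr <- hrme_frame(matrix(0.5, 64, 64))
  # axis-aligned square covering pixel centres 10..20 in x and y
  roi <- roi_polygon(fr, cbind(c(9.5, 20.5, 20.5, 9.5),
                               c(9.5, 9.5, 20.5, 20.5)))
  expect_equal(sum(roi$mask), 11L * 11L)
  expect_true(roi$mask[15, 15])   # row 15 = y 14, col 15 = x 14
  expect_false(roi$mask[9, 15])
})

test_that("CLAHE maps constant images to constant images within range", {
  fr <- hrme_frame(matrix(0.4, 128, 128))
  out <- equalize_contrast(fr)
  expect_lt(stats::sd(out$pixels[out$fov]), 1e-9)
  expect_gte(min(out$pixels), 0)
  expect_lte(max(out$pixels), 1)
})

test_that("CLAHE increases nucleus/background separation at low contrast", {
  nuclei <- nucleus_params(background = 0.45, peak_intensity = 0.5,
                           peak_sd = 0.01)
  r <- render_frame(0.12, small_spec(pattern_amplitude = 0.05),
                    nuclei = nuclei, noise = noise_model(2000, 0.005),
                    seed = 45)
  fisher <- function(img) {
    fg <- img[r$truth$nuclear_mask]
    bg <- img[r$frame$fov & !r$truth$nuclear_mask]
    (mean(fg) - mean(bg))^2 / (stats::var(fg) + stats::var(bg))
  }
  eq <- equalize_contrast(apply_roi(r$frame, roi_full(r$frame)))
  expect_gt(fisher(eq$pixels), fisher(r$frame$pixels))
})

test_that("CLAHE rejects tile grids larger than the image", {
  fr <- hrme_frame(matrix(0.5, 6, 6))
  expect_error(equalize_contrast(fr, tiles = c(8, 8)), "tile")
})

test_that("median filtering leaves constant images unchanged", {
  fr <- hrme_frame(matrix(0.5, 64, 64))
  out <- remove_fiber_pattern(fr, 3)
  expect_lt(max(abs(out$pixels[out$fov] - 0.5)), 1e-3)
})

test_that("a radius-3 median suppresses the honeycomb to <= 10% amplitude", {
  spec <- small_spec(pattern_amplitude = 0.4)
  p <- make_fiber_pattern(spec)
  a <- diff(range(p[fov_mask(spec)]))  # input peak-to-trough
  fr <- hrme_frame(pmin(pmax(p / 2, 0), 1), 1, fov_mask(spec))
  out <- remove_fiber_pattern(fr, 3)
  interior <- hrme:::disc_mask(nrow(p), ncol(p), nrow(p) / 2 - 12)
  resid <- diff(range(out$pixels[interior])) * 2  # undo the /2 scaling
  expect_lte(resid, 0.1 * a)
})

test_that("median filtering erodes a 6 px nucleus only at its boundary", {
  # on a two-valued image the median is the neighbourhood majority
  # vote; that vote, computed by brute force, is the oracle for the
  # filtered-and-rethresholded nucleus mask
  n <- 64
  img <- matrix(0.25, n, n)
  truth <- hrme:::disc_mask(n, n, 6, center = c(32, 32))
  img[truth] <- 0.75
  fr <- hrme_frame(img, 1, matrix(TRUE, n, n))
  out <- remove_fiber_pattern(fr)  # default core-spanning kernel (r = 2)
  mask <- out$pixels > 0.5
  oracle <- matrix(FALSE, n, n)
  for (i in 3:(n - 2)) for (j in 3:(n - 2))
    oracle[i, j] <- sum(truth[(i - 2):(i + 2), (j - 2):(j + 2)]) > 12
  expect_identical(mask, oracle)
  # erosion is confined to a sub-pixel boundary band: every lost pixel
  # lies within 1 px of the continuous nucleus boundary, and nothing
  # is gained outside the nucleus
  lost <- which(truth & !mask, arr.ind = TRUE)
  d <- sqrt((lost[, 1] - 32)^2 + (lost[, 2] - 32)^2)
  expect_true(all(d > 5))
  expect_equal(sum(mask & !truth), 0L)
  # oracle-computed retention for this geometry: 101 of 113 px
  expect_equal(sum(mask & truth), 101L)
  expect_equal(sum(truth), 113L)
})

test_that("preprocessing is deterministic and re-runnable", {
  r <- render_small(0.10, seed = 46, noise = noise_model())
  a <- preprocess_frame(r$frame)
  b <- preprocess_frame(r$frame)
  expect_identical(a$pixels, b$pixels)
  # re-running CLAHE/median on their own output is safe and deterministic
  expect_identical(equalize_contrast(a)$pixels,
                   equalize_contrast(a)$pixels)
  expect_identical(remove_fiber_pattern(a)$pixels,
                   remove_fiber_pattern(a)$pixels)
  # the non-standard order is available but distinct
  c <- preprocess_frame(r$frame, reorder = TRUE)
  expect_false(identical(a$pixels, c$pixels))
})
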