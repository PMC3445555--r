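test_that("the suggested threshold separates a two-valued image", {
  img <- matrix(0.2, 64, 64)
  img[20:30, 20:30] <- 0.8
  fr <- hrme_frame(img, 1, matrix(TRUE, 64, 64))
  t <- suggest_threshold(fr)
  expect_gt(t, 0.2)
  expect_lt(t, 0.8)
  expect_error(suggest_threshold(hrme_frame(matrix(0.5, 64, 64))),
               "constant")
})

test_that("the suggested threshold recovers the mask on noiseless frames", {
  r <- render_small(0.15, seed = 51, amplitude = 0)
  fr <- apply_roi(r$frame, roi_full(r$frame))
  t <- suggest_threshold(fr)
  mask <- binarize(fr, t)
  agree <- mean(mask[fr$fov] == r$truth$nuclear_mask[fr$fov])
  expect_gte(agree, 0.99)
})

test_that("the suggested threshold is affine-equivariant", {
  r <- render_small(0.15, seed = 52, noise = noise_model())
  fr <- apply_roi(r$frame, roi_full(r$frame))
  t <- suggest_threshold(fr)
  fr2 <- fr
  fr2$pixels <- 0.5 * fr$pixels + 0.1
  t2 <- suggest_threshold(fr2)
  expect_equal(t2, 0.5 * t + 0.1, tolerance = 1e-12)
})

test_that("binarize obeys its boundary and monotonicity contracts", {
  r <- render_small(0.10, seed = 53, noise = noise_model())
  fr <- apply_roi(r$frame, roi_full(r$frame))
  roi <- hrme:::frame_roi(fr)
  expect_equal(sum(binarize(fr, max(fr$pixels))), 0L)
  expect_identical(unname(binarize(fr, min(fr$pixels) - 0.01)),
                   unname(roi))
  prev <- binarize(fr, 0.2)
  for (t in c(0.35, 0.5, 0.65)) {
    cur <- binarize(fr, t)
    expect_true(all(prev[cur]))  # cur subseteq prev
    prev <- cur
  }
})

test_that("8-connected labeling matches a flood-fill oracle", {
  set.seed(99)
  for (rep in 1:3) {
    mask <- matrix(runif(64 * 64) < 0.3, 64, 64)
    lo <- label_objects(mask)
    oracle <- flood_fill_label(mask)
    expect_equal(max(lo$labeled_mask), max(oracle))
    # identical partitions: each implementation label maps to exactly
    # one oracle label and vice versa
    pairs <- unique(cbind(lo$labeled_mask[mask], oracle[mask]))
    expect_equal(nrow(pairs), max(oracle))
  }
})

test_that("labeling simple masks behaves as expected", {
  expect_equal(nrow(label_objects(matrix(FALSE, 8, 8))$objects), 0L)
  m <- matrix(FALSE, 32, 32)
  m[hrme:::disc_mask(32, 32, 4, c(8, 8))] <- TRUE
  m[hrme:::disc_mask(32, 32, 4, c(24, 24))] <- TRUE
  lo <- label_objects(m)
  expect_equal(nrow(lo$objects), 2L)
  expect_equal(sum(lo$objects$area_px), sum(m))
  # diagonal contact is one object under 8-connectivity
  d <- matrix(FALSE, 4, 4); d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_equal(nrow(label_objects(d)$objects), 1L)
})

test_that("the size filter uses strict published boundaries", {
  m <- matrix(FALSE, 120, 300)
  m[1:7, 1:7] <- TRUE          # 49 px -> removed ("fewer than 50")
  m[1:5, 20:29] <- TRUE        # 50 px -> kept
  m[20:49, 40:89] <- TRUE      # 1500 px -> kept
  m[60:98, 100:138] <- TRUE    # 39*39 = 1521 px -> removed ("more than 1500")
  seg <- filter_objects(label_objects(m))
  areas <- sort(seg$objects$area_px)
  expect_equal(areas, c(50L, 1500L))
  expect_error(filter_objects(label_objects(m), min_px = 100, max_px = 50),
               "min_px")
})

test_that("the size filter is idempotent and keeps in-range masks intact", {
  r <- render_small(0.15, seed = 54)
  fr <- preprocess_frame(r$frame)
  seg1 <- segment_frame(fr)
  seg2 <- filter_objects(seg1$labeled_mask, threshold_used =
                           seg1$threshold_used)
  expect_identical(seg1$binary_mask, seg2$binary_mask)
  expect_equal(seg1$objects$area_px, seg2$objects$area_px)
  # identity on a mask whose objects are all within [50, 1500]
  m <- matrix(FALSE, 64, 64)
  m[10:20, 10:20] <- TRUE
  seg <- filter_objects(label_objects(m))
  expect_identical(unname(seg$binary_mask), unname(m))
})

test_that("segmentation is exact on noiseless in-range synthetic frames", {
  for (seed in c(55, 56)) {
    r <- render_small(0.12, seed = seed, amplitude = 0)
    areas <- r$nuclei$area_px
    expect_true(all(areas >= 50 & areas <= 1500))
    fr <- apply_roi(r$frame, roi_full(r$frame))
    seg <- segment_frame(fr)
    expect_identical(seg$binary_mask, r$truth$nuclear_mask)
  }
})

test_that("object areas sum to the mask pixel count", {
  r <- render_small(0.18, seed = 57)
  seg <- segment_frame(preprocess_frame(r$frame))
  expect_equal(sum(seg$objects$area_px), sum(seg$binary_mask))
  expect_equal(seg$objects$label, seq_len(nrow(seg$objects)))
})
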