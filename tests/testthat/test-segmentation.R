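test_that("gaussian low-pass preserves constants and spreads peaks", {
  cst <- matrix(7, 32, 32)
  expect_equal(gaussian_lowpass(cst, sigma = 2), cst, tolerance = 1e-8)

  spot <- matrix(0, 41, 41)
  spot[21, 21] <- 100
  sm <- gaussian_lowpass(spot, sigma = 2)
  expect_lt(max(sm), 100)
  expect_gt(sum(sm > 1e-3), 1) # mass spread over a neighborhood
  expect_equal(sum(sm), 100, tolerance = 1e-6)

  # blob peak location is stable under smoothing despite uniform noise
  set.seed(11)
  blob <- matrix(0, 61, 61)
  for (r in 1:61) {
    for (c in 1:61) {
      blob[r, c] <- 50 * exp(-((r - 35)^2 + (c - 22)^2) / (2 * 9))
    }
  }
  noisy <- blob + matrix(runif(61 * 61, 0, 5), 61, 61)
  pk_before <- which(blob == max(blob), arr.ind = TRUE)
  sm <- gaussian_lowpass(noisy, sigma = 2)
  pk_after <- which(sm == max(sm), arr.ind = TRUE)
  expect_lte(max(abs(pk_after - pk_before)), 1)

  expect_error(gaussian_lowpass(cst, sigma = 0), "positive")
  expect_error(gaussian_lowpass(matrix(-1, 5, 5), 2), "non-negative")
})

test_that("hysteresis keeps low-intensity plateaus connected to a seed", {
  img <- matrix(0, 20, 20)
  expect_equal(sum(hysteresis_mask(img + 1, low = 5, high = 10)), 0)

  # plateau between the thresholds touching a bright peak: all foreground
  img <- matrix(0, 20, 20)
  img[8:12, 4:15] <- 7 # plateau, low < 7 < high
  img[10, 15] <- 20 # seed > high at the plateau edge
  m <- hysteresis_mask(img, low = 5, high = 10)
  expect_true(all(m[8:12, 4:15]))
  expect_equal(sum(m), 5 * 12)

  # disconnected blob without a seed is dropped
  img2 <- img
  img2[3:5, 3:5] <- 8
  m2 <- hysteresis_mask(img2, low = 5, high = 10)
  expect_equal(sum(m2[3:5, 3:5]), 0)
  expect_equal(m2, flood_hysteresis(img2, 5, 10))

  expect_error(hysteresis_mask(img, low = 10, high = 5), "<=")
})

test_that("hysteresis agrees with a flood-fill oracle on random fields", {
  set.seed(42)
  for (i in 1:5) {
    img <- matrix(runif(30 * 30, 0, 10), 30, 30)
    img <- gaussian_lowpass(img, 1.5)
    expect_equal(hysteresis_mask(img, 4.5, 5.5), flood_hysteresis(img, 4.5, 5.5))
    # low == high reduces to plain thresholding
    expect_equal(hysteresis_mask(img, 5, 5), img >= 5)
  }
})

test_that("opening removes sub-disc objects and spurs, and is idempotent", {
  empty <- matrix(FALSE, 15, 15)
  expect_equal(open_mask(empty, 3), empty)

  tiny <- empty
  tiny[7:8, 7:8] <- TRUE # 2x2 blob, smaller than the r = 3 disc
  expect_equal(sum(open_mask(tiny, 3)), 0)

  sq <- matrix(FALSE, 40, 40)
  sq[15:34, 15:34] <- TRUE
  sq[10:14, 24] <- TRUE # single-pixel spur
  op <- open_mask(sq, 3)
  expect_equal(sum(op[10:14, 24]), 0) # spur gone
  expect_true(all(op[18:31, 18:31]))
  expect_equal(op, brute_open(sq, 3))
  expect_equal(open_mask(op, 3), op) # idempotent
})

test_that("labeling is 8-connected with exact centroids and areas", {
  empty <- matrix(FALSE, 10, 10)
  expect_equal(nrow(mask_detections(label_mask(empty))), 0)

  m <- matrix(FALSE, 20, 20)
  m[3:5, 3:5] <- TRUE # centered at x=3, y=3 (0-based)
  m[12:16, 10:14] <- TRUE # centered at x=11, y=13
  det <- mask_detections(label_mask(m), frame = 4, channel = "nuclei")
  expect_equal(nrow(det), 2)
  expect_equal(det$x, c(3, 11))
  expect_equal(det$y, c(3, 13))
  expect_equal(det$area, c(9L, 25L))
  expect_equal(det$frame, c(4L, 4L))

  px <- matrix(FALSE, 9, 9)
  px[6, 4] <- TRUE # x = 3, y = 5 (0-based)
  d1 <- mask_detections(label_mask(px))
  expect_equal(c(d1$x, d1$y, d1$area), c(3, 5, 1))

  diagonal <- matrix(FALSE, 6, 6)
  diagonal[2, 2] <- TRUE
  diagonal[3, 3] <- TRUE
  expect_equal(max(label_mask(diagonal)), 1) # 8-connectivity joins diagonals
})

test_that("nucleus counting flags clumps and respects the count invariant", {
  green <- matrix(0L, 30, 30)
  green[5:15, 5:15] <- 1L # object 1
  green[20:28, 20:28] <- 2L # object 2
  det <- dplyr::bind_rows(
    make_nucleus_detections(0, x = c(7, 12, 24, 2), y = c(7, 12, 24, 2)),
    tibble::tibble(
      frame = 0L, channel = "microtubules", object_label = 1:2,
      x = c(10, 24), y = c(10, 24), area = c(121L, 81L)
    )
  )
  out <- count_nuclei(det, green)
  g <- dplyr::filter(out, channel == "microtubules")
  r <- dplyr::filter(out, channel == "nuclei")
  expect_equal(g$nucleus_count, c(2L, 1L))
  expect_equal(g$is_clump, c(TRUE, FALSE))
  expect_equal(r$green_object, c(1L, 1L, 2L, NA)) # last centroid on background
  expect_equal(r$green_is_clump, c(TRUE, TRUE, FALSE, FALSE))
  expect_lte(sum(g$nucleus_count), nrow(r))

  bad <- det
  bad$frame <- c(0L, 1L, 0L, 0L, 0L, 0L)
  expect_error(count_nuclei(bad, green), "one frame")
})

test_that("noise-free rendered frames segment to the true cell count", {
  spec <- synth_spec(
    n_frames = 3, n_interactions = 0, n_cells = 4, noise_sd = 0,
    frame_shape = c(256, 336), seed = 5
  )
  movie <- render_movie(simulate_trajectories(spec))
  det <- segment_movie(movie, synthetic_segment_params(spec))
  per <- dplyr::count(det, frame, channel)
  expect_true(all(per$n == 4))
})
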