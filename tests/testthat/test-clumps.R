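test_that("clump codes follow the positional base-1000 construction", {
  expect_equal(encode_clump_code(c(2, 1)), 2001)
  expect_equal(encode_clump_code(c(1, 2)), 2001) # order-insensitive
  expect_equal(encode_clump_code(c(3, 2)), 3002)
  expect_equal(encode_clump_code(c(5, 3, 2)), 5003002)
  expect_equal(encode_clump_code(7), 7)
  expect_equal(encode_clump_code(c(1, 2, 3, 5)), 5003002001)
  expect_equal(decode_clump_code(24013), c(13L, 24L))
  expect_equal(decode_clump_code(0), integer(0))
  expect_equal(decode_clump_code(5003002), c(2L, 3L, 5L))
  expect_error(encode_clump_code(c(1, 1000)), "base")
  expect_error(encode_clump_code(c(4, 4)), "distinct")
  # configurable base
  expect_equal(encode_clump_code(c(3, 2), base = 10), 32)
  expect_equal(decode_clump_code(32, base = 10), c(2L, 3L))
})

test_that("codes are permutation-invariant and collision-free", {
  set.seed(9)
  for (i in 1:50) {
    labels <- sample(999, sample(2:4, 1))
    codes <- apply(
      matrix(unlist(lapply(1:6, function(j) sample(labels))), ncol = 6), 2,
      encode_clump_code
    )
    expect_equal(length(unique(codes)), 1)
  }
  # brute-force injectivity over all pairs and singletons with labels <= 50
  pairs <- utils::combn(50, 2)
  codes <- c(
    apply(pairs, 2, encode_clump_code),
    vapply(1:50, encode_clump_code, numeric(1))
  )
  expect_equal(anyDuplicated(codes), 0)
})

test_that("track annotation stamps shared-object codes per frame", {
  tracks <- dplyr::bind_rows(
    straight_track(0:4, start = c(0, 0), label = 1),
    straight_track(0:4, start = c(0, 10), label = 2),
    straight_track(0:4, start = c(0, 20), label = 3),
    straight_track(0:4, start = c(0, 30), label = 5)
  )
  tracks$det_id <- seq_len(nrow(tracks))
  det <- make_nucleus_detections(
    frame = tracks$frame, x = tracks$x, y = tracks$y,
    green_object = c(
      rep(1, 5), rep(1, 5), # tracks 1, 2 share object 1 every frame
      rep(2, 5), rep(3, 5)
    ),
    green_is_clump = c(rep(TRUE, 10), rep(FALSE, 10))
  )
  det$det_id <- tracks$det_id
  ann <- annotate_clumps(tracks, det)
  expect_equal(unique(ann$clump_code[ann$track_label %in% c(1, 2)]), 2001)
  expect_equal(unique(ann$clump_code[ann$track_label %in% c(3, 5)]), 0)

  # four tracks merged into one object on one frame
  det4 <- det
  det4$green_object[det4$frame == 3] <- 9L
  det4$green_is_clump[det4$frame == 3] <- TRUE
  ann4 <- annotate_clumps(tracks, det4)
  expect_equal(unique(ann4$clump_code[ann4$frame == 3]), 5003002001)
})

test_that("clump spans are maximal runs of identical codes", {
  tr <- straight_track(0:6, label = 1)
  tr$clump_code <- c(0, 0, 2001, 2001, 2001, 0, 0)
  sp <- find_clump_spans(tr, S = 5)
  expect_equal(nrow(sp), 1)
  expect_equal(sp$t_k0, 2)
  expect_equal(sp$t_kC, 4)
  expect_equal(sp$TC, 3L)

  tr$clump_code <- rep(0, 7)
  expect_equal(nrow(find_clump_spans(tr, 5)), 0)

  tr$clump_code <- c(0, 2001, 0, 2001, 0, 0, 0)
  sp2 <- find_clump_spans(tr, 5)
  expect_equal(sp2$TC, c(1L, 1L))
  expect_equal(sp2$t_k0, c(1, 3))

  # a code change mid-overlap splits the run
  tr$clump_code <- c(0, 2001, 2001, 3002001, 2001, 2001, 0)
  expect_equal(nrow(find_clump_spans(tr, 5)), 3)
})

test_that("case selection applies the two-cell in-and-out criteria", {
  S <- 5
  mk <- function(label, codes) {
    tr <- straight_track(seq_along(codes) - 1, start = c(0, 10 * label),
      label = label
    )
    tr$clump_code <- codes
    tr
  }
  codes_ok <- c(rep(0, 10), rep(2001, 3), rep(0, 10))
  tracks <- dplyr::bind_rows(
    mk(1, codes_ok), mk(2, codes_ok),
    mk(3, c(rep(0, 10), rep(5004003, 3), rep(0, 10))), # 3-member clump
    mk(4, c(rep(0, 10), rep(5004003, 3), rep(0, 10))),
    mk(5, c(rep(0, 10), rep(5004003, 3), rep(0, 10)))
  )
  # track 6 enters a clump but the movie ends 2 frames later
  tracks <- dplyr::bind_rows(
    tracks,
    mk(6, c(rep(0, 10), rep(7006, 3), 0, 0)),
    mk(7, c(rep(0, 10), rep(7006, 3), rep(0, 10)))
  )
  spans <- find_clump_spans(tracks, S)
  cases <- select_cases(tracks, spans, S)
  expect_equal(sort(cases$track_label), c(1L, 2L, 7L))
  expect_false(6 %in% cases$track_label) # post-window incomplete
  expect_true(all(!cases$track_label %in% 3:5)) # 3-member clumps excluded
  # both partners valid -> flagged and linked by the shared code
  both <- dplyr::filter(cases, code == 2001)
  expect_equal(nrow(both), 2)
  expect_true(all(both$partner_valid))
  expect_false(dplyr::filter(cases, code == 7006)$partner_valid)
  expect_equal(cases$control_start, cases$t_k0 - 2L * S)
  # the independent validator agrees with every selected case
  expect_true(all(validate_cases(tracks, cases)))
})

test_that("TC stratification filters on either side of the threshold", {
  cases <- tibble::tibble(case_id = 1:3, TC = c(3L, 19L, 12L))
  expect_equal(stratify_by_tc(cases, 10, "le")$TC, 3L)
  expect_equal(stratify_by_tc(cases, 12, "le")$TC, c(3L, 12L))
  expect_equal(stratify_by_tc(cases, 10, "gt")$TC, c(19L, 12L))
  expect_equal(stratify_by_tc(cases, 12, "lt")$TC, 3L)
  expect_equal(nrow(stratify_by_tc(cases, Inf, "le")), 3)
})
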