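test_that("entry and exit vectors span the S-frame windows around the clump", {
  # straight track, unit speed along +x, clump frames 10..12
  tr <- straight_track(0:20, start = c(0, 0), heading = c(1, 0))
  expect_equal(entry_vector(tr, t_k0 = 10, S = 5), c(4, 0))
  expect_equal(exit_vector(tr, t_kC = 12, S = 5), c(4, 0))

  # positions printed for a fixture: hand-subtracted differences
  fix <- tibble::tibble(
    frame = 5:15,
    x = c(0, 1, 3, 6, 10, 15, 21, 28, 36, 45, 55),
    y = c(0, 2, 3, 5, 8, 8, 9, 11, 14, 18, 23)
  )
  expect_equal(entry_vector(fix, t_k0 = 11, S = 5), c(15 - 1, 8 - 2))
  expect_equal(exit_vector(fix, t_kC = 10, S = 5), c(55 - 21, 23 - 9))

  # stationary cell: zero vector, flagged degenerate downstream
  st <- straight_track(0:20, heading = c(0, 0))
  expect_equal(entry_vector(st, 10, 5), c(0, 0))
  expect_error(entry_vector(tr, t_k0 = 4, S = 5), "missing")

  # U-turn: exit antiparallel to entry
  ut <- dplyr::bind_rows(
    tibble::tibble(frame = 0:12, x = 0:12, y = 0),
    tibble::tibble(frame = 13:25, x = 12 - (1:13), y = 0)
  )
  ent <- entry_vector(ut, t_k0 = 10, S = 5)
  ext <- exit_vector(ut, t_kC = 12, S = 5)
  expect_equal(ext, -ent)
})

test_that("incidence rotation aligns entry with +x' and preserves distances", {
  pts <- rbind(c(1, 2), c(3, 5), c(-2, 0.5))
  # entry already along +x: identity
  r0 <- incidence_rotation(pts, entry = c(3, 0))
  expect_equal(r0$incidence, 0)
  expect_equal(unname(r0$points), pts)
  # entry along +y: rotation by -pi/2
  r1 <- incidence_rotation(rbind(c(0, 1)), entry = c(0, 2))
  expect_equal(r1$incidence, pi / 2)
  expect_equal(unname(r1$points), rbind(c(1, 0)), tolerance = 1e-12)
  # pairwise distances preserved for random clouds and entries
  set.seed(14)
  for (i in 1:20) {
    cloud <- matrix(rnorm(20), ncol = 2)
    entry <- rnorm(2)
    origin <- rnorm(2)
    rot <- incidence_rotation(cloud, entry, origin = origin)$points
    expect_equal(as.vector(dist(rot)), as.vector(dist(cloud)), tolerance = 1e-9)
  }
  expect_error(incidence_rotation(pts, c(0, 0)), "degenerate")
})

test_that("delta direction matches the cross/dot oracle and wraps to [-pi, pi]", {
  expect_equal(delta_direction(c(2, 0), c(2, 0)), 0)
  expect_equal(delta_direction(c(1, 0), c(0, 1)), pi / 2) # CCW positive
  expect_equal(delta_direction(c(1, 0), c(0, -1)), -pi / 2)
  set.seed(3)
  for (i in 1:200) {
    entry <- rnorm(2)
    exit <- rnorm(2)
    th <- delta_direction(entry, exit)
    expect_equal(th, atan2_angle(entry, exit), tolerance = 1e-12)
    expect_lte(abs(th), pi)
    # invariance under global rotation; mirroring negates the angle
    phi <- runif(1, 0, 2 * pi)
    rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
    expect_equal(
      delta_direction(as.vector(rot %*% entry), as.vector(rot %*% exit)), th,
      tolerance = 1e-12
    )
    mir <- c(1, -1)
    expect_equal(delta_direction(entry * mir, exit * mir), -th,
      tolerance = 1e-12
    )
  }
  expect_error(delta_direction(c(1, 0), c(0, 0)), "degenerate")
})

test_that("control angle mirrors the contact geometry on pre-clump frames", {
  # straight control window: zero angle
  tr <- straight_track(0:20, heading = c(2, 1))
  expect_equal(control_delta_direction(tr, t_k0 = 12, S = 5), 0)

  # track turning +30 degrees exactly at t_k0 - S
  S <- 5
  t_k0 <- 12
  h1 <- c(2, 0)
  h2 <- as.vector(matrix(
    c(cos(pi / 6), sin(pi / 6), -sin(pi / 6), cos(pi / 6)), 2, 2
  ) %*% h1)
  pos <- matrix(0, 21, 2)
  for (t in 1:20) {
    h <- if (t <= t_k0 - S - 1) h1 else h2
    pos[t + 1, ] <- pos[t, ] + h
  }
  turn <- tibble::tibble(frame = 0:20, x = pos[, 1], y = pos[, 2])
  expect_equal(control_delta_direction(turn, t_k0, S), pi / 6, tolerance = 1e-12)
  expect_error(control_delta_direction(tr, t_k0 = 9, S = 5), "missing")
})

test_that("theta is invariant under rigid motions of the whole track table", {
  spec <- synth_spec(n_frames = 30, n_interactions = 2, turn = 40, TC = 4, seed = 21)
  tracks <- ground_truth_tracks(simulate_trajectories(spec))
  spans <- find_clump_spans(tracks, 5)
  cases <- select_cases(tracks, spans, 5)
  ang <- measure_angles(tracks, cases)
  expect_gt(nrow(cases), 0)
  phi <- 1.1
  moved <- dplyr::mutate(tracks,
    xr = cos(phi) * x - sin(phi) * y + 40,
    yr = sin(phi) * x + cos(phi) * y - 17, x = xr, y = yr
  )
  ang2 <- measure_angles(moved, cases)
  expect_equal(ang2$theta_deg, ang$theta_deg, tolerance = 1e-9)
  mirrored <- dplyr::mutate(tracks, y = -y)
  ang3 <- measure_angles(mirrored, cases)
  expect_equal(ang3$theta_deg, -ang$theta_deg, tolerance = 1e-9)
})

test_that("measured angles recover programmed turns on ground-truth tracks", {
  spec <- synth_spec(
    n_frames = 35, n_interactions = 3, turn = 55, TC = 2, seed = 8
  )
  truth <- simulate_trajectories(spec)
  tracks <- ground_truth_tracks(truth)
  cases <- select_cases(tracks, find_clump_spans(tracks, 5), 5)
  expect_equal(nrow(cases), 6) # both partners of all three contacts
  ang <- measure_angles(tracks, cases)
  contact <- dplyr::filter(ang, kind == "contact")
  control <- dplyr::filter(ang, kind == "control")
  expect_equal(contact$theta_deg, rep(55, 6), tolerance = 1e-9)
  expect_equal(control$theta_deg, rep(0, 6), tolerance = 1e-9)
  expect_false(any(ang$degenerate))

  # a stationary cell yields degenerate (NA) angles, not an error
  st <- straight_track(0:25, heading = c(0, 0))
  fake_case <- tibble::tibble(
    case_id = 1L, track_label = 1L, partner_label = 2L, code = 2001,
    t_k0 = 12L, t_kC = 14L, TC = 3L, S = 5L, control_start = 2L,
    partner_valid = FALSE
  )
  a <- measure_angles(st, fake_case)
  expect_true(all(a$degenerate))
  expect_true(all(is.na(a$theta_deg)))
})
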