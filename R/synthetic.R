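# Ground-truthed synthetic two-channel movies.
#
# The generator emulates the study data: bright compact nuclei (Gaussian
# spots, red channel) inside larger, dimmer microtubule bodies (flat discs,
# green channel), cells moving at roughly constant velocity, and scheduled
# pairwise contacts in which the two microtubule discs fuse for a programmed
# number of frames (TC) after which each cell departs with its entry heading
# rotated by a programmed turn angle. Additive Gaussian noise is applied at
# render time. All randomness flows from the single spec seed.
#
# Contact geometry. Each scheduled pair approaches on an antiparallel flyby
# with lateral separation d_sep, takes one small lateral step into a hold
# separation d_hold for exactly TC frames, steps back out, and departs along
# the turned heading. d_hold = 1.7 * cell_radius keeps the discs robustly
# fused while the nuclei stay well separated, and d_sep = d_hold + 7 px
# keeps the discs robustly apart outside the hold; the single-frame lateral
# step (3.5 px) stays inside the keyhole tolerance circle even after
# centroid-estimation noise. The rendered green
# merge interval therefore equals the programmed TC frames exactly, with no
# ambiguous partially-fused frames. The side each cell holds on is chosen so
# that the turned departure headings diverge.

#' Specification of a synthetic movie
#'
#' @param n_frames Number of frames.
#' @param frame_shape `c(n_h, n_w)` frame size in pixels.
#' @param n_interactions Number of scheduled two-cell contacts; each uses its
#'   own region of the frame (at most 12 regions at the default frame size).
#' @param turn Turn angle (degrees, counter-clockwise) applied to both cells
#'   of every contact when `interactions` is not supplied.
#' @param TC Programmed time in clump (frames) for every contact when
#'   `interactions` is not supplied.
#' @param interactions Optional data frame scheduling contacts explicitly:
#'   columns `cell_a`, `cell_b`, `t_start`, `TC`, `turn_a`, `turn_b`
#'   (turns in degrees). Cells must be consecutive pairs `(1,2), (3,4), ...`
#'   and each cell may appear in at most one contact.
#' @param n_cells Total cells; defaults to `2 * n_interactions`. Extra cells
#'   are solitary wanderers with heading jitter.
#' @param nucleus_radius Nucleus spot radius (px); rendered as a Gaussian
#'   with sigma `nucleus_radius / 2`.
#' @param cell_radius Microtubule disc radius (px).
#' @param nucleus_intensity,cell_intensity Peak intensities (arbitrary units).
#' @param speed Cell speed in pixels/frame.
#' @param noise_sd Additive Gaussian noise sd at render time (intensity
#'   units; default 10% of the nucleus peak).
#' @param heading_jitter_deg Per-frame heading jitter (degrees, sd) applied
#'   to solitary cells; scheduled pairs follow exact piecewise paths.
#' @param seed Integer seed; seeded runs are bit-reproducible.
#' @return A list of class `synth_spec`.
#' @export
synth_spec <- function(n_frames = 40, frame_shape = c(512, 672),
                       n_interactions = 0, turn = 30, TC = 3,
                       interactions = NULL, n_cells = NULL,
                       nucleus_radius = 4, cell_radius = 12,
                       nucleus_intensity = 200, cell_intensity = 120,
                       speed = 2, noise_sd = 20, heading_jitter_deg = 2,
                       seed = 1) {
  if (is.null(interactions) && n_interactions > 0) {
    t_max <- n_frames - TC - 5 - 3
    if (t_max < 12) abort("`n_frames` too small for the scheduled contacts.")
    starts <- round(seq(12, t_max, length.out = n_interactions))
    interactions <- tibble(
      cell_a = seq_len(n_interactions) * 2L - 1L,
      cell_b = seq_len(n_interactions) * 2L,
      t_start = as.integer(starts), TC = as.integer(TC),
      turn_a = turn, turn_b = turn
    )
  }
  if (is.null(interactions)) {
    interactions <- tibble(
      cell_a = integer(), cell_b = integer(), t_start = integer(),
      TC = integer(), turn_a = double(), turn_b = double()
    )
  }
  interactions <- as_tibble(interactions)
  if (is.null(n_cells)) n_cells <- max(2 * nrow(interactions), 1)
  spec <- structure(
    list(
      n_frames = n_frames, frame_shape = frame_shape, n_cells = n_cells,
      nucleus_radius = nucleus_radius, cell_radius = cell_radius,
      nucleus_intensity = nucleus_intensity, cell_intensity = cell_intensity,
      speed = speed, noise_sd = noise_sd,
      heading_jitter_deg = heading_jitter_deg,
      interactions = interactions, seed = as.integer(seed)
    ),
    class = "synth_spec"
  )
  validate_synth_spec(spec)
  spec
}

validate_synth_spec <- function(spec) {
  ia <- spec$interactions
  cells <- c(ia$cell_a, ia$cell_b)
  if (anyDuplicated(cells)) {
    abort("infeasible schedule: a cell appears in more than one contact.")
  }
  if (nrow(ia) > 0) {
    if (any(cells < 1 | cells > spec$n_cells)) {
      abort("interactions reference cells outside 1..n_cells.")
    }
    if (any(ia$t_start < 12)) {
      abort("contacts must start at frame >= 12 (full control window).")
    }
    if (any(ia$t_start + ia$TC + 4 >= spec$n_frames)) {
      abort("contact exit window runs past the end of the movie.")
    }
  }
  n_regions <- 12
  if (nrow(ia) + max(0, spec$n_cells - 2 * nrow(ia)) > n_regions) {
    abort("too many cells/contacts for the 12 frame regions.")
  }
  invisible(spec)
}

rot2 <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
}

# Region centers: 3 columns x 4 rows over the frame.
region_centers <- function(frame_shape) {
  n_h <- frame_shape[1]
  n_w <- frame_shape[2]
  grid <- expand.grid(col = 1:3, row = 1:4)
  cbind(
    x = (grid$col - 0.5) * n_w / 3,
    y = (grid$row - 0.5) * n_h / 4
  )
}

# One pair's local-coordinate trajectory (before per-pair rotation and
# translation). Returns list(a, b): n_frames x 2 matrices.
pair_paths <- function(t0, TC, turn_a, turn_b, n_frames, speed,
                       d_hold, d_sep) {
  t_end <- t0 + TC - 1
  freeze <- min(n_frames - 1, t_end + 8)
  step <- speed
  for (s in c(1, -1)) {
    lat_a <- -s * d_sep / 2
    lat_b <- s * d_sep / 2
    ha <- as.vector(rot2(turn_a) %*% c(step, 0))
    hb <- as.vector(rot2(turn_b) %*% c(-step, 0))
    # cell a travels +x, b travels -x; both aligned at x = 0 at t0 - 1
    pa <- matrix(NA_real_, n_frames, 2)
    pb <- matrix(NA_real_, n_frames, 2)
    m0 <- t0 - 11
    for (t in 0:(n_frames - 1)) {
      tt <- max(t, m0)
      if (tt <= t0 - 1) {
        pa[t + 1, ] <- c(-step * (t0 - 1 - tt), lat_a)
        pb[t + 1, ] <- c(step * (t0 - 1 - tt), lat_b)
      } else if (tt <= t_end) {
        pa[t + 1, ] <- c(0, -s * d_hold / 2)
        pb[t + 1, ] <- c(0, s * d_hold / 2)
      } else {
        j <- min(tt, freeze) - (t_end + 1)
        pa[t + 1, ] <- c(0, lat_a) + j * ha
        pb[t + 1, ] <- c(0, lat_b) + j * hb
      }
    }
    post <- (t_end + 2):(n_frames)
    d_post <- sqrt(rowSums((pa[post, , drop = FALSE] -
      pb[post, , drop = FALSE])^2))
    if (all(d_post >= d_sep - 1)) {
      return(list(a = pa, b = pb))
    }
  }
  abort("infeasible schedule: turned departure headings do not diverge.")
}

#' Simulate ground-truth trajectories
#'
#' @param spec A [synth_spec()] object.
#' @return A list of class `synthetic_truth` with tibbles `positions`
#'   (`frame`, `cell`, `x`, `y`), `clumps` (`cell_a`, `cell_b`, `t_start`,
#'   `t_end`, `TC`, `code`), `turns` (`cell`, `turn_deg`), and the `spec`.
#' @export
simulate_trajectories <- function(spec) {
  set.seed(spec$seed)
  centers <- region_centers(spec$frame_shape)
  ia <- spec$interactions
  n_pairs <- nrow(ia)
  d_hold <- 1.7 * spec$cell_radius
  d_sep <- d_hold + 7
  pos <- matrix(NA_real_, spec$n_frames * spec$n_cells, 2)
  cell_of <- rep(seq_len(spec$n_cells), each = spec$n_frames)
  frame_of <- rep(0:(spec$n_frames - 1), spec$n_cells)
  used_regions <- integer(0)
  for (k in seq_len(n_pairs)) {
    paths <- pair_paths(
      ia$t_start[k], ia$TC[k], ia$turn_a[k], ia$turn_b[k],
      spec$n_frames, spec$speed, d_hold, d_sep
    )
    phi <- runif(1, 0, 360)
    center <- centers[k, ] + c(runif(1, -8, 8), runif(1, -5, 5))
    place <- function(p) {
      sweep(p %*% t(rot2(phi)), 2, center, FUN = "+")
    }
    pos[cell_of == ia$cell_a[k], ] <- place(paths$a)
    pos[cell_of == ia$cell_b[k], ] <- place(paths$b)
    used_regions <- c(used_regions, k)
  }
  solo <- setdiff(seq_len(spec$n_cells), c(ia$cell_a, ia$cell_b))
  free_regions <- setdiff(seq_len(nrow(centers)), used_regions)
  # wander box sized so neighbouring regions stay > 2 cell radii apart
  spacing <- min(spec$frame_shape[2] / 3, spec$frame_shape[1] / 4)
  box_half <- max(12, spacing / 2 - spec$cell_radius - 4)
  for (i in seq_along(solo)) {
    center <- centers[free_regions[i], ]
    heading <- runif(1, 0, 2 * pi)
    p <- matrix(NA_real_, spec$n_frames, 2)
    p[1, ] <- center + runif(2, -10, 10)
    for (t in 2:spec$n_frames) {
      heading <- heading + rnorm(1, 0, spec$heading_jitter_deg) * pi / 180
      cand <- p[t - 1, ] + spec$speed * c(cos(heading), sin(heading))
      # reflect off the region box
      for (dim in 1:2) {
        if (abs(cand[dim] - center[dim]) > box_half) {
          heading <- if (dim == 1) pi - heading else -heading
          cand <- p[t - 1, ] + spec$speed * c(cos(heading), sin(heading))
        }
      }
      p[t, ] <- cand
    }
    pos[cell_of == solo[i], ] <- p
  }
  positions <- tibble(
    frame = frame_of, cell = cell_of, x = pos[, 1], y = pos[, 2]
  ) |> arrange(frame, cell)
  clumps <- if (n_pairs > 0) {
    tibble(
      cell_a = ia$cell_a, cell_b = ia$cell_b, t_start = ia$t_start,
      t_end = ia$t_start + ia$TC - 1L, TC = ia$TC,
      code = purrr::map2_dbl(ia$cell_a, ia$cell_b, ~ encode_clump_code(c(.x, .y)))
    )
  } else {
    tibble(
      cell_a = integer(), cell_b = integer(), t_start = integer(),
      t_end = integer(), TC = integer(), code = double()
    )
  }
  turns <- tibble(
    cell = c(ia$cell_a, ia$cell_b), turn_deg = c(ia$turn_a, ia$turn_b)
  )
  structure(
    list(positions = positions, clumps = clumps, turns = turns, spec = spec),
    class = "synthetic_truth"
  )
}

render_cell_patch <- function(img, cx, cy, radius, value, gaussian) {
  nr <- nrow(img)
  nc <- ncol(img)
  extent <- if (gaussian) ceiling(radius * 2.5) else ceiling(radius + 1)
  r0 <- max(1, floor(cy + 1 - extent))
  r1 <- min(nr, ceiling(cy + 1 + extent))
  c0 <- max(1, floor(cx + 1 - extent))
  c1 <- min(nc, ceiling(cx + 1 + extent))
  if (r0 > r1 || c0 > c1) {
    return(img)
  }
  yy <- (r0:r1) - 1 - cy
  xx <- (c0:c1) - 1 - cx
  d2 <- outer(yy^2, xx^2, "+")
  patch <- if (gaussian) {
    sigma <- radius / 2
    value * exp(-d2 / (2 * sigma^2))
  } else {
    value * (d2 <= radius^2)
  }
  img[r0:r1, c0:c1] <- pmax(img[r0:r1, c0:c1], patch)
  img
}

#' Render a synthetic movie from ground-truth trajectories
#'
#' Nuclei are Gaussian spots (sigma `nucleus_radius / 2`, peak
#' `nucleus_intensity`) in the red channel; microtubule bodies are flat discs
#' (radius `cell_radius`, level `cell_intensity`) in the green channel.
#' Overlapping discs fuse into one connected object. Additive Gaussian noise
#' (sd `noise_sd`) is applied to both channels and clipped at zero.
#'
#' @param truth A `synthetic_truth` object from [simulate_trajectories()].
#' @return A list of class `synthetic_movie`: one element per frame, each a
#'   list with `red` and `green` intensity matrices.
#' @export
render_movie <- function(truth) {
  spec <- truth$spec
  set.seed(spec$seed + 1L)
  shape <- spec$frame_shape
  by_frame <- split(truth$positions, truth$positions$frame)
  frames <- purrr::map(by_frame, function(pf) {
    red <- matrix(0, shape[1], shape[2])
    green <- matrix(0, shape[1], shape[2])
    for (i in seq_len(nrow(pf))) {
      red <- render_cell_patch(
        red, pf$x[i], pf$y[i], spec$nucleus_radius,
        spec$nucleus_intensity,
        gaussian = TRUE
      )
      green <- render_cell_patch(
        green, pf$x[i], pf$y[i], spec$cell_radius, spec$cell_intensity,
        gaussian = FALSE
      )
    }
    if (spec$noise_sd > 0) {
      red <- red + rnorm(length(red), 0, spec$noise_sd)
      green <- green + rnorm(length(green), 0, spec$noise_sd)
      red[red < 0] <- 0
      green[green < 0] <- 0
    }
    list(red = red, green = green)
  })
  structure(unname(frames), class = "synthetic_movie", spec = spec)
}

#' Segmentation parameters matched to a synthetic movie
#'
#' Fixed hysteresis thresholds derived from the known rendered peaks (rather
#' than the adaptive per-frame defaults): the blurred nucleus peak halves
#' under the sigma-2 low-pass, so the red thresholds are 0.15/0.35 of the
#' nucleus peak; the green thresholds are 0.45/0.70 of the disc level with a
#' gentler sigma-1 low-pass so the fused/apart transition of neighbouring
#' discs stays sharp.
#'
#' @param spec A [synth_spec()] object.
#' @return A [segment_params()] object.
#' @export
synthetic_segment_params <- function(spec) {
  segment_params(
    sigma = c(nuclei = 2, microtubules = 1),
    low = c(
      nuclei = 0.15 * spec$nucleus_intensity,
      microtubules = 0.45 * spec$cell_intensity
    ),
    high = c(
      nuclei = 0.35 * spec$nucleus_intensity,
      microtubules = 0.70 * spec$cell_intensity
    ),
    open_radius = 3
  )
}

#' Ground-truth track table
#'
#' The true trajectories in the tracks-table schema (cell ids as track
#' labels, velocities as per-frame position differences, clump codes from the
#' programmed contact intervals), enabling stage-isolation tests of the
#' clump/direction modules without segmentation or tracking.
#'
#' @param truth A `synthetic_truth` object.
#' @return A tracks tibble (`frame`, `x`, `y`, `vx`, `vy`, `speed`,
#'   `track_label`, `clump_code`).
#' @export
ground_truth_tracks <- function(truth) {
  tr <- truth$positions |>
    arrange(cell, frame) |>
    group_by(cell) |>
    mutate(
      vx = x - lag(x, default = NA), vy = y - lag(y, default = NA)
    ) |>
    ungroup() |>
    mutate(
      vx = ifelse(is.na(vx), 0, vx), vy = ifelse(is.na(vy), 0, vy),
      speed = sqrt(vx^2 + vy^2), track_label = cell, clump_code = 0
    )
  for (i in seq_len(nrow(truth$clumps))) {
    cl <- truth$clumps[i, ]
    sel <- tr$cell %in% c(cl$cell_a, cl$cell_b) &
      tr$frame >= cl$t_start & tr$frame <= cl$t_end
    tr$clump_code[sel] <- cl$code
  }
  select(tr, frame, x, y, vx, vy, speed, track_label, clump_code)
}

#' Write ground truth to CSV files
#'
#' @param truth A `synthetic_truth` object.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the written `tracks.csv` and `clumps.csv`.
#' @export
export_ground_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tracks_path <- file.path(dir, "tracks.csv")
  clumps_path <- file.path(dir, "clumps.csv")
  write_tracks(ground_truth_tracks(truth), tracks_path)
  readr::write_csv(truth$clumps, clumps_path)
  invisible(c(tracks = tracks_path, clumps = clumps_path))
}
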