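# Keyhole-style nucleus tracking.
#
# Linking works on triplets of frames: parent (t-1), present (t), child (t+1).
# From the parent and present positions the next position is extrapolated
# linearly, and candidate detections are gated by a "keyhole" region: the
# union of a narrow wedge centered on the direction of motion (anticipating
# continued motion) and a circle around the present position (tolerating
# stops and reversals). For stationary or newborn tracks the keyhole
# degenerates to the circle alone.

#' Tracking parameters
#'
#' @param wedge_half_angle Half-opening angle of the forward wedge, degrees.
#' @param wedge_length_factor Wedge length as a multiple of the last
#'   per-frame displacement.
#' @param r_min Minimum radius (pixels) of the tolerance circle around the
#'   present position; the effective radius is
#'   `max(|present - parent|, r_min)`.
#' @return A list of class `track_params`.
#' @export
track_params <- function(wedge_half_angle = 30, wedge_length_factor = 3,
                         r_min = 5) {
  structure(
    list(
      wedge_half_angle = wedge_half_angle,
      wedge_length_factor = wedge_length_factor, r_min = r_min
    ),
    class = "track_params"
  )
}

#' Predict the next position by linear extrapolation
#'
#' @param parent,present Numeric `c(x, y)` positions at frames `t - 1` and
#'   `t` of the same track.
#' @return Numeric `c(x, y)`: `present + (present - parent)`.
#' @export
predict_position <- function(parent, present) {
  present + (present - parent)
}

#' Keyhole membership test
#'
#' Returns whether candidate points fall inside the keyhole region spawned by
#' a track's parent and present positions: the union of a wedge of half-angle
#' `wedge_half_angle` around the motion direction (length
#' `wedge_length_factor * |present - parent|`) and a circle of radius
#' `max(|present - parent|, r_min)` around the present position. For
#' zero-velocity tracks the region is the circle alone.
#'
#' @param x,y Candidate coordinates (vectors).
#' @param parent,present Numeric `c(x, y)` positions; `parent` may be `NULL`
#'   for a track with a single point (no velocity yet).
#' @param params A [track_params()] object.
#' @return Logical vector.
#' @export
in_keyhole <- function(x, y, parent, present, params = track_params()) {
  dx <- x - present[1]
  dy <- y - present[2]
  dist <- sqrt(dx^2 + dy^2)
  if (is.null(parent)) {
    v <- c(0, 0)
  } else {
    v <- present - parent
  }
  vnorm <- sqrt(sum(v^2))
  inside <- dist <= max(vnorm, params$r_min)
  if (vnorm > 0) {
    cosang <- (dx * v[1] + dy * v[2]) / (dist * vnorm)
    cosang[dist == 0] <- 1
    in_wedge <- dist <= params$wedge_length_factor * vnorm &
      cosang >= cos(params$wedge_half_angle * pi / 180)
    inside <- inside | in_wedge
  }
  inside
}

#' Keyhole region as a predicate
#'
#' @inheritParams in_keyhole
#' @return A function `f(x, y)` returning logical membership.
#' @export
keyhole_region <- function(parent, present, params = track_params()) {
  force(parent)
  force(present)
  force(params)
  function(x, y) in_keyhole(x, y, parent, present, params)
}

# Link one frame of detections to the active tracks (greedy nearest
# predicted-position assignment, keyhole-gated; ties broken by lower track
# label). Returns an integer vector: for each detection row, the track label
# it joins, or NA.
link_frame <- function(active, det_xy, params) {
  n_det <- nrow(det_xy)
  assignment <- rep(NA_integer_, n_det)
  if (length(active) == 0 || n_det == 0) {
    return(assignment)
  }
  pairs <- purrr::map(active, function(tr) {
    parent <- tr$parent
    present <- tr$present
    ok <- in_keyhole(det_xy[, 1], det_xy[, 2], parent, present, params)
    if (!any(ok)) {
      return(NULL)
    }
    pred <- if (is.null(parent)) present else predict_position(parent, present)
    d <- sqrt((det_xy[ok, 1] - pred[1])^2 + (det_xy[ok, 2] - pred[2])^2)
    tibble(label = tr$label, det = which(ok), dist = d)
  })
  pairs <- bind_rows(pairs)
  if (nrow(pairs) == 0) {
    return(assignment)
  }
  pairs <- arrange(pairs, dist, label)
  taken_track <- integer(0)
  for (i in seq_len(nrow(pairs))) {
    lab <- pairs$label[i]
    det <- pairs$det[i]
    if (!is.na(assignment[det]) || lab %in% taken_track) next
    assignment[det] <- lab
    taken_track <- c(taken_track, lab)
  }
  assignment
}

#' Build tracks from per-frame nucleus detections
#'
#' Links nucleus detections frame to frame with the keyhole gate. Each track
#' claims at most one detection per frame and vice versa; conflicts are
#' resolved by nearest distance to the predicted position (ties to the lower
#' track label). Unclaimed detections start new tracks, labeled in order of
#' creation starting at 1. A track that misses a frame is terminated.
#'
#' @param detections Detections tibble (only `channel == "nuclei"` rows are
#'   used) with columns `frame`, `x`, `y` and optionally `det_id`.
#' @param params A [track_params()] object.
#' @return A tracks tibble with columns `frame`, `x`, `y`, `vx`, `vy`,
#'   `speed`, `track_label`, `clump_code` (0; filled by [annotate_clumps()])
#'   and `det_id`. Velocity is the position difference from the previous
#'   frame; zero at each track's first point.
#' @export
build_tracks <- function(detections, params = track_params()) {
  det <- filter(detections, channel == "nuclei")
  if (!"det_id" %in% names(det)) det$det_id <- seq_len(nrow(det))
  empty <- tibble(
    frame = integer(), x = double(), y = double(), vx = double(),
    vy = double(), speed = double(), track_label = integer(),
    clump_code = double(), det_id = integer()
  )
  if (nrow(det) == 0) {
    return(empty)
  }
  det <- arrange(det, frame, det_id)
  frames <- sort(unique(det$frame))
  tracks <- list() # label -> list(label, parent, present, last_frame, rows)
  next_label <- 1L
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    t <- frames[fi]
    dt <- det[det$frame == t, ]
    det_xy <- cbind(dt$x, dt$y)
    active_idx <- which(purrr::map_int(tracks, "last_frame") == t - 1L)
    assignment <- link_frame(tracks[active_idx], det_xy, params)
    rows <- vector("list", nrow(dt))
    for (j in seq_len(nrow(dt))) {
      lab <- assignment[j]
      if (is.na(lab)) {
        lab <- next_label
        next_label <- next_label + 1L
        tracks[[lab]] <- list(
          label = lab, parent = NULL,
          present = c(dt$x[j], dt$y[j]), last_frame = t
        )
        v <- c(0, 0)
      } else {
        tr <- tracks[[lab]]
        v <- c(dt$x[j], dt$y[j]) - tr$present
        tracks[[lab]]$parent <- tr$present
        tracks[[lab]]$present <- c(dt$x[j], dt$y[j])
        tracks[[lab]]$last_frame <- t
      }
      rows[[j]] <- tibble(
        frame = t, x = dt$x[j], y = dt$y[j], vx = v[1], vy = v[2],
        speed = sqrt(sum(v^2)), track_label = lab, clump_code = 0,
        det_id = dt$det_id[j]
      )
    }
    out[[fi]] <- bind_rows(rows)
  }
  arrange(bind_rows(out), track_label, frame)
}
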