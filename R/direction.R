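# Change-of-direction analysis around a clump.
#
# The entry heading of a cell is the vector between its positions at frames
# t_k0 - S and t_k0 - 1; the exit heading uses frames t_kC + 1 and t_kC + S.
# The direction change theta_x in [-pi, pi] is the signed angle from entry to
# exit, computed by rotating the coordinates so the entry heading lies along
# the +x' axis (the incidence rotation) and reading off the exit heading in
# that frame of reference. Sign convention: positive = counter-clockwise in
# the standard mathematical orientation of the (x, y) pixel coordinates.
# Matched controls repeat the construction on the 2S clump-free frames before
# contact, split into two halves (a zero-length pseudo-clump at t_k0 - S).

track_position <- function(track, at, what) {
  i <- match(at, track$frame)
  if (is.na(i)) {
    abort(sprintf("frame %d missing from the track (%s window).", at, what))
  }
  c(track$x[i], track$y[i])
}

#' Entry and exit heading vectors of a clump span
#'
#' @param track Tibble of one track's points (`frame`, `x`, `y`).
#' @param t_k0,t_kC First and last frame of the clump.
#' @param S Half-window length in frames.
#' @return Numeric `c(dx, dy)`.
#' @export
entry_vector <- function(track, t_k0, S = 5) {
  track_position(track, t_k0 - 1, "entry") -
    track_position(track, t_k0 - S, "entry")
}

#' @rdname entry_vector
#' @export
exit_vector <- function(track, t_kC, S = 5) {
  track_position(track, t_kC + S, "exit") -
    track_position(track, t_kC + 1, "exit")
}

#' Rotate coordinates so a heading lies along +x'
#'
#' Applies the rigid rotation about `origin` that maps the `entry` heading
#' onto the +x' direction. Distances are preserved; the returned incidence
#' angle is the angle of `entry` in the original coordinates (the rotation
#' applied is by minus this angle).
#'
#' @param points Two-column matrix (or data frame) of `(x, y)` points.
#' @param entry Non-zero heading vector `c(dx, dy)`.
#' @param origin Center of rotation (default the origin).
#' @return A list with `points` (rotated matrix) and `incidence` (radians).
#' @export
incidence_rotation <- function(points, entry, origin = c(0, 0)) {
  if (sqrt(sum(entry^2)) == 0) {
    abort("degenerate case: zero entry vector has no direction.")
  }
  incidence <- atan2(entry[2], entry[1])
  rot <- matrix(
    c(cos(-incidence), sin(-incidence), -sin(-incidence), cos(-incidence)),
    2, 2
  )
  pts <- as.matrix(points)
  shifted <- sweep(pts, 2, origin)
  out <- shifted %*% t(rot)
  out <- sweep(out, 2, origin, FUN = "+")
  colnames(out) <- c("x", "y")
  list(points = out, incidence = incidence)
}

#' Signed direction change between two headings
#'
#' The angle of the `exit` heading in the frame of reference in which the
#' `entry` heading points along +x', wrapped to `[-pi, pi]`. Positive values
#' are counter-clockwise turns in the mathematical orientation of the pixel
#' coordinates.
#'
#' @param entry,exit Non-zero heading vectors `c(dx, dy)`.
#' @return Angle in radians in `[-pi, pi]`.
#' @export
delta_direction <- function(entry, exit) {
  if (sqrt(sum(exit^2)) == 0) {
    abort("degenerate case: zero exit vector has no direction.")
  }
  rotated <- incidence_rotation(rbind(exit), entry)$points
  atan2(rotated[1, 2], rotated[1, 1])
}

#' Direction change over the control window
#'
#' Repeats the before/after construction on the `2S` clump-free frames
#' leading up to the clump: entry over `[t_k0 - 2S, t_k0 - S - 1]` and exit
#' over `[t_k0 - S, t_k0 - 1]`, i.e. the contact geometry with a zero-length
#' clump placed at `t_k0 - S`.
#'
#' @inheritParams entry_vector
#' @return Angle in radians in `[-pi, pi]`.
#' @export
control_delta_direction <- function(track, t_k0, S = 5) {
  entry <- track_position(track, t_k0 - S - 1, "control entry") -
    track_position(track, t_k0 - 2 * S, "control entry")
  exit <- track_position(track, t_k0 - 1, "control exit") -
    track_position(track, t_k0 - S, "control exit")
  delta_direction(entry, exit)
}

#' Measure contact and control direction changes for selected cases
#'
#' For every case, computes the contact angle (entry vs. exit heading around
#' the clump) and the matched control angle (two halves of the `2S` pre-clump
#' window). Cases with a degenerate (zero-length) heading are kept in the
#' table with `theta_deg = NA` and `degenerate = TRUE` so they can be
#' reported, but they carry no angle.
#'
#' @param tracks Annotated tracks tibble.
#' @param cases Cases tibble from [select_cases()].
#' @return A tibble with one row per case and kind: `case_id`, `track_label`,
#'   `kind` (`"contact"`/`"control"`), `theta_deg`, `TC`, `degenerate`.
#' @export
measure_angles <- function(tracks, cases) {
  if (nrow(cases) == 0) {
    return(tibble(
      case_id = integer(), track_label = integer(), kind = character(),
      theta_deg = double(), TC = integer(), degenerate = logical()
    ))
  }
  by_track <- split(tracks, tracks$track_label)
  one <- function(case_id, track_label, t_k0, t_kC, TC, S, ...) {
    track <- by_track[[as.character(track_label)]]
    contact <- tryCatch(
      delta_direction(
        entry_vector(track, t_k0, S), exit_vector(track, t_kC, S)
      ),
      error = function(e) NA_real_
    )
    control <- tryCatch(
      control_delta_direction(track, t_k0, S),
      error = function(e) NA_real_
    )
    tibble(
      case_id = case_id, track_label = track_label,
      kind = c("contact", "control"),
      theta_deg = c(contact, control) * 180 / pi,
      TC = TC, degenerate = is.na(c(contact, control))
    )
  }
  bind_rows(purrr::pmap(cases, one))
}
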