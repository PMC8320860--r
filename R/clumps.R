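# Clump annotation of tracks, clump spans, and experiment-case selection.

#' Annotate track points with clump codes
#'
#' For every frame, each nucleus lying inside a microtubule object that
#' contains two or more nuclei receives the positional clump code of all
#' track labels sharing that object (see [encode_clump_code()]); all other
#' points get code 0.
#'
#' @param tracks Tracks tibble from [build_tracks()] (must carry `det_id`).
#' @param detections Detections tibble from [segment_movie()].
#' @param base Positional base of the clump code.
#' @return The tracks tibble with `clump_code` filled.
#' @export
annotate_clumps <- function(tracks, detections, base = 1000) {
  red <- filter(detections, channel == "nuclei")
  if (!"det_id" %in% names(tracks) || !"det_id" %in% names(red)) {
    abort("`tracks` and `detections` must share a `det_id` column.")
  }
  info <- left_join(
    select(tracks, det_id, track_label),
    select(red, det_id, frame, green_object, green_is_clump),
    by = "det_id"
  )
  grouped <- info |>
    filter(!is.na(green_object) & green_is_clump) |>
    group_by(frame, green_object) |>
    mutate(code = encode_clump_code(unique(track_label), base = base)) |>
    ungroup()
  tracks$clump_code <- 0
  hit <- match(grouped$det_id, tracks$det_id)
  tracks$clump_code[hit] <- grouped$code
  tracks
}

#' Find clump spans on annotated tracks
#'
#' A clump span is a maximal run of consecutive track points carrying the
#' same non-zero clump code. `t_k0`/`t_kC` are the first/last frames of the
#' run and `TC` (time in clump) is the inclusive frame count.
#'
#' @param tracks Annotated tracks tibble.
#' @param S Half-window length in frames attached to each span (frames
#'   `t_k0 - S .. t_kC + S` form the clump span's analysis window).
#' @return A tibble with columns `track_label`, `code`, `t_k0`, `t_kC`,
#'   `TC`, `S`.
#' @export
find_clump_spans <- function(tracks, S = 5) {
  if (nrow(tracks) == 0) {
    return(tibble(
      track_label = integer(), code = double(), t_k0 = integer(),
      t_kC = integer(), TC = integer(), S = as.integer(S)[0]
    ))
  }
  spans <- tracks |>
    arrange(track_label, frame) |>
    group_by(track_label) |>
    mutate(run = cumsum(clump_code != lag(clump_code, default = -1))) |>
    group_by(track_label, run) |>
    summarise(
      code = clump_code[1], t_k0 = min(frame), t_kC = max(frame),
      TC = n(), .groups = "drop"
    ) |>
    filter(code != 0) |>
    select(-run)
  spans$S <- as.integer(S)
  arrange(spans, track_label, t_k0)
}

window_clump_free <- function(track_points, frames) {
  all(frames %in% track_points$frame) &&
    all(track_points$clump_code[track_points$frame %in% frames] == 0)
}

#' Select experiment cases
#'
#' Keeps clump spans suitable for the before/after direction analysis:
#' exactly two member labels in the code; the track exists and is clump-free
#' over the `2S` frames leading up to the clump (`t_k0 - 2S .. t_k0 - 1`,
#' which doubles as the control window) and over the `S` frames after it
#' (`t_kC + 1 .. t_kC + S`). Cases where the partner track also qualifies are
#' flagged (`partner_valid`), enabling a per-clump analysis; they are not
#' dropped.
#'
#' @param tracks Annotated tracks tibble.
#' @param spans Spans tibble from [find_clump_spans()]; must have been
#'   computed with the same `S`.
#' @param S Half-window length in frames (default 5: the immediate reaction
#'   after contact).
#' @param base Positional base of the clump code.
#' @return A tibble of cases: `case_id`, `track_label`, `partner_label`,
#'   `code`, `t_k0`, `t_kC`, `TC`, `S`, `control_start`, `partner_valid`.
#' @export
select_cases <- function(tracks, spans, S = 5, base = 1000) {
  empty <- tibble(
    case_id = integer(), track_label = integer(), partner_label = integer(),
    code = double(), t_k0 = integer(), t_kC = integer(), TC = integer(),
    S = integer(), control_start = integer(), partner_valid = logical()
  )
  if (nrow(spans) == 0) {
    return(empty)
  }
  if (!all(spans$S == S)) {
    abort("`spans` were computed with a different `S`.")
  }
  by_track <- split(tracks, tracks$track_label)
  keep <- purrr::pmap_lgl(spans, function(track_label, code, t_k0, t_kC, ...) {
    members <- decode_clump_code(code, base = base)
    if (length(members) != 2) {
      return(FALSE)
    }
    pts <- by_track[[as.character(track_label)]]
    window_clump_free(pts, (t_k0 - 2 * S):(t_k0 - 1)) &&
      window_clump_free(pts, (t_kC + 1):(t_kC + S))
  })
  ok <- spans[keep, ]
  if (nrow(ok) == 0) {
    return(empty)
  }
  ok$partner_label <- purrr::map2_int(ok$code, ok$track_label, function(code, lab) {
    members <- decode_clump_code(code, base = base)
    as.integer(setdiff(members, lab))
  })
  span_key <- function(d) paste(d$code, d$t_k0, d$t_kC, d$track_label)
  ok$partner_valid <- paste(ok$code, ok$t_k0, ok$t_kC, ok$partner_label) %in%
    span_key(ok)
  ok$control_start <- as.integer(ok$t_k0 - 2 * S)
  ok$case_id <- seq_len(nrow(ok))
  select(
    ok, case_id, track_label, partner_label, code, t_k0, t_kC, TC, S,
    control_start, partner_valid
  )
}

#' Independently re-validate selected cases
#'
#' A deliberately separate implementation of the case-selection predicates,
#' used to cross-check [select_cases()]: two members, matching partner label,
#' full clump-free pre (`2S`) and post (`S`) windows, and the clump frames
#' themselves carrying the case's code.
#'
#' @param tracks Annotated tracks tibble.
#' @param cases Cases tibble from [select_cases()].
#' @param base Positional base of the clump code.
#' @return Logical vector, one entry per case.
#' @export
validate_cases <- function(tracks, cases, base = 1000) {
  purrr::pmap_lgl(cases, function(track_label, partner_label, code, t_k0,
                                  t_kC, S, ...) {
    members <- decode_clump_code(code, base = base)
    if (length(members) != 2) {
      return(FALSE)
    }
    if (!setequal(members, c(track_label, partner_label))) {
      return(FALSE)
    }
    pts <- tracks[tracks$track_label == track_label, ]
    codes <- pts$clump_code[match(
      (t_k0 - 2 * S):(t_kC + S), pts$frame
    )]
    if (anyNA(codes)) {
      return(FALSE)
    }
    pre_post <- c(seq_len(2 * S), length(codes) - seq_len(S) + 1)
    inside <- setdiff(seq_along(codes), pre_post)
    all(codes[pre_post] == 0) && all(codes[inside] == code)
  })
}

#' Filter cases by time in clump
#'
#' @param cases Cases tibble carrying a `TC` column.
#' @param a Threshold on the number of frames spent in the clump.
#' @param side `"le"` keeps `TC <= a`, `"lt"` keeps `TC < a`, `"gt"` keeps
#'   `TC > a`, `"ge"` keeps `TC >= a`.
#' @return The filtered cases tibble.
#' @export
stratify_by_tc <- function(cases, a, side = c("le", "lt", "gt", "ge")) {
  side <- arg_match(side)
  keep <- switch(side,
    le = cases$TC <= a, lt = cases$TC < a,
    gt = cases$TC > a, ge = cases$TC >= a
  )
  cases[keep, ]
}
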