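# End-to-end pipeline: segment -> track -> clumps -> analyze.

#' Pipeline configuration
#'
#' Bundles the tunable parameters of every stage. Serializable to YAML; every
#' [run_pipeline()] call with an output directory writes the resolved
#' configuration next to its outputs so each run is reproducible.
#'
#' @param segment A [segment_params()] object.
#' @param track A [track_params()] object.
#' @param S Half-window length in frames around each clump (default 5).
#' @param tc_max Combined analysis keeps cases with `TC < tc_max`
#'   (default 10); `NULL` disables the filter.
#' @param base Positional base of the clump codes.
#' @param paired Use the paired tests (default) or the unpaired variants.
#' @param seed Seed recorded with the run.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(segment = segment_params(), track = track_params(),
                            S = 5, tc_max = 10, base = 1000, paired = TRUE,
                            seed = 1L) {
  structure(
    list(
      segment = segment, track = track, S = S, tc_max = tc_max,
      base = base, paired = paired, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Write or read a pipeline configuration as YAML
#'
#' @param config A [pipeline_config()] object.
#' @param path YAML file path.
#' @export
write_config <- function(config, path) {
  seg <- unclass(config$segment)
  for (field in c("sigma", "low", "high")) {
    if (!is.null(seg[[field]])) seg[[field]] <- as.list(seg[[field]])
  }
  out <- unclass(config)
  out$segment <- seg
  out$track <- unclass(config$track)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  seg <- raw$segment
  pipeline_config(
    segment = segment_params(
      sigma = unlist(seg$sigma), low = unlist(seg$low),
      high = unlist(seg$high), open_radius = seg$open_radius,
      k_low = seg$k_low, k_high = seg$k_high
    ),
    track = do.call(track_params, raw$track),
    S = raw$S, tc_max = raw$tc_max, base = raw$base, paired = raw$paired,
    seed = raw$seed
  )
}

#' Run the full analysis pipeline
#'
#' Executes segmentation, tracking, clump annotation, case selection and the
#' direction-change comparison in order. The input may be a movie (a list of
#' `list(red, green)` frames) or an already-annotated track table, in which
#' case the earlier stages are skipped.
#'
#' @param input A movie list, or a tracks tibble / path to a tracks CSV.
#' @param config A [pipeline_config()] object.
#' @param out_dir Optional output directory; when given, the detections,
#'   tracks, cases and angles tables, the comparison (JSON if jsonlite is
#'   installed) and the resolved configuration are written there.
#' @return A list with `detections` (NULL when starting from tracks),
#'   `tracks`, `spans`, `cases`, `angles` and `comparison` (NULL when fewer
#'   than 5 usable cases).
#' @export
run_pipeline <- function(input, config = pipeline_config(), out_dir = NULL) {
  detections <- NULL
  if (is.character(input)) input <- read_tracks(input)
  if (is.data.frame(input)) {
    tracks <- input
    check_schema(tracks, tracks_schema, "track table")
  } else {
    detections <- segment_movie(input, params = config$segment)
    tracks <- build_tracks(detections, params = config$track)
    tracks <- annotate_clumps(tracks, detections, base = config$base)
  }
  spans <- find_clump_spans(tracks, S = config$S)
  cases <- select_cases(tracks, spans, S = config$S, base = config$base)
  angles <- measure_angles(tracks, cases)
  comparison <- NULL
  usable <- if (nrow(angles) == 0) {
    0L
  } else {
    sum(!angles$degenerate[angles$kind == "contact"])
  }
  if (nrow(cases) == 0) {
    warn("no experiment cases found; nothing to analyze.")
  } else if (usable >= 5) {
    comparison <- tryCatch(
      compare_angles(angles, tc_max = config$tc_max, paired = config$paired),
      error = function(e) {
        warn(conditionMessage(e))
        NULL
      }
    )
  } else {
    warn("fewer than 5 usable cases; skipping the group comparison.")
  }
  result <- list(
    detections = detections, tracks = tracks, spans = spans, cases = cases,
    angles = angles, comparison = comparison
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    if (!is.null(detections)) {
      readr::write_csv(detections, file.path(out_dir, "detections.csv"))
    }
    write_tracks(tracks, file.path(out_dir, "tracks.csv"))
    write_cases(cases, file.path(out_dir, "cases.csv"))
    readr::write_csv(angles, file.path(out_dir, "angles.csv"))
    write_config(config, file.path(out_dir, "config.yaml"))
    if (!is.null(comparison) && requireNamespace("jsonlite", quietly = TRUE)) {
      jsonlite::write_json(
        glance(comparison), file.path(out_dir, "comparison.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  result
}
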