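# Readers and writers for the interchange tables and movies.
#
# The track table is the interchange format between stages: CSV with columns
# frame, x, y, vx, vy, speed, track_label, clump_code. Frame indices are
# 0-based. Clump codes are read as doubles, which represent them exactly up
# to 2^53 (five members at base 1000).

tracks_schema <- c(
  "frame", "x", "y", "vx", "vy", "speed", "track_label", "clump_code"
)
cases_schema <- c(
  "case_id", "track_label", "partner_label", "code", "t_k0", "t_kC", "TC",
  "S", "control_start", "partner_valid"
)

check_schema <- function(df, schema, what) {
  missing <- setdiff(schema, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

#' Read and write track tables
#'
#' @param path CSV file path.
#' @param one_based If `TRUE`, frame indices in the file are 1-based (e.g.
#'   MATLAB-style exports) and are shifted to the package's 0-based
#'   convention on read.
#' @return A tracks tibble.
#' @export
read_tracks <- function(path, one_based = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, tracks_schema, "track table")
  df$frame <- as.integer(df$frame) - as.integer(one_based)
  df$track_label <- as.integer(df$track_label)
  df$clump_code <- as.numeric(df$clump_code)
  as_tibble(df)
}

#' @rdname read_tracks
#' @param tracks Tracks tibble.
#' @export
write_tracks <- function(tracks, path) {
  check_schema(tracks, tracks_schema, "track table")
  readr::write_csv(tracks[, tracks_schema], path)
  invisible(path)
}

#' Read and write experiment-case tables
#'
#' @param path CSV file path.
#' @return A cases tibble.
#' @export
read_cases <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_schema(df, cases_schema, "case table")
  as_tibble(df)
}

#' @rdname read_cases
#' @param cases Cases tibble.
#' @export
write_cases <- function(cases, path) {
  check_schema(cases, cases_schema, "case table")
  readr::write_csv(cases[, cases_schema], path)
  invisible(path)
}

#' Write and read a two-channel movie as multi-page TIFF
#'
#' One 16-bit multi-page TIFF per channel. Intensities are scaled by
#' `scale` into `[0, 1]` on write and scaled back on read.
#'
#' @param movie List of frames, each a list with `red` and `green` matrices.
#' @param dir Output directory; files `nuclei.tif` and `microtubules.tif`.
#' @param scale Intensity corresponding to full scale (default: movie max).
#' @return `write_movie_tiff()` the directory invisibly; `read_movie_tiff()`
#'   a movie list.
#' @export
write_movie_tiff <- function(movie, dir, scale = NULL) {
  check_installed("tiff")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(scale)) {
    scale <- max(purrr::map_dbl(movie, ~ max(.x$red, .x$green)))
  }
  clamp <- function(m) pmin(pmax(m / scale, 0), 1)
  tiff::writeTIFF(
    purrr::map(movie, ~ clamp(.x$red)),
    file.path(dir, "nuclei.tif"),
    bits.per.sample = 16
  )
  tiff::writeTIFF(
    purrr::map(movie, ~ clamp(.x$green)),
    file.path(dir, "microtubules.tif"),
    bits.per.sample = 16
  )
  writeLines(as.character(scale), file.path(dir, "scale.txt"))
  invisible(dir)
}

#' @rdname write_movie_tiff
#' @export
read_movie_tiff <- function(dir) {
  check_installed("tiff")
  scale_file <- file.path(dir, "scale.txt")
  scale <- if (file.exists(scale_file)) {
    as.numeric(readLines(scale_file))
  } else {
    1
  }
  red <- tiff::readTIFF(file.path(dir, "nuclei.tif"), all = TRUE)
  green <- tiff::readTIFF(file.path(dir, "microtubules.tif"), all = TRUE)
  purrr::map2(red, green, ~ list(red = .x * scale, green = .y * scale))
}
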