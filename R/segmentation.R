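# Segmentation of the two fluorescence channels.
#
# Pipeline per frame and channel: Gaussian low-pass -> hysteresis threshold ->
# morphological opening (disc, r = 3) -> 8-connected labeling. Clumps are then
# flagged on the microtubule ("green") channel by counting how many nucleus
# ("red") centroids fall inside each object.
#
# Coordinate convention used throughout the package: x = column, y = row,
# both 0-based, with pixel centers at integer coordinates. Images are plain R
# matrices indexed [y + 1, x + 1].

#' Segmentation parameters
#'
#' @param sigma Gaussian low-pass standard deviation in pixels. A single value
#'   or a named vector `c(nuclei =, microtubules =)`.
#' @param low,high Hysteresis thresholds on the *smoothed* intensity scale.
#'   `NULL` (default) derives them per frame and channel as
#'   `mean + k_low * sd` and `mean + k_high * sd` of the smoothed intensities.
#'   A single value or a named vector `c(nuclei =, microtubules =)`.
#' @param open_radius Disc radius (pixels) of the morphological opening used
#'   to remove noise specks and smooth edges.
#' @param k_low,k_high Multipliers for the adaptive thresholds.
#' @return A list of class `segment_params`.
#' @export
segment_params <- function(sigma = 2, low = NULL, high = NULL,
                           open_radius = 3, k_low = 1, k_high = 3) {
  per_channel <- function(v) {
    if (is.null(v)) {
      return(NULL)
    }
    if (length(v) == 1) {
      v <- c(nuclei = unname(v), microtubules = unname(v))
    }
    if (!all(c("nuclei", "microtubules") %in% names(v))) {
      abort("per-channel parameters must be named 'nuclei' and 'microtubules'.")
    }
    v[c("nuclei", "microtubules")]
  }
  structure(
    list(
      sigma = per_channel(sigma), low = per_channel(low),
      high = per_channel(high), open_radius = open_radius,
      k_low = k_low, k_high = k_high
    ),
    class = "segment_params"
  )
}

check_image <- function(img, arg = "img") {
  if (!is.matrix(img) || !is.numeric(img)) {
    abort(sprintf("`%s` must be a numeric matrix.", arg))
  }
  if (any(!is.finite(img)) || any(img < 0)) {
    abort(sprintf("`%s` must contain finite, non-negative intensities.", arg))
  }
  invisible(img)
}

#' Gaussian low-pass filter
#'
#' Smooths one channel image with an isotropic Gaussian kernel. Constant
#' images are preserved and total intensity is approximately conserved (up to
#' boundary handling).
#'
#' @param img Numeric intensity matrix (finite, non-negative).
#' @param sigma Kernel standard deviation in pixels (> 0).
#' @return Smoothed matrix of the same dimensions.
#' @export
gaussian_lowpass <- function(img, sigma = 2) {
  check_image(img)
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0) {
    abort("`sigma` must be a single positive number.")
  }
  out <- EBImage::imageData(EBImage::gblur(img, sigma = sigma))
  # FFT round-off can leave tiny negative values on a dark background.
  out[out < 0] <- 0
  out
}

#' Hysteresis threshold segmentation
#'
#' A pixel is foreground iff its intensity is `>= low` and it is 8-connected
#' to at least one pixel with intensity `>= high`. With `low == high` this
#' reduces to plain thresholding.
#'
#' @param img Numeric intensity matrix.
#' @param low,high Thresholds with `low < high` (or equal).
#' @return Logical matrix of the same dimensions.
#' @export
hysteresis_mask <- function(img, low, high) {
  check_image(img)
  if (low > high) {
    abort("`low` must be <= `high`.")
  }
  labs <- label_mask(img >= low)
  if (max(labs) == 0) {
    return(labs > 0)
  }
  seeded <- unique(labs[img >= high])
  seeded <- seeded[seeded > 0]
  labs %in% seeded & labs > 0 -> keep
  matrix(keep, nrow(img), ncol(img))
}

#' Morphological opening with a disc
#'
#' Erosion followed by dilation with a disc structuring element; removes
#' objects and protrusions smaller than the disc. Idempotent.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @param radius Disc radius in pixels (default 3).
#' @return Logical matrix.
#' @export
open_mask <- function(mask, radius = 3) {
  m <- (mask > 0) * 1
  if (radius < 1) {
    return(mask > 0)
  }
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  EBImage::imageData(EBImage::opening(m, brush)) > 0
}

#' Label connected components (8-connectivity)
#'
#' Connected foreground components are labeled `1..K` with no gaps, in order
#' of first appearance in column-major scan order.
#'
#' @param mask Logical (or 0/1 numeric) matrix.
#' @return Integer matrix of labels; 0 is background.
#' @export
label_mask <- function(mask) {
  m <- (mask > 0) * 1
  labs <- EBImage::imageData(EBImage::bwlabel(m))
  k <- max(labs)
  if (k == 0) {
    return(matrix(0L, nrow(m), ncol(m)))
  }
  # bwlabel is 4-connected; merge labels that touch diagonally.
  nr <- nrow(labs)
  nc <- ncol(labs)
  edges <- NULL
  if (nr > 1 && nc > 1) {
    a1 <- labs[-nr, -nc]
    b1 <- labs[-1, -1] # down-right neighbor
    a2 <- labs[-nr, -1]
    b2 <- labs[-1, -nc] # down-left neighbor
    sel1 <- a1 > 0 & b1 > 0 & a1 != b1
    sel2 <- a2 > 0 & b2 > 0 & a2 != b2
    edges <- rbind(cbind(a1[sel1], b1[sel1]), cbind(a2[sel2], b2[sel2]))
  }
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::graph_from_edgelist(unique(edges), directed = FALSE)
    g <- igraph::add_vertices(g, max(0, k - igraph::vcount(g)))
    comp <- igraph::components(g)$membership
    labs[labs > 0] <- comp[labs[labs > 0]]
    k <- max(labs)
  }
  # relabel consecutively by first appearance
  first <- match(seq_len(k), labs[labs > 0])
  ord <- order(first)
  remap <- integer(k)
  remap[ord] <- seq_len(k)
  remap <- remap[seq_len(k)]
  out <- matrix(0L, nr, nc)
  out[labs > 0] <- remap[labs[labs > 0]]
  out
}

#' Extract per-object detections from a labeled mask
#'
#' @param labels Integer label matrix from [label_mask()].
#' @param frame Integer frame index (0-based).
#' @param channel `"nuclei"` or `"microtubules"`.
#' @return A tibble with columns `frame`, `channel`, `object_label`,
#'   `x`, `y` (0-based centroid in pixels), `area`.
#' @export
mask_detections <- function(labels, frame = 0, channel = "nuclei") {
  channel <- arg_match(channel, c("nuclei", "microtubules"))
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    return(tibble(
      frame = integer(), channel = character(), object_label = integer(),
      x = double(), y = double(), area = integer()
    ))
  }
  lab <- labels[idx]
  nr <- nrow(labels)
  rows <- ((idx - 1) %% nr)
  cols <- (idx - 1) %/% nr
  area <- tabulate(lab)
  tibble(
    frame = as.integer(frame), channel = channel,
    object_label = seq_along(area),
    x = as.vector(rowsum(cols, lab)) / area,
    y = as.vector(rowsum(rows, lab)) / area,
    area = area
  )
}

#' Count nuclei inside microtubule objects and flag clumps
#'
#' Each nucleus centroid is assigned to the microtubule object whose label
#' region contains its nearest pixel; a microtubule object holding two or more
#' nuclei is a clump.
#'
#' @param detections Detections tibble for *one frame* holding both channels
#'   (as produced by [segment_frame()] before clump annotation).
#' @param green_labels Label matrix of the microtubule channel for that frame.
#' @return The detections tibble with, on microtubule rows, `nucleus_count`
#'   and `is_clump`, and on nucleus rows, `green_object` (NA when the centroid
#'   lies on background) and `green_is_clump`.
#' @export
count_nuclei <- function(detections, green_labels) {
  if (nrow(detections) > 0 && length(unique(detections$frame)) != 1) {
    abort("`detections` must contain exactly one frame.")
  }
  red <- filter(detections, channel == "nuclei")
  green <- filter(detections, channel == "microtubules")
  if (nrow(green) > 0 && max(green$object_label) > max(green_labels)) {
    abort("`green_labels` does not match the microtubule detections.")
  }
  host <- rep(NA_integer_, nrow(red))
  if (nrow(red) > 0) {
    rr <- pmin(pmax(round(red$y), 0), nrow(green_labels) - 1) + 1
    cc <- pmin(pmax(round(red$x), 0), ncol(green_labels) - 1) + 1
    lab <- green_labels[cbind(rr, cc)]
    host[lab > 0] <- lab[lab > 0]
  }
  counts <- tabulate(host[!is.na(host)], nbins = max(green$object_label, 0))
  green$nucleus_count <- counts[green$object_label]
  green$is_clump <- green$nucleus_count >= 2
  red$green_object <- host
  red$green_is_clump <- !is.na(host) & green$is_clump[match(host, green$object_label)]
  bind_rows(red, green)
}

resolve_threshold <- function(value, smoothed, k) {
  if (is.null(value)) mean(smoothed) + k * sd(smoothed) else unname(value)
}

#' Segment one two-channel frame
#'
#' @param red,green Intensity matrices of the nucleus and microtubule channel.
#' @param frame Integer frame index (0-based).
#' @param params A [segment_params()] object.
#' @return A list with `detections` (tibble, both channels, clump-annotated),
#'   `red_labels` and `green_labels` (integer label matrices).
#' @export
segment_frame <- function(red, green, frame = 0, params = segment_params()) {
  if (!identical(dim(red), dim(green))) {
    abort("`red` and `green` must have identical dimensions.")
  }
  one <- function(img, ch) {
    s <- gaussian_lowpass(img, params$sigma[[ch]])
    low <- resolve_threshold(params$low[[ch]], s, params$k_low)
    high <- resolve_threshold(params$high[[ch]], s, params$k_high)
    if (low > high) low <- high
    mask <- open_mask(hysteresis_mask(s, low, high), params$open_radius)
    label_mask(mask)
  }
  red_labels <- one(red, "nuclei")
  green_labels <- one(green, "microtubules")
  det <- bind_rows(
    mask_detections(red_labels, frame, "nuclei"),
    mask_detections(green_labels, frame, "microtubules")
  )
  det <- count_nuclei(det, green_labels)
  list(detections = det, red_labels = red_labels, green_labels = green_labels)
}

#' Segment a whole movie
#'
#' @param movie A list of frames, each a list with elements `red` and `green`
#'   (intensity matrices), e.g. from [render_movie()] or [read_movie_tiff()].
#' @param params A [segment_params()] object.
#' @return A detections tibble over all frames, with a movie-wide unique
#'   `det_id` on every row.
#' @export
segment_movie <- function(movie, params = segment_params()) {
  frames <- purrr::imap(movie, function(fr, i) {
    segment_frame(fr$red, fr$green, frame = i - 1L, params = params)$detections
  })
  det <- bind_rows(frames)
  det$det_id <- seq_len(nrow(det))
  det
}
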