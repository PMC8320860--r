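# Independent oracles used to cross-check the implementation.

# Exact two-sided paired signed-rank p-value by brute-force enumeration of
# all 2^n sign assignments of the absolute differences.
enum_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(1)
  }
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# Hysteresis oracle: flood fill (8-connectivity) through the low mask from
# every seed pixel above the high threshold.
flood_hysteresis <- function(img, low, high) {
  nr <- nrow(img)
  nc <- ncol(img)
  fg <- img >= low
  out <- matrix(FALSE, nr, nc)
  queue <- which(img >= high & fg)
  out[queue] <- TRUE
  while (length(queue) > 0) {
    idx <- queue[1]
    queue <- queue[-1]
    r <- (idx - 1) %% nr + 1
    c <- (idx - 1) %/% nr + 1
    for (dr in -1:1) {
      for (dc in -1:1) {
        rr <- r + dr
        cc <- c + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc) {
          j <- (cc - 1) * nr + rr
          if (fg[j] && !out[j]) {
            out[j] <- TRUE
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  out
}

# Morphology oracle: erosion then dilation by explicit neighborhood loops
# over the same disc brush (objects must stay clear of the border).
brute_morph <- function(mask, brush, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(mask)
  nc <- ncol(mask)
  k <- (nrow(brush) - 1) / 2
  off <- which(brush > 0, arr.ind = TRUE) - (k + 1)
  out <- matrix(FALSE, nr, nc)
  for (r in seq_len(nr)) {
    for (c in seq_len(nc)) {
      rr <- r + off[, 1]
      cc <- c + off[, 2]
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      vals <- mask[cbind(rr[ok], cc[ok])]
      out[r, c] <- if (op == "erode") {
        all(vals) && all(ok)
      } else {
        any(vals)
      }
    }
  }
  out
}

brute_open <- function(mask, radius = 3) {
  brush <- EBImage::makeBrush(2 * radius + 1, shape = "disc")
  brute_morph(brute_morph(mask > 0, brush, "erode"), brush, "dilate")
}

# Signed angle between two vectors via the cross/dot formula (independent of
# the rotation-based implementation).
atan2_angle <- function(entry, exit) {
  atan2(
    entry[1] * exit[2] - entry[2] * exit[1],
    entry[1] * exit[1] + entry[2] * exit[2]
  )
}

# A minimal detections table for hand-built scenes: one nucleus per row,
# with explicit clump membership columns as segment_movie() would emit.
make_nucleus_detections <- function(frame, x, y, green_object = NA,
                                    green_is_clump = FALSE) {
  tibble::tibble(
    frame = as.integer(frame), channel = "nuclei",
    object_label = seq_along(x), x = x, y = y, area = 1L,
    green_object = as.integer(green_object),
    green_is_clump = green_is_clump,
    nucleus_count = NA_integer_, is_clump = NA
  )
}

# Straight-line track points table.
straight_track <- function(frames, start = c(0, 0), heading = c(1, 0),
                           label = 1L, clump_code = 0) {
  k <- seq_along(frames) - 1
  tibble::tibble(
    frame = as.integer(frames),
    x = start[1] + heading[1] * k, y = start[2] + heading[2] * k,
    vx = c(0, rep(heading[1], length(frames) - 1)),
    vy = c(0, rep(heading[2], length(frames) - 1)),
    speed = sqrt(vx^2 + vy^2), track_label = as.integer(label),
    clump_code = clump_code
  )
}
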