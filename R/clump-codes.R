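#' Positional clump codes
#'
#' A *clump* is a single microtubule-channel object that contains two or more
#' nucleus detections, i.e. a moment of cell-cell contact. The set of track
#' labels inside one clump is encoded as a single integer by writing the
#' ascending-sorted labels as digits in base `base` (default 1000):
#' \deqn{c(r_1, \dots, r_m) = \sum_{i=1}^{m} \mathrm{base}^{\,i-1}\, r_i,
#'       \qquad r_1 < r_2 < \dots < r_m.}
#' Tracks 1 and 2 therefore encode to 2001, tracks 2 and 3 to 3002, and tracks
#' 2, 3 and 5 to 5003002. The code 0 represents the empty set (no clump).
#'
#' The encoding is order-insensitive and injective as long as every label is
#' in `[1, base - 1]`. Codes are plain doubles: they are exact up to 2^53,
#' which covers clumps of up to five members at the default base.
#'
#' @param labels Integer vector of distinct track labels, each in
#'   `[1, base - 1]`. May be given in any order.
#' @param code A single non-negative numeric code.
#' @param base Positional base; must exceed the largest track label ever
#'   assigned (default 1000).
#'
#' @return `encode_clump_code()` returns a single numeric code;
#'   `decode_clump_code()` returns the ascending-sorted integer labels
#'   (`integer(0)` for code 0).
#'
#' @examples
#' encode_clump_code(c(2, 1)) # 2001
#' encode_clump_code(c(5, 3, 2)) # 5003002
#' decode_clump_code(24013) # 13 24
#' @export
encode_clump_code <- function(labels, base = 1000) {
  if (length(labels) == 0) {
    return(0)
  }
  labels <- as.numeric(labels)
  if (anyNA(labels) || any(labels < 1) || any(labels != floor(labels))) {
    abort("`labels` must be positive integers.")
  }
  if (any(labels >= base)) {
    abort(sprintf(
      "track label %s is >= base (%d); the positional encoding would overflow.",
      max(labels), base
    ))
  }
  if (anyDuplicated(labels)) {
    abort("`labels` must be distinct; duplicated labels make the code ambiguous.")
  }
  labels <- sort(labels)
  sum(labels * base^(seq_along(labels) - 1))
}

#' @rdname encode_clump_code
#' @export
decode_clump_code <- function(code, base = 1000) {
  if (length(code) != 1 || is.na(code) || code < 0 || code != floor(code)) {
    abort("`code` must be a single non-negative integer.")
  }
  labels <- integer(0)
  while (code > 0) {
    labels <- c(labels, as.integer(code %% base))
    code <- code %/% base
  }
  sort(labels[labels > 0])
}
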