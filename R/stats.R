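# Paired statistics comparing contact and control direction changes.

#' Paired Wilcoxon signed-rank test
#'
#' Tests whether the paired differences `x - y` are symmetric about zero.
#' Zero differences are dropped (signed-rank convention). With `n <= 25`
#' effective pairs and untied absolute differences the exact null
#' distribution of the rank sum is used; otherwise a normal approximation
#' with continuity correction and tie correction. When every difference is
#' zero the test is degenerate and `p = 1` is reported with a flag.
#'
#' @param x,y Paired numeric vectors of equal length, or `y = NULL` to test
#'   `x` directly as differences.
#' @param exact_max Largest effective n for which the exact distribution is
#'   used (default 25).
#' @return A list with `statistic` (V, the positive-rank sum), `p.value`,
#'   `n_effective`, `method` and `degenerate`.
#' @export
signed_rank_test <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else x - y
  if (anyNA(d)) abort("missing values in the paired differences.")
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(
      statistic = 0, p.value = 1, n_effective = 0L,
      method = "degenerate (all differences zero)", degenerate = TRUE
    ))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- anyDuplicated(r) > 0
  if (n <= exact_max && !ties) {
    p_low <- stats::psignrank(v, n)
    p_high <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact signed-rank distribution"
  } else if (n <= exact_max) {
    # tied ranks: exact null distribution of V by convolution over the
    # (half-integer) ranks, scaled by 2 to stay on integers
    r2 <- round(2 * r)
    tot <- sum(r2)
    cnt <- numeric(tot + 1)
    cnt[1] <- 1
    for (ri in r2) {
      cnt <- cnt + c(rep(0, ri), cnt[seq_len(tot + 1 - ri)])
    }
    v2 <- round(2 * v)
    p_low <- sum(cnt[seq_len(v2 + 1)]) / 2^n
    p_high <- sum(cnt[(v2 + 1):(tot + 1)]) / 2^n
    p <- min(1, 2 * min(p_low, p_high))
    method <- "exact signed-rank distribution (tied ranks)"
  } else {
    mu <- n * (n + 1) / 4
    tie_sizes <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    z <- v - mu
    z <- sign(z) * max(0, abs(z) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity correction"
  }
  list(
    statistic = v, p.value = p, n_effective = n, method = method,
    degenerate = FALSE
  )
}

#' Compare contact and control direction changes
#'
#' Summarises the two paired groups of direction-change angles (degrees) and
#' tests them against each other with a paired Wilcoxon signed-rank test
#' (medians) and a paired t-test (means). Pairs with a missing angle (e.g.
#' degenerate zero-heading cases) are dropped from both groups.
#'
#' @param contact,control Paired numeric vectors of angles in degrees.
#' @param paired If `FALSE`, an unpaired rank-sum / two-sample t comparison
#'   is run instead (sensitivity analysis).
#' @param tc_filter Optional character description of any time-in-clump
#'   filter applied upstream (carried into the result for reporting).
#' @return An object of class `contact_comparison` with [tidy()], [glance()],
#'   [autoplot()] and print methods.
#' @export
compare_groups <- function(contact, control, paired = TRUE, tc_filter = NULL) {
  if (paired && length(contact) != length(control)) {
    abort("paired comparison requires equally long groups.")
  }
  if (paired) {
    ok <- !is.na(contact) & !is.na(control)
    contact <- contact[ok]
    control <- control[ok]
  } else {
    contact <- contact[!is.na(contact)]
    control <- control[!is.na(control)]
  }
  n <- if (paired) length(contact) else c(length(contact), length(control))
  if (min(n) < 5) {
    abort("fewer than 5 cases per group; the comparison is not meaningful.")
  }
  if (paired) {
    w <- signed_rank_test(contact, control)
    tt <- tryCatch(
      stats::t.test(contact, control, paired = TRUE),
      error = function(e) list(p.value = NA_real_) # constant differences
    )
  } else {
    wt <- stats::wilcox.test(contact, control)
    w <- list(
      statistic = unname(wt$statistic), p.value = wt$p.value,
      n_effective = NA_integer_, method = "rank-sum (unpaired)",
      degenerate = FALSE
    )
    tt <- stats::t.test(contact, control)
  }
  structure(
    list(
      group_contact = contact, group_control = control,
      mean_contact = mean(contact), sd_contact = sd(contact),
      mean_control = mean(control), sd_control = sd(control),
      wilcoxon_p = w$p.value, wilcoxon_statistic = w$statistic,
      wilcoxon_method = w$method, degenerate = w$degenerate,
      ttest_p = tt$p.value, n = length(contact), paired = paired,
      tc_filter = tc_filter
    ),
    class = "contact_comparison"
  )
}

#' Compare angles straight from a measurement table
#'
#' Convenience wrapper pairing the `contact` and `control` rows of a
#' [measure_angles()] table by case, optionally restricted to cases with
#' `TC < tc_max`.
#'
#' @param angles Angle table from [measure_angles()].
#' @param tc_max If not `NULL`, keep only cases with `TC < tc_max`.
#' @param paired Passed to [compare_groups()].
#' @return A `contact_comparison` object.
#' @export
compare_angles <- function(angles, tc_max = NULL, paired = TRUE) {
  if (!is.null(tc_max)) {
    angles <- filter(angles, TC < tc_max)
  }
  wide <- tidyr::pivot_wider(
    select(angles, case_id, kind, theta_deg, TC),
    names_from = kind, values_from = theta_deg
  )
  compare_groups(
    wide$contact, wide$control,
    paired = paired,
    tc_filter = if (is.null(tc_max)) NULL else sprintf("TC < %g", tc_max)
  )
}

#' @export
print.contact_comparison <- function(x, ...) {
  cat("Direction-change comparison (degrees)\n")
  if (!is.null(x$tc_filter)) cat("  filter:   ", x$tc_filter, "\n")
  cat(sprintf(
    "  contact:   mean %6.2f (sd %6.2f)\n", x$mean_contact, x$sd_contact
  ))
  cat(sprintf(
    "  control:   mean %6.2f (sd %6.2f)\n", x$mean_control, x$sd_control
  ))
  cat(sprintf("  n:         %d%s\n", x$n, if (x$paired) " paired" else ""))
  cat(sprintf(
    "  Wilcoxon p: %.4g (%s)\n", x$wilcoxon_p, x$wilcoxon_method
  ))
  cat(sprintf("  t-test p:   %.4g\n", x$ttest_p))
  invisible(x)
}
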