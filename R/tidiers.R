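# broom-style tidiers for fitted comparison objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a contact/control comparison
#'
#' @param x A `contact_comparison` object from [compare_groups()].
#' @param ... Unused.
#' @return One row per group with `group`, `n`, `mean`, `sd`.
#' @export
tidy.contact_comparison <- function(x, ...) {
  tibble(
    group = c("contact", "control"),
    n = c(length(x$group_contact), length(x$group_control)),
    mean = c(x$mean_contact, x$mean_control),
    sd = c(x$sd_contact, x$sd_control)
  )
}

#' Glance at a contact/control comparison
#'
#' @param x A `contact_comparison` object.
#' @param ... Unused.
#' @return A one-row tibble with the group summaries and both p-values.
#' @export
glance.contact_comparison <- function(x, ...) {
  tibble(
    n = x$n,
    mean_contact = x$mean_contact, sd_contact = x$sd_contact,
    mean_control = x$mean_control, sd_control = x$sd_control,
    wilcoxon_p = x$wilcoxon_p, ttest_p = x$ttest_p,
    paired = x$paired,
    tc_filter = if (is.null(x$tc_filter)) NA_character_ else x$tc_filter
  )
}
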