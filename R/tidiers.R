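#' Tidy a chi-squared comparison
#'
#' @param x An `indel_chi2` from [chi2_test()] or [chi2_gof()].
#' @param ... Ignored.
#' @return One-row tibble with `statistic`, `df`, `p_value`, `method`.
#' @export
tidy.indel_chi2 <- function(x, ...) {
  tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
         method = x$convention, correct = x$correct)
}

#' @rdname tidy.indel_chi2
#' @export
glance.indel_chi2 <- function(x, ...) tidy(x)

#' Tidy / glance a germline-filter result
#'
#' `tidy()` returns the somatic indels with a `germline_matched` flag;
#' `glance()` returns the one-row count summary.
#'
#' @param x A `germline_filter` from [filter_germline()].
#' @param ... Ignored.
#' @return A tibble.
#' @export
tidy.germline_filter <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$retained, germline_matched = FALSE),
    dplyr::mutate(x$removed, germline_matched = TRUE)
  )
}

#' @rdname tidy.germline_filter
#' @export
glance.germline_filter <- function(x, ...) {
  tibble(n_input = x$n_input, n_removed = x$n_removed,
         n_retained = x$n_input - x$n_removed,
         overlap_pct = x$overlap_pct)
}

#' Glance at a cross-cohort overlap
#'
#' @param x A `cohort_overlap` from [cohort_overlap()].
#' @param ... Ignored.
#' @return One-row tibble of shared counts and percentages.
#' @export
glance.cohort_overlap <- function(x, ...) {
  tibble(n_a = x$n_a, n_b = x$n_b,
         n_shared_a = x$n_shared_a, n_shared_b = x$n_shared_b,
         shared_a_pct = pct(x$n_shared_a, x$n_a),
         shared_b_pct = pct(x$n_shared_b, x$n_b))
}

#' Long-format view of a cohort summary
#'
#' @param x A `cohort_summary` from [summarize_cohort()].
#' @param ... Ignored.
#' @return Tibble with `cohort`, `metric`, `value`.
#' @export
tidy.cohort_summary <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), -cohort, names_to = "metric",
                      values_to = "value")
}
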