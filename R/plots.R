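#' Plot conservation-score ECDFs by stratum
#'
#' Draws the empirical CDF of per-position conservation scores, one line
#' per stratum, with insertion/deletion distinguished by line type —
#' the standard visual comparison of somatic and germline score
#' distributions.
#'
#' @param object An `indel_score_dist` from [score_distribution()].
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.indel_score_dist <- function(object, ...) {
  ec <- object$ecdf
  colour_var <- if ("cohort" %in% names(ec)) "cohort" else "region_group"
  p <- ggplot2::ggplot(ec, ggplot2::aes(x = score, y = ecdf,
                                        colour = .data[[colour_var]],
                                        linetype = itype)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "phyloP score", y = "cumulative fraction",
                  linetype = "indel type") +
    ggplot2::theme_minimal()
  if ("cohort" %in% names(ec) && "region_group" %in% names(ec)) {
    p <- p + ggplot2::facet_wrap(~region_group)
  }
  p
}

#' Plot the three-state secondary-structure distribution
#'
#' @param object An `ss_dist` from [ss_state_distribution()] (or a tibble
#'   with `state`, `pct`, optionally `cohort`).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.ss_dist <- function(object, ...) {
  df <- as_tibble(object)
  aes <- if ("cohort" %in% names(df)) {
    ggplot2::aes(x = state, y = pct, fill = cohort)
  } else {
    ggplot2::aes(x = state, y = pct)
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "secondary structure", y = "% of affected residues") +
    ggplot2::theme_minimal()
}

#' Plot a stratified TFBS-overlap table
#'
#' @param x A tibble from [overlap_table()] (optionally with a `cohort`
#'   column from row-binding several cohorts).
#' @return A ggplot object.
#' @export
plot_overlap_table <- function(x) {
  aes <- if ("cohort" %in% names(x)) {
    ggplot2::aes(x = stratum, y = pct, fill = cohort)
  } else {
    ggplot2::aes(x = stratum, y = pct)
  }
  ggplot2::ggplot(x, aes) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "% overlapping TFBSs") +
    ggplot2::theme_minimal()
}
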