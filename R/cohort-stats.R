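#' Table percentage with half-up rounding
#'
#' All report percentages are `100 * numerator / denominator` rounded
#' half-up to two decimals (so 16.735 prints as 16.74). A zero or missing
#' denominator yields `NA`.
#'
#' @param num,den Non-negative counts (vectorized).
#' @param digits Decimal places (default 2).
#' @return Numeric vector of percentages.
#' @examples
#' pct(18391, 109856) # 16.74
#' @export
pct <- function(num, den, digits = 2L) {
  out <- ifelse(!is.na(den) & den > 0, round_half_up(100 * num / den, digits),
                NA_real_)
  out
}

round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Cohort summary counts and percentages
#'
#' Builds the one-row cohort summary mirroring the standard report layout:
#' transcript indels, deletion/insertion split, CDS/UTR counts, FS/NFS
#' split, and (when TFBS overlap has been annotated) the stratified overlap
#' counts. The CDS and UTR percentages are calculated against the number of
#' transcript indels; deletion/insertion and FS/NFS percentages use their
#' immediate parent denominators; TFBS percentages use the stratum totals.
#'
#' @param annotated Annotated indel tibble (`region`, `frame`, optionally
#'   `overlaps_tfbs`).
#' @param cohort Label for the summary row; defaults to the `cohort` column
#'   value when unique.
#' @param n_total Total call-set size before any filtering (defaults to
#'   `nrow(annotated)`).
#' @param n_germline_matched Number of indels removed as germline matches,
#'   if a [filter_germline()] step preceded annotation.
#' @return One-row tibble of class `cohort_summary`.
#' @export
summarize_cohort <- function(annotated, cohort = NULL, n_total = NULL,
                             n_germline_matched = NULL) {
  if (is.null(cohort)) {
    cohort <- if ("cohort" %in% names(annotated) &&
                  dplyr::n_distinct(annotated$cohort) == 1L &&
                  nrow(annotated) > 0L)
      annotated$cohort[1] else NA_character_
  }
  if (is.null(n_total)) n_total <- nrow(annotated)
  tx <- annotated[annotated$region != "intergenic", , drop = FALSE]
  cds <- tx[tx$region == "CDS", , drop = FALSE]
  n_tx <- nrow(tx)
  n_del <- sum(tx$itype == "deletion")
  n_ins <- sum(tx$itype == "insertion")
  n_complex <- sum(tx$itype == "complex")
  n_cds <- nrow(cds)
  n_fs <- sum(cds$frame == "FS")
  n_nfs <- sum(cds$frame == "NFS")
  n_utr5 <- sum(tx$region == "UTR5")
  n_utr3 <- sum(tx$region == "UTR3")
  out <- tibble(
    cohort = cohort,
    total_indels = n_total,
    germline_matched = n_germline_matched %||% NA_integer_,
    germline_pct = if (is.null(n_germline_matched)) NA_real_
                   else pct(n_germline_matched, n_total),
    transcript_indels = n_tx,
    n_transcripts = dplyr::n_distinct(tx$transcript_id),
    deletions = n_del, deletion_pct = pct(n_del, n_tx),
    insertions = n_ins, insertion_pct = pct(n_ins, n_tx),
    complex_indels = n_complex,
    cds_indels = n_cds, cds_pct = pct(n_cds, n_tx),
    n_transcripts_cds = dplyr::n_distinct(cds$transcript_id),
    fs_indels = n_fs, fs_pct = pct(n_fs, n_cds),
    nfs_indels = n_nfs, nfs_pct = pct(n_nfs, n_cds),
    utr5_indels = n_utr5, utr5_pct = pct(n_utr5, n_tx),
    utr3_indels = n_utr3, utr3_pct = pct(n_utr3, n_tx)
  )
  if ("overlaps_tfbs" %in% names(annotated)) {
    non_cds <- tx[tx$region != "CDS", , drop = FALSE]
    out$tfbs_overlap <- sum(tx$overlaps_tfbs)
    out$tfbs_overlap_pct <- pct(sum(tx$overlaps_tfbs), n_tx)
    out$cds_tfbs_overlap <- sum(cds$overlaps_tfbs)
    out$cds_tfbs_overlap_pct <- pct(sum(cds$overlaps_tfbs), n_cds)
    out$non_cds_tfbs_overlap <- sum(non_cds$overlaps_tfbs)
    out$non_cds_tfbs_overlap_pct <- pct(sum(non_cds$overlaps_tfbs),
                                        nrow(non_cds))
  }
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Pearson chi-squared test on a contingency table
#'
#' Thin, checked wrapper around [stats::chisq.test()] for the r x c count
#' comparisons between cohorts. The default is no continuity correction;
#' `correct = TRUE` applies the Yates correction for 2 x 2 tables.
#'
#' @param x Matrix (or data frame) of non-negative counts, at least 2 x 2.
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#' @return Object of class `indel_chi2` wrapping the `htest`; `tidy()` and
#'   `glance()` methods are provided.
#' @export
chi2_test <- function(x, correct = FALSE) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("contingency table must be at least 2 x 2", call. = FALSE)
  }
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("contingency table has a zero marginal", call. = FALSE)
  }
  ht <- stats::chisq.test(x, correct = correct)
  out <- list(htest = ht, statistic = unname(ht$statistic),
              df = unname(ht$parameter), p_value = ht$p.value,
              correct = correct, convention = "pearson_rxc")
  class(out) <- "indel_chi2"
  out
}

#' Chi-squared goodness of fit against reference proportions
#'
#' One-sample counterpart of [chi2_test()]: compares observed counts (e.g.
#' a cancer cohort's deletion/insertion split) against the proportions of a
#' reference cohort (e.g. the germline panel).
#'
#' @param observed Vector of observed counts.
#' @param expected Reference counts or proportions (normalized internally).
#' @return Object of class `indel_chi2`.
#' @export
chi2_gof <- function(observed, expected) {
  p <- expected / sum(expected)
  ht <- stats::chisq.test(observed, p = p)
  out <- list(htest = ht, statistic = unname(ht$statistic),
              df = unname(ht$parameter), p_value = ht$p.value,
              correct = FALSE, convention = "gof_vs_reference_proportions")
  class(out) <- "indel_chi2"
  out
}

#' @export
print.indel_chi2 <- function(x, ...) {
  cat("<indel_chi2> X-squared = ", format(x$statistic), ", df = ", x$df,
      ", p = ", format(x$p_value, digits = 4), " [", x$convention, "]\n",
      sep = "")
  invisible(x)
}

#' Rank genes by indel count
#'
#' @param annotated Annotated indel tibble.
#' @param region Region filter (default `"CDS"`); `NULL` counts all
#'   transcript indels.
#' @param n Keep the top `n` genes (default all).
#' @return Tibble `gene_symbol`, `n`, descending with alphabetical
#'   tie-break.
#' @export
top_genes <- function(annotated, region = "CDS", n = Inf) {
  x <- annotated[!is.na(annotated$gene_symbol), , drop = FALSE]
  if (!is.null(region)) {
    x <- x[x$region %in% region, , drop = FALSE]
  } else {
    x <- x[x$region != "intergenic", , drop = FALSE]
  }
  out <- x |>
    dplyr::count(gene_symbol, name = "n") |>
    dplyr::arrange(dplyr::desc(n), gene_symbol)
  if (is.finite(n)) out <- utils::head(out, n)
  out
}

#' Summary of indels in a significantly-mutated-gene list
#'
#' Restricts a cohort to a gene list (e.g. the 125 protein-coding SMGs) and
#' tabulates the standard columns: indels in the listed genes, listed genes
#' with CDS indels (percentage of the list size), CDS indels (percentage of
#' listed-gene indels), CDS indels overlapping TFBSs (percentage of listed
#' CDS indels), and the non-CDS complements.
#'
#' @param annotated Annotated indel tibble with `overlaps_tfbs`.
#' @param smg_genes Character vector of gene symbols; symbols absent from
#'   the cohort's annotation are retained for matching with a warning.
#' @param cohort Label for the row.
#' @return One-row tibble.
#' @export
smg_table <- function(annotated, smg_genes, cohort = NULL) {
  stopifnot(all(c("region", "gene_symbol", "overlaps_tfbs") %in%
                  names(annotated)))
  if (is.null(cohort)) {
    cohort <- if ("cohort" %in% names(annotated) && nrow(annotated) > 0L)
      annotated$cohort[1] else NA_character_
  }
  known <- unique(annotated$gene_symbol)
  unknown <- setdiff(smg_genes, known)
  if (length(unknown) > 0L) {
    warning(length(unknown), " gene-list symbol(s) not seen in the cohort ",
            "annotation; retained for matching", call. = FALSE)
  }
  x <- annotated[annotated$region != "intergenic" &
                   !is.na(annotated$gene_symbol) &
                   annotated$gene_symbol %in% smg_genes, , drop = FALSE]
  cds <- x[x$region == "CDS", , drop = FALSE]
  non_cds <- x[x$region != "CDS", , drop = FALSE]
  tibble(
    cohort = cohort,
    smg_indels = nrow(x),
    smgs_with_cds_indels = dplyr::n_distinct(cds$gene_symbol),
    smgs_with_cds_pct = pct(dplyr::n_distinct(cds$gene_symbol),
                            length(smg_genes)),
    smg_cds_indels = nrow(cds),
    smg_cds_pct = pct(nrow(cds), nrow(x)),
    smg_cds_tfbs_overlap = sum(cds$overlaps_tfbs),
    smg_cds_tfbs_pct = pct(sum(cds$overlaps_tfbs), nrow(cds)),
    smg_non_cds_indels = nrow(non_cds),
    smg_non_cds_tfbs_overlap = sum(non_cds$overlaps_tfbs),
    smg_non_cds_tfbs_pct = pct(sum(non_cds$overlaps_tfbs), nrow(non_cds))
  )
}

#' Hypergeometric gene-set enrichment with Bonferroni correction
#'
#' One-sided hypergeometric tail test of each gene set against a hit list,
#' a generic replacement for web-service enrichment tools: `p` is the
#' probability of observing at least the attained overlap when
#' `length(hits)` genes are drawn from the background. Bonferroni adjusts
#' over the number of sets actually tested; significance is flagged at
#' `alpha` (default 0.001).
#'
#' @param hits Character vector of hit gene symbols (must be a subset of
#'   `background`).
#' @param background Character vector of background gene symbols.
#' @param sets Named list of character vectors.
#' @param alpha Significance cutoff on the adjusted p-value.
#' @return Tibble `set`, `set_size`, `overlap`, `p_value`, `p_adjusted`,
#'   `significant`; sets with zero background overlap are skipped with a
#'   message.
#' @export
enrich_gene_sets <- function(hits, background, sets, alpha = 0.001) {
  hits <- unique(hits); background <- unique(background)
  if (!all(hits %in% background)) {
    stop("`hits` must be a subset of `background`", call. = FALSE)
  }
  N <- length(background); K <- length(hits)
  in_bg <- lapply(sets, intersect, background)
  skipped <- names(sets)[lengths(in_bg) == 0L]
  if (length(skipped) > 0L) {
    message("skipping ", length(skipped),
            " set(s) with no background overlap")
  }
  keep <- lengths(in_bg) > 0L
  m_tested <- sum(keep)
  out <- purrr::imap_dfr(in_bg[keep], function(g, nm) {
    m <- length(g)
    k <- length(intersect(hits, g))
    p <- stats::phyper(k - 1, m, N - m, K, lower.tail = FALSE)
    tibble(set = nm, set_size = m, overlap = k, p_value = p)
  })
  if (nrow(out) == 0L) {
    return(tibble(set = character(), set_size = integer(),
                  overlap = integer(), p_value = double(),
                  p_adjusted = double(), significant = logical()))
  }
  out$p_adjusted <- pmin(1, out$p_value * m_tested)
  out$significant <- out$p_adjusted < alpha
  dplyr::arrange(out, p_value, set)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
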