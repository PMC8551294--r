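#' Overlap of indels with TFBS intervals
#'
#' A deletion overlaps a TFBS iff its deleted-base interval intersects the
#' TFBS interval by at least one base; an insertion overlaps iff at least
#' one of its two breakpoint-flanking bases lies inside a TFBS. Each indel
#' counts once however many TFBSs it hits; the per-indel hit count is also
#' reported. Overlap is computed genome-wide and can then be stratified by
#' region class.
#'
#' @param indels Normalized (optionally annotated) indel tibble.
#' @param tfbs Sorted, disjoint TFBS tibble from [read_tfbs_bed()].
#' @return `indels` with `n_tfbs_hit` and `overlaps_tfbs` columns.
#' @export
annotate_tfbs_overlap <- function(indels, tfbs) {
  if (!"indel_id" %in% names(indels)) {
    indels$indel_id <- seq_len(nrow(indels))
  }
  if (nrow(indels) == 0L) {
    indels$n_tfbs_hit <- integer(); indels$overlaps_tfbs <- logical()
    return(indels)
  }
  if (nrow(tfbs) == 0L) {
    indels$n_tfbs_hit <- 0L
    indels$overlaps_tfbs <- FALSE
    return(indels)
  }
  fp <- indel_footprint(indels)
  hits <- interval_hits(fp, tfbs)
  cnt <- tabulate(hits$q, nbins = nrow(indels))
  indels$n_tfbs_hit <- as.integer(cnt)
  indels$overlaps_tfbs <- cnt >= 1L
  indels
}

#' Stratified indel-TFBS overlap table
#'
#' Counts and percentages of TFBS-overlapping indels in the strata used by
#' the cohort reports: all transcript indels, CDS indels, and non-CDS
#' transcript indels. Percentage denominators are the stratum totals; empty
#' strata report a missing percentage.
#'
#' @param annotated Indel tibble with `region` and `overlaps_tfbs` columns.
#' @param genes Optional gene-symbol restriction (e.g. an SMG list).
#' @return Tibble `stratum`, `n`, `n_overlap`, `pct`.
#' @export
overlap_table <- function(annotated, genes = NULL) {
  stopifnot(all(c("region", "overlaps_tfbs") %in% names(annotated)))
  x <- annotated
  if (!is.null(genes)) {
    x <- x[!is.na(x$gene_symbol) & x$gene_symbol %in% genes, , drop = FALSE]
  }
  tx <- x[x$region != "intergenic", , drop = FALSE]
  strata <- list(
    transcript = tx,
    CDS = tx[tx$region == "CDS", , drop = FALSE],
    non_CDS = tx[tx$region != "CDS", , drop = FALSE]
  )
  purrr::imap_dfr(strata, function(s, nm) {
    tibble(stratum = nm, n = nrow(s), n_overlap = sum(s$overlaps_tfbs),
           pct = if (nrow(s) == 0L) NA_real_
                 else pct(sum(s$overlaps_tfbs), nrow(s)))
  })
}
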