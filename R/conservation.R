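#' Genomic positions scored for conservation, per indel
#'
#' Implements the collection rule for per-base conservation scoring: every
#' deleted base position for a deletion (`pos + 1 ... pos + |seq|`, 1-based)
#' and the two breakpoint-flanking positions for an insertion (`pos`,
#' `pos + 1`), clipped at position 1 for insertions at a chromosome start.
#' Complex records contribute their trimmed REF span.
#'
#' @param indels Normalized indel tibble (an `indel_id` column is added if
#'   absent).
#' @return Tibble `indel_id`, `chrom`, `pos` (1-based), one row per
#'   collected position.
#' @export
collect_positions <- function(indels) {
  if (!"indel_id" %in% names(indels)) {
    indels$indel_id <- seq_len(nrow(indels))
  }
  if (nrow(indels) == 0L) {
    return(tibble(indel_id = integer(), chrom = character(), pos = integer()))
  }
  n_pos <- ifelse(indels$itype == "deletion", nchar(indels$seq),
           ifelse(indels$itype == "insertion", 2L,
                  nchar(indels$ref_allele) - 1L))
  n_pos <- pmax(as.integer(n_pos), 1L)
  first <- ifelse(indels$itype == "insertion", indels$pos, indels$pos + 1L)
  out <- tibble(
    indel_id = rep(indels$indel_id, n_pos),
    chrom = rep(indels$chrom, n_pos),
    pos = as.integer(rep(first, n_pos) +
                       (sequence(n_pos) - 1L))
  )
  out[out$pos >= 1L, , drop = FALSE]
}

#' Conservation scores at indel positions
#'
#' Looks up the track at every collected position; positions absent from
#' the track are dropped from score lists and counted in `n_missing`.
#'
#' @param indels Normalized indel tibble.
#' @param track Conservation track tibble from [read_conservation()].
#' @return Tibble `indel_id`, `chrom`, `pos`, `score`, `missing_score`, with
#'   attribute `n_missing`.
#' @export
score_indels <- function(indels, track) {
  scored <- lookup_scores(collect_positions(indels), track)
  attr(scored, "n_missing") <- sum(scored$missing_score)
  scored
}

#' Per-stratum score distributions (histograms and ECDFs)
#'
#' Builds the exportable distribution tables behind conservation-score
#' figures: one histogram and one empirical CDF per stratum, where strata
#' are the combinations of region group (CDS vs UTR, the two UTR classes
#' pooled) and indel type, optionally crossed with a `cohort` column.
#'
#' @param annotated Annotated indel tibble (needs `region`, `itype`).
#' @param track Conservation track tibble.
#' @param binwidth Histogram bin width in score units (default 0.5).
#' @return An object of class `indel_score_dist`: list with `ecdf` and
#'   `hist` tibbles. `autoplot()` draws the ECDF panel.
#' @export
score_distribution <- function(annotated, track, binwidth = 0.5) {
  # local row key; cohorts bound together may carry clashing ids
  annotated$indel_id <- seq_len(nrow(annotated))
  x <- annotated |>
    dplyr::mutate(region_group = dplyr::case_when(
      region == "CDS" ~ "CDS",
      region %in% c("UTR5", "UTR3") ~ "UTR",
      TRUE ~ "other"
    ))
  keep_cols <- c("indel_id", "region_group", "itype",
                 intersect("cohort", names(x)))
  scored <- score_indels(x, track) |>
    dplyr::filter(!missing_score) |>
    dplyr::left_join(x[, c("indel_id", setdiff(keep_cols, "indel_id"))],
                     by = "indel_id")
  grp <- intersect(c("cohort", "region_group", "itype"), names(scored))
  ecdf_tbl <- scored |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::arrange(score, .by_group = TRUE) |>
    dplyr::mutate(ecdf = dplyr::row_number() / dplyr::n()) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(grp, "score")))) |>
    dplyr::summarise(ecdf = max(ecdf), .groups = "drop")
  hist_tbl <- scored |>
    dplyr::mutate(bin = floor(score / binwidth) * binwidth) |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), bin, name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::mutate(density = n / sum(n) / binwidth) |>
    dplyr::ungroup()
  out <- list(ecdf = ecdf_tbl, hist = hist_tbl, binwidth = binwidth)
  class(out) <- "indel_score_dist"
  out
}

#' Rank genes by conserved indel positions
#'
#' Counts, per gene, the CDS indel positions whose conservation score is
#' strictly above the cutoff, split into the TFBS-overlap and no-overlap
#' strata, and ranks genes by that count (descending, ties by gene symbol).
#' Positions contributed by several indels of the same gene are counted
#' once per (gene, position) by default; `dedup_positions = FALSE` restores
#' per-occurrence counting.
#'
#' @param annotated Annotated indel tibble with `region`, `gene_symbol` and
#'   `overlaps_tfbs` columns (see [annotate_tfbs_overlap()]).
#' @param track Conservation track tibble.
#' @param cutoff Score cutoff; positions must exceed it strictly (default 5).
#' @param dedup_positions Count each (gene, position) once (default `TRUE`).
#' @return Tibble `stratum` (`cds_tfbs_overlap` / `cds_no_tfbs_overlap`),
#'   `gene_symbol`, `n_positions`, ranked within stratum.
#' @export
rank_conserved_genes <- function(annotated, track, cutoff = 5,
                                 dedup_positions = TRUE) {
  stopifnot(all(c("region", "overlaps_tfbs", "gene_symbol") %in%
                  names(annotated)))
  annotated$indel_id <- seq_len(nrow(annotated))  # local row key
  cds <- annotated[annotated$region == "CDS", , drop = FALSE]
  if (nrow(cds) == 0L) {
    return(tibble(stratum = character(), gene_symbol = character(),
                  n_positions = integer()))
  }
  scored <- score_indels(cds, track) |>
    dplyr::filter(!missing_score, score > cutoff) |>
    dplyr::left_join(cds[, c("indel_id", "gene_symbol", "overlaps_tfbs")],
                     by = "indel_id") |>
    dplyr::mutate(stratum = ifelse(overlaps_tfbs, "cds_tfbs_overlap",
                                   "cds_no_tfbs_overlap"))
  if (dedup_positions) {
    scored <- dplyr::distinct(scored, stratum, gene_symbol, chrom, pos)
  }
  scored |>
    dplyr::count(stratum, gene_symbol, name = "n_positions") |>
    dplyr::arrange(stratum, dplyr::desc(n_positions), gene_symbol)
}
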