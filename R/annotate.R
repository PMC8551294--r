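#' Select one representative transcript per gene
#'
#' Follows the longest-transcript convention: the transcript with the
#' largest exonic length represents its gene; ties are broken by the
#' lexicographically smallest transcript id. An optional priority list (e.g.
#' canonical transcript tags) overrides the length rule for genes it names.
#' Genes with no valid transcript are excluded with a warning.
#'
#' @param transcripts Tibble from [read_transcripts()].
#' @param priority Optional character vector of transcript ids that take
#'   precedence (earlier entries win).
#' @return Tibble with one row per gene.
#' @export
select_representative_transcripts <- function(transcripts, priority = NULL) {
  n_genes_in <- dplyr::n_distinct(transcripts$gene_id)
  tx <- transcripts[transcripts$valid, , drop = FALSE]
  if (dplyr::n_distinct(tx$gene_id) < n_genes_in) {
    warning(n_genes_in - dplyr::n_distinct(tx$gene_id),
            " gene(s) with no valid transcript excluded", call. = FALSE)
  }
  tx$.prio <- match(tx$transcript_id, priority)
  tx |>
    dplyr::group_by(gene_id) |>
    dplyr::arrange(.prio, dplyr::desc(exonic_length), transcript_id,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".prio")
}

# Flattened region intervals of a representative transcript set, with
# precedence ranks: CDS (1) > UTR5 (2) > UTR3 (3) > rest of the transcript
# span (4). 0-based half-open.
region_index <- function(tx) {
  one <- function(row_ivl, region, rank, i) {
    ivl <- row_ivl[[i]]
    if (nrow(ivl) == 0L) return(NULL)
    tibble(chrom = tx$chrom[i], start = ivl$start, end = ivl$end,
           region = region, rank = rank,
           transcript_id = tx$transcript_id[i], gene_id = tx$gene_id[i],
           gene_symbol = tx$gene_symbol[i])
  }
  pieces <- purrr::map(seq_len(nrow(tx)), function(i) {
    dplyr::bind_rows(
      one(tx$cds, "CDS", 1L, i),
      one(tx$utr5, "UTR5", 2L, i),
      one(tx$utr3, "UTR3", 3L, i),
      tibble(chrom = tx$chrom[i], start = tx$tx_start[i], end = tx$tx_end[i],
             region = "other_transcript", rank = 4L,
             transcript_id = tx$transcript_id[i], gene_id = tx$gene_id[i],
             gene_symbol = tx$gene_symbol[i])
    )
  })
  dplyr::bind_rows(pieces)
}

# overlaps between 0-based half-open interval tibbles, as a hits tibble
interval_hits <- function(query, subject) {
  q <- GenomicRanges::GRanges(query$chrom,
                              IRanges::IRanges(query$start + 1L,
                                               pmax(query$end, query$start + 1L)))
  s <- GenomicRanges::GRanges(subject$chrom,
                              IRanges::IRanges(subject$start + 1L, subject$end))
  h <- suppressWarnings(GenomicRanges::findOverlaps(q, s))
  tibble(q = S4Vectors::queryHits(h), s = S4Vectors::subjectHits(h))
}

#' Classify indels against transcript regions
#'
#' Assigns each indel exactly one region: `CDS`, `UTR5`, `UTR3`,
#' `other_transcript` (inside a transcript span but not exonic CDS/UTR, i.e.
#' mostly intronic), or `intergenic`. Deletions are classified by their
#' deleted-base span, insertions by the two bases flanking the breakpoint.
#' A footprint crossing a boundary takes the highest-precedence region
#' (CDS > UTR5 > UTR3 > other_transcript); UTR labels are strand-aware.
#'
#' @param indels Normalized indel tibble.
#' @param transcripts Representative transcript tibble (one row per gene,
#'   see [select_representative_transcripts()]); a multi-transcript tibble is
#'   reduced with the default rules.
#' @return `indels` with columns `indel_id`, `region`, `transcript_id`,
#'   `gene_id`, `gene_symbol` appended.
#' @export
classify_region <- function(indels, transcripts) {
  if (!all(c("exons", "cds") %in% names(transcripts))) {
    stop("`transcripts` must come from read_transcripts()", call. = FALSE)
  }
  if (anyDuplicated(transcripts$gene_id)) {
    transcripts <- select_representative_transcripts(transcripts)
  }
  if (!"indel_id" %in% names(indels)) {
    indels$indel_id <- seq_len(nrow(indels))
  }
  idx <- region_index(transcripts)
  fp <- indel_footprint(indels)
  hits <- interval_hits(fp, idx)
  best <- hits |>
    dplyr::mutate(rank = idx$rank[s],
                  gene_symbol = idx$gene_symbol[s],
                  transcript_id = idx$transcript_id[s],
                  gene_id = idx$gene_id[s],
                  region = idx$region[s]) |>
    dplyr::arrange(q, rank, gene_symbol, transcript_id) |>
    dplyr::distinct(q, .keep_all = TRUE)
  indels$region <- "intergenic"
  indels$transcript_id <- NA_character_
  indels$gene_id <- NA_character_
  indels$gene_symbol <- NA_character_
  indels$region[best$q] <- best$region
  indels$transcript_id[best$q] <- best$transcript_id
  indels$gene_id[best$q] <- best$gene_id
  indels$gene_symbol[best$q] <- best$gene_symbol
  indels
}

#' Frameshift / non-frameshift classification of coding indels
#'
#' A CDS indel is non-frameshift (NFS) iff its net length change is a
#' multiple of three nucleotides, otherwise frameshift (FS). Non-CDS indels
#' are `not_coding`; complex records are `complex` and excluded from frame
#' analysis.
#'
#' @param indels Indel tibble with a `region` column (see
#'   [classify_region()]).
#' @return `indels` with a `frame` column.
#' @export
classify_frame <- function(indels) {
  stopifnot("region" %in% names(indels))
  indels$frame <- dplyr::case_when(
    indels$itype == "complex" ~ "complex",
    indels$region != "CDS" ~ "not_coding",
    abs(indels$net_len) %% 3L == 0L ~ "NFS",
    TRUE ~ "FS"
  )
  indels
}

#' Annotate a cohort of indels against transcript models
#'
#' Convenience wrapper: selects representative transcripts, classifies
#' regions and frames.
#'
#' @inheritParams classify_region
#' @param priority Optional transcript priority list.
#' @return Annotated indel tibble with `region` and `frame` columns.
#' @export
annotate_indels <- function(indels, transcripts, priority = NULL) {
  rep_tx <- select_representative_transcripts(transcripts, priority = priority)
  indels |>
    classify_region(rep_tx) |>
    classify_frame()
}

# 1-based CDS offsets (in transcription orientation) of 1-based genomic
# positions; NA for positions outside the CDS.
cds_offsets <- function(tx_row, gpos) {
  cds <- tx_row$cds[[1]]
  if (nrow(cds) == 0L) return(rep(NA_integer_, length(gpos)))
  cds <- dplyr::arrange(cds, start)
  w <- cds$end - cds$start
  if (tx_row$strand == "+") {
    before <- cumsum(c(0L, w[-length(w)]))
    out <- rep(NA_integer_, length(gpos))
    for (j in seq_len(nrow(cds))) {
      inside <- gpos > cds$start[j] & gpos <= cds$end[j]
      out[inside] <- before[j] + (gpos[inside] - cds$start[j])
    }
  } else {
    after <- rev(cumsum(c(0L, rev(w)[-length(w)])))
    out <- rep(NA_integer_, length(gpos))
    for (j in seq_len(nrow(cds))) {
      inside <- gpos > cds$start[j] & gpos <= cds$end[j]
      out[inside] <- after[j] + (cds$end[j] - gpos[inside] + 1L)
    }
  }
  out
}

#' Protein residues affected by non-frameshift coding indels
#'
#' For an NFS deletion the affected residues are those whose codons
#' intersect the deleted bases; for an NFS insertion they are the two
#' residues flanking the breakpoint, clipped at the protein ends. Genomic
#' coordinates are mapped to CDS offsets honoring the transcript strand.
#' Bases of a CDS-classified indel that fall outside the CDS (boundary
#' spanning resolved by precedence) are clipped with a warning.
#'
#' @param indels Annotated indel tibble (needs `region`, `frame`,
#'   `transcript_id`, `indel_id`).
#' @param transcripts Representative transcript tibble.
#' @return Tibble with one row per NFS CDS indel: `indel_id`, `protein_id`
#'   (the transcript id), `start_residue`, `end_residue` (1-based
#'   inclusive), `kind` (`deleted_residues` or `insertion_flanks`).
#' @export
affected_residues <- function(indels, transcripts) {
  nfs <- indels[indels$frame %in% "NFS" &
                  indels$itype %in% c("insertion", "deletion"), , drop = FALSE]
  if (nrow(nfs) == 0L) {
    return(tibble(indel_id = integer(), protein_id = character(),
                  start_residue = integer(), end_residue = integer(),
                  kind = character()))
  }
  tx_by_id <- split(transcripts, transcripts$transcript_id)
  clipped <- FALSE
  rows <- purrr::map(seq_len(nrow(nfs)), function(i) {
    row <- nfs[i, ]
    tx <- tx_by_id[[row$transcript_id]]
    if (is.null(tx)) return(NULL)
    prot_len <- tx$cds_length %/% 3L
    if (row$itype == "deletion") {
      gpos <- seq.int(row$pos + 1L, row$pos + nchar(row$seq))
      off <- cds_offsets(tx, gpos)
      if (anyNA(off)) clipped <<- TRUE
      off <- off[!is.na(off)]
      if (length(off) == 0L) return(NULL)
      res <- sort(unique(pmin(pmax((off + 2L) %/% 3L, 1L), prot_len)))
      kind <- "deleted_residues"
    } else {
      off <- cds_offsets(tx, c(row$pos, row$pos + 1L))
      off <- off[!is.na(off)]
      if (length(off) == 0L) return(NULL)
      res <- (off + 2L) %/% 3L
      res <- sort(unique(pmin(pmax(res, 1L), prot_len)))
      kind <- "insertion_flanks"
    }
    tibble(indel_id = row$indel_id, protein_id = tx$transcript_id,
           start_residue = min(res), end_residue = max(res), kind = kind)
  })
  if (clipped) {
    warning("some CDS-classified indels extend outside the CDS; ",
            "residue spans clipped", call. = FALSE)
  }
  dplyr::bind_rows(rows)
}
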