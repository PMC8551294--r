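#' Read transcript models from GFF3 or GTF
#'
#' Accepts both Ensembl dialects; the attribute syntax is sniffed from the
#' parsed metadata columns. Exon and CDS intervals are collected per
#' transcript, converted to 0-based half-open internal coordinates, and the
#' 5'/3' UTRs are derived as the exonic bases outside the CDS, split by the
#' transcript's strand orientation (on the minus strand the 5' UTR sits at
#' the higher genomic coordinates).
#'
#' @param path Path to a GFF3 or GTF file.
#' @param harmonize_chrom One of `"none"`, `"strip_chr"`, `"add_chr"`.
#' @return A tibble with one row per transcript: `transcript_id`, `gene_id`,
#'   `gene_symbol`, `chrom`, `strand`, `tx_start`, `tx_end` (0-based
#'   half-open span), `exonic_length`, `cds_length`, `coding`, `valid`, and
#'   list-columns `exons`, `cds`, `utr5`, `utr3` (tibbles of `start`, `end`).
#'   Transcripts whose CDS falls outside the exon span are flagged
#'   `valid = FALSE` with a warning.
#' @export
read_transcripts <- function(path,
                             harmonize_chrom = c("none", "strip_chr", "add_chr")) {
  harmonize_chrom <- match.arg(harmonize_chrom)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  fmt <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE)) "gtf" else "gff3"
  gr <- rtracklayer::import(path, format = fmt)
  mc <- S4Vectors::mcols(gr)
  is_gff3 <- "Parent" %in% names(mc)

  chrom <- as.character(GenomicRanges::seqnames(gr))
  chrom <- switch(harmonize_chrom,
    none = chrom,
    strip_chr = sub("^chr", "", chrom),
    add_chr = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
  feat <- tibble(
    chrom = chrom,
    start = GenomicRanges::start(gr) - 1L,  # to 0-based half-open
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(mc$type)
  )
  if (is_gff3) {
    parent <- vapply(as.list(mc$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
    feat$feature_id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
    feat$parent <- parent
    feat$name <- if ("Name" %in% names(mc)) as.character(mc$Name) else NA_character_
    gene_rows <- feat[feat$type == "gene", ]
    gene_symbols <- setNames(gene_rows$name, gene_rows$feature_id)
    tx <- feat[feat$type %in% c("mRNA", "transcript"), ]
    tx$transcript_id <- tx$feature_id
    tx$gene_id <- tx$parent
    parts <- feat[feat$type %in% c("exon", "CDS"), ]
    parts$transcript_id <- parts$parent
  } else {
    feat$transcript_id <- as.character(mc$transcript_id)
    feat$gene_id <- as.character(mc$gene_id)
    feat$name <- if ("gene_name" %in% names(mc))
      as.character(mc$gene_name) else NA_character_
    tx <- feat[feat$type == "transcript", ]
    parts <- feat[feat$type %in% c("exon", "CDS"), ]
    if (nrow(tx) == 0L) {  # exon-only GTFs: synthesize transcript rows
      tx <- parts[parts$type == "exon", ] |>
        dplyr::group_by(transcript_id) |>
        dplyr::summarise(chrom = chrom[1], start = min(start), end = max(end),
                         strand = strand[1], gene_id = gene_id[1],
                         name = name[1], .groups = "drop")
    }
    gene_symbols <- setNames(tx$name, tx$gene_id)
  }

  exon_by_tx <- split(parts[parts$type == "exon", c("start", "end")],
                      parts$transcript_id[parts$type == "exon"])
  cds_by_tx <- split(parts[parts$type == "CDS", c("start", "end")],
                     parts$transcript_id[parts$type == "CDS"])

  rows <- purrr::pmap(
    list(tx$transcript_id, tx$gene_id, tx$chrom, tx$strand),
    function(tid, gid, chr, strd) {
      ex <- exon_by_tx[[tid]]
      if (is.null(ex) || nrow(ex) == 0L) return(NULL)
      ex <- dplyr::arrange(as_tibble(ex), start)
      cd <- cds_by_tx[[tid]]
      cd <- if (is.null(cd)) tibble(start = integer(), end = integer())
            else dplyr::arrange(as_tibble(cd), start)
      ut <- derive_utrs(ex, cd, strd)
      tibble(
        transcript_id = tid, gene_id = gid,
        gene_symbol = NA_character_, chrom = chr, strand = strd,
        tx_start = min(ex$start), tx_end = max(ex$end),
        exonic_length = sum(ex$end - ex$start),
        cds_length = sum(cd$end - cd$start),
        coding = nrow(cd) > 0L, valid = ut$valid,
        exons = list(ex), cds = list(cd),
        utr5 = list(ut$utr5), utr3 = list(ut$utr3)
      )
    }
  )
  out <- dplyr::bind_rows(rows)
  out$gene_symbol <- dplyr::coalesce(unname(gene_symbols[out$gene_id]),
                                     out$gene_id)
  if (any(!out$valid)) {
    warning(sum(!out$valid), " transcript(s) have CDS outside the exon span; ",
            "flagged invalid", call. = FALSE)
  }
  out
}

# exon/CDS interval algebra on 0-based half-open tibbles
derive_utrs <- function(exons, cds, strand) {
  if (nrow(cds) == 0L) {
    return(list(utr5 = tibble(start = integer(), end = integer()),
                utr3 = tibble(start = integer(), end = integer()),
                valid = TRUE))
  }
  ex_ir <- IRanges::IRanges(exons$start + 1L, exons$end)
  cd_ir <- IRanges::IRanges(cds$start + 1L, cds$end)
  valid <- length(IRanges::setdiff(cd_ir, ex_ir)) == 0L
  utr_ir <- IRanges::setdiff(ex_ir, cd_ir)
  utr <- tibble(start = IRanges::start(utr_ir) - 1L, end = IRanges::end(utr_ir))
  cds_lo <- min(cds$start); cds_hi <- max(cds$end)
  before <- utr[utr$end <= cds_lo, ]
  after <- utr[utr$start >= cds_hi, ]
  if (strand == "-") {
    list(utr5 = after, utr3 = before, valid = valid)
  } else {
    list(utr5 = before, utr3 = after, valid = valid)
  }
}

#' Read a set of non-overlapping TFBS intervals from BED
#'
#' BED input is 0-based half-open already; intervals are sorted and the
#' non-overlap promise is verified (touching intervals are allowed).
#'
#' @param path Path to a BED3+ file.
#' @param harmonize_chrom One of `"none"`, `"strip_chr"`, `"add_chr"`.
#' @return Sorted tibble `chrom`, `start`, `end`.
#' @export
read_tfbs_bed <- function(path,
                          harmonize_chrom = c("none", "strip_chr", "add_chr")) {
  harmonize_chrom <- match.arg(harmonize_chrom)
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "BED")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  chrom <- switch(harmonize_chrom,
    none = chrom,
    strip_chr = sub("^chr", "", chrom),
    add_chr = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
  x <- tibble(chrom = chrom,
              start = GenomicRanges::start(gr) - 1L,
              end = GenomicRanges::end(gr)) |>
    dplyr::arrange(chrom, start)
  bad <- x |>
    dplyr::group_by(chrom) |>
    dplyr::filter(dplyr::row_number() > 1L & start < dplyr::lag(end)) |>
    dplyr::ungroup()
  if (nrow(bad) > 0L) {
    stop("TFBS intervals overlap; first collision at ", bad$chrom[1], ":",
         bad$start[1], "-", bad$end[1], call. = FALSE)
  }
  x
}

#' Read a per-base conservation track (bedGraph or fixed-step wig)
#'
#' Expands interval scores to one score per base. Positions covered by more
#' than one line keep the last value, with a warning.
#'
#' @param path Path to a bedGraph (`.bedgraph`/`.bg`) or wiggle (`.wig`)
#'   file.
#' @param format Track format; inferred from the file extension by default.
#' @return Tibble `chrom`, `pos` (1-based), `score`. Lookups for absent
#'   positions are missing, never zero.
#' @export
read_conservation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("track file not found: ", path, call. = FALSE)
  if (is.null(format)) {
    format <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE)) "wig"
              else "bedGraph"
  }
  gr <- rtracklayer::import(path, format = format)
  w <- GenomicRanges::width(gr)
  out <- tibble(
    chrom = rep(as.character(GenomicRanges::seqnames(gr)), w),
    pos = unlist(purrr::map2(GenomicRanges::start(gr),
                             GenomicRanges::end(gr), seq.int)),
    score = rep(S4Vectors::mcols(gr)$score, w)
  )
  dup <- duplicated(out[, c("chrom", "pos")], fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " overlapping track position(s); last value wins",
            call. = FALSE)
    out <- out[!dup, , drop = FALSE]
  }
  out
}

#' Look up conservation scores at genomic positions
#'
#' @param positions Tibble with `chrom` and `pos` (1-based).
#' @param track Tibble from [read_conservation()].
#' @return `positions` with a `score` column (`NA` where the track has no
#'   value) and a logical `missing_score` column.
#' @export
lookup_scores <- function(positions, track) {
  out <- dplyr::left_join(positions, track, by = c("chrom", "pos"))
  out$missing_score <- is.na(out$score)
  out
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and `#` comments are ignored; duplicates
#' are dropped keeping first occurrence.
#'
#' @param path Path to the list file.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("gene list not found: ", path, call. = FALSE)
  x <- trimws(readLines(path, warn = FALSE))
  unique(x[nzchar(x) & !startsWith(x, "#")])
}

#' Read a gene-set collection in GMT format
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE)) {
    stop("reading GMT collections requires the fgsea package", call. = FALSE)
  }
  fgsea::gmtPathways(path)
}

#' Write / read a summary table as TSV
#'
#' Thin, format-stable wrappers used for all report tables; a written table
#' re-read with [read_summary_tsv()] equals the original.
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path` (write) or a tibble (read).
#' @export
write_summary_tsv <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, progress = FALSE)
  invisible(path)
}

#' @rdname write_summary_tsv
#' @export
read_summary_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
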