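# Hand-built fixtures and independent brute-force oracles. The oracles use
# plain per-base loops so they share no code path with the implementation.

empty_ivl <- function() tibble::tibble(start = integer(), end = integer())

# runs of consecutive sorted 1-based positions -> 0-based half-open tibble
runs_to_intervals <- function(pos) {
  if (length(pos) == 0L) return(empty_ivl())
  pos <- sort(pos)
  out <- list()
  s <- pos[1]; prev <- pos[1]
  for (p in pos[-1]) {
    if (p != prev + 1L) {
      out[[length(out) + 1L]] <- c(s, prev)
      s <- p
    }
    prev <- p
  }
  out[[length(out) + 1L]] <- c(s, prev)
  tibble::tibble(start = vapply(out, `[`, 0, 1) - 1L,
                 end = vapply(out, `[`, 0, 2))
}

# construct a transcript-model row in the read_transcripts() schema from
# explicit exon intervals and exonic UTR/CDS lengths
make_transcript <- function(exons, strand = "+", u5 = 0L, u3 = 0L,
                            chrom = "chr1", tid = "TX1", gid = "G1",
                            sym = "GENE1") {
  exons <- dplyr::arrange(exons, start)
  gpos <- unlist(Map(function(s, e) seq.int(s + 1L, e), exons$start,
                     exons$end))
  if (strand == "-") gpos <- rev(gpos)
  L <- length(gpos)
  cds_len <- L - u5 - u3
  stopifnot(cds_len >= 3L)
  tibble::tibble(
    transcript_id = tid, gene_id = gid, gene_symbol = sym,
    chrom = chrom, strand = strand,
    tx_start = min(exons$start), tx_end = max(exons$end),
    exonic_length = L, cds_length = cds_len,
    coding = cds_len > 0L, valid = TRUE,
    exons = list(exons),
    cds = list(runs_to_intervals(gpos[u5 + seq_len(cds_len)])),
    utr5 = list(runs_to_intervals(gpos[seq_len(u5)])),
    utr3 = list(runs_to_intervals(gpos[u5 + cds_len + seq_len(u3)]))
  )
}

# random small gene model, both strands, 1-3 exons
rand_transcript <- function(id = 1L, chrom = "chr1") {
  n_ex <- sample(1:3, 1)
  widths <- sample(30:60, n_ex, replace = TRUE)
  introns <- if (n_ex > 1) sample(10:30, n_ex - 1, replace = TRUE) else integer()
  starts <- integer(n_ex)
  starts[1] <- sample(10:50, 1)
  if (n_ex > 1) for (j in 2:n_ex) {
    starts[j] <- starts[j - 1] + widths[j - 1] + introns[j - 1]
  }
  exons <- tibble::tibble(start = starts, end = starts + widths)
  L <- sum(widths)
  u5 <- sample(0:10, 1); u3 <- sample(0:10, 1)
  cds_len <- L - u5 - u3
  u3 <- u3 + cds_len %% 3L
  make_transcript(exons, strand = sample(c("+", "-"), 1), u5 = u5, u3 = u3,
                  chrom = chrom, tid = sprintf("TX%03d", id),
                  gid = sprintf("G%03d", id), sym = sprintf("GENE%03d", id))
}

make_indels <- function(chrom, pos, itype, seq, cohort = NA_character_) {
  n <- max(length(chrom), length(pos), length(itype), length(seq))
  tibble::tibble(
    chrom = rep_len(chrom, n), pos = as.integer(rep_len(pos, n)),
    itype = rep_len(itype, n), seq = toupper(rep_len(seq, n))
  ) |>
    dplyr::mutate(
      ref_allele = ifelse(itype == "deletion", paste0("N", seq), "N"),
      alt_allele = ifelse(itype == "deletion", "N", paste0("N", seq)),
      net_len = ifelse(itype == "deletion", -nchar(seq), nchar(seq)),
      cohort = cohort
    )
}

rand_indels <- function(n, chrom = "chr1", pos_range = c(1L, 300L),
                        max_len = 6L) {
  len <- sample(seq_len(max_len), n, replace = TRUE)
  seqs <- vapply(len, function(k)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
    character(1))
  make_indels(chrom = sample(chrom, n, replace = TRUE),
              pos = sample(pos_range[1]:pos_range[2], n, replace = TRUE),
              itype = sample(c("deletion", "insertion"), n, replace = TRUE),
              seq = seqs)
}

# 1-based base positions an indel is judged by
oracle_bases <- function(row) {
  if (row$itype == "deletion") {
    seq.int(row$pos + 1L, row$pos + nchar(row$seq))
  } else {
    c(row$pos, row$pos + 1L)
  }
}

in_ivl <- function(b, ivl) {
  any(ivl$start < b & b <= ivl$end)
}

# per-base region scan with CDS > UTR5 > UTR3 > other_transcript precedence
oracle_region <- function(row, transcripts) {
  best_rank <- 5L; best_sym <- NA_character_
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    if (tx$chrom != row$chrom) next
    for (b in oracle_bases(row)) {
      r <- if (in_ivl(b, tx$cds[[1]])) 1L
      else if (in_ivl(b, tx$utr5[[1]])) 2L
      else if (in_ivl(b, tx$utr3[[1]])) 3L
      else if (tx$tx_start < b && b <= tx$tx_end) 4L
      else 5L
      if (r < best_rank ||
          (r == best_rank && !is.na(best_sym) && r < 5L &&
           tx$gene_symbol < best_sym)) {
        best_rank <- r
        best_sym <- tx$gene_symbol
      }
    }
  }
  region <- c("CDS", "UTR5", "UTR3", "other_transcript", "intergenic")[best_rank]
  list(region = region,
       gene_symbol = if (best_rank < 5L) best_sym else NA_character_)
}

# exonic positions of a transcript in transcription order (independent walk)
oracle_tx_positions <- function(tx) {
  ex <- dplyr::arrange(tx$exons[[1]], start)
  gpos <- unlist(Map(function(s, e) seq.int(s + 1L, e), ex$start, ex$end))
  if (tx$strand == "-") gpos <- rev(gpos)
  gpos
}

# affected residues by per-base codon lookup
oracle_residues <- function(row, tx) {
  gpos <- oracle_tx_positions(tx)
  cds_gpos <- gpos[vapply(gpos, in_ivl, TRUE, ivl = tx$cds[[1]])]
  res <- integer(0)
  for (b in oracle_bases(row)) {
    idx <- match(b, cds_gpos)
    if (!is.na(idx)) res <- c(res, ceiling(idx / 3))
  }
  if (length(res) == 0L) return(NULL)
  prot_len <- length(cds_gpos) %/% 3L
  res <- pmin(pmax(res, 1L), prot_len)
  c(min(res), max(res))
}

# quadratic TFBS overlap
oracle_tfbs_overlap <- function(row, tfbs) {
  if (row$itype == "deletion") {
    fs <- row$pos; fe <- row$pos + nchar(row$seq)
  } else {
    fs <- row$pos - 1L; fe <- row$pos + 1L
  }
  hit <- 0L
  for (i in seq_len(nrow(tfbs))) {
    if (tfbs$chrom[i] == row$chrom &&
        tfbs$start[i] < fe && fs < tfbs$end[i]) {
      hit <- hit + 1L
    }
  }
  hit
}

# all-pairs matching oracles
oracle_match_any <- function(a, b, mode = "exact", window = 5L) {
  out <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      same <- if (mode == "exact") {
        a$chrom[i] == b$chrom[j] && a$pos[i] == b$pos[j] &&
          a$itype[i] == b$itype[j] && identical(a$seq[i], b$seq[j])
      } else {
        a$chrom[i] == b$chrom[j] && a$itype[i] == b$itype[j] &&
          abs(a$pos[i] - b$pos[j]) <= window
      }
      if (same) { out[i] <- TRUE; break }
    }
  }
  out
}

write_vcf_text <- function(path, rows) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               rows), path)
}
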