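#' Normalize raw VCF-style indel records
#'
#' Reduces each REF/ALT allele pair to its minimal anchored representation:
#' shared trailing bases are trimmed first, then shared leading bases (the
#' anchor base before the event is kept, per VCF convention). When a reference
#' sequence is supplied the indel is additionally left-aligned to its 5'-most
#' equivalent position. Records whose trimmed alleles both retain bases beyond
#' the anchor are flagged `complex`; equal-length pairs are flagged `snv` so
#' callers can drop them with a count.
#'
#' The returned tibble is the package's core indel representation:
#' * `pos` — 1-based anchored position (the base *before* the event),
#' * `itype` — `"insertion"`, `"deletion"`, `"complex"` or `"snv"`,
#' * `seq` — the inserted or deleted bases (uppercase),
#' * `net_len` — signed length change `nchar(alt) - nchar(ref)`.
#'
#' @param x A data frame with columns `chrom`, `pos`, `ref`, `alt`; any other
#'   columns (e.g. `cohort`, `sample_id`) are carried through.
#' @param reference Optional named character vector (or list) of chromosome
#'   sequences used for left alignment. Names must match `chrom`.
#' @return A tibble with columns `chrom`, `pos`, `ref_allele`, `alt_allele`,
#'   `itype`, `seq`, `net_len` plus carried-through columns. Normalization is
#'   idempotent.
#' @examples
#' normalize_indels(tibble::tibble(
#'   chrom = "chr1", pos = c(100L, 55L), ref = c("CA", "C"),
#'   alt = c("C", "CTTG")
#' ))
#' @export
normalize_indels <- function(x, reference = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(x)))
  extra <- x[setdiff(names(x), c("chrom", "pos", "ref", "alt",
                                 "ref_allele", "alt_allele",
                                 "itype", "seq", "net_len"))]
  ref <- toupper(as.character(x$ref))
  alt <- toupper(as.character(x$alt))
  pos <- as.integer(x$pos)
  chrom <- as.character(x$chrom)

  # trim shared trailing bases while both alleles keep >= 2 characters
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    can <- nr > 1L & na > 1L &
      substr(ref, nr, nr) == substr(alt, na, na)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 1L, nr[can] - 1L)
    alt[can] <- substr(alt[can], 1L, na[can] - 1L)
  }
  # trim shared leading bases, advancing the anchor
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    can <- nr > 1L & na > 1L &
      substr(ref, 1L, 1L) == substr(alt, 1L, 1L)
    if (!any(can)) break
    ref[can] <- substr(ref[can], 2L, nr[can])
    alt[can] <- substr(alt[can], 2L, na[can])
    pos[can] <- pos[can] + 1L
  }

  nr <- nchar(ref); na <- nchar(alt)
  itype <- rep(NA_character_, length(ref))
  sq <- rep(NA_character_, length(ref))

  ins <- na > nr & nr == 1L & substr(alt, 1L, 1L) == ref
  del <- nr > na & na == 1L & substr(ref, 1L, 1L) == alt
  itype[ins] <- "insertion"; sq[ins] <- substr(alt[ins], 2L, na[ins])
  itype[del] <- "deletion";  sq[del] <- substr(ref[del], 2L, nr[del])

  # suffix-anchored forms (anchor base after the event): re-anchor before it
  ins2 <- is.na(itype) & na > nr & nr == 1L & substr(alt, na, na) == ref
  del2 <- is.na(itype) & nr > na & na == 1L & substr(ref, nr, nr) == alt
  if (any(ins2)) {
    sq[ins2] <- substr(alt[ins2], 1L, na[ins2] - 1L)
    itype[ins2] <- "insertion"
    pos[ins2] <- pos[ins2] - 1L
    alt[ins2] <- paste0("N", sq[ins2]); ref[ins2] <- "N"
  }
  if (any(del2)) {
    sq[del2] <- substr(ref[del2], 1L, nr[del2] - 1L)
    itype[del2] <- "deletion"
    pos[del2] <- pos[del2] - 1L
    ref[del2] <- paste0("N", sq[del2]); alt[del2] <- "N"
  }

  itype[is.na(itype) & nr == 1L & na == 1L] <- "snv"
  itype[is.na(itype)] <- "complex"  # MNV-like or mixed records
  # non-ACGT event sequence disqualifies a simple indel call
  bad_seq <- !is.na(sq) & !grepl("^[ACGT]+$", sq)
  itype[bad_seq] <- "complex"
  sq[itype %in% c("snv", "complex")] <- NA_character_

  out <- tibble(
    chrom = chrom, pos = pos,
    ref_allele = ref, alt_allele = alt,
    itype = itype, seq = sq,
    net_len = nchar(alt) - nchar(ref)
  )
  out <- dplyr::bind_cols(out, extra)

  if (!is.null(reference)) {
    out <- left_align_indels(out, reference)
  }
  out
}

# Shift simple indels to their 5'-most equivalent position given reference
# chromosome sequences. Scalar loop per record; alleles are short.
left_align_indels <- function(x, reference) {
  simple <- which(x$itype %in% c("insertion", "deletion"))
  for (i in simple) {
    chr_seq <- reference[[x$chrom[i]]]
    if (is.null(chr_seq) || is.na(chr_seq)) next
    p <- x$pos[i]
    s <- strsplit(x$seq[i], "")[[1]]
    L <- length(s)
    while (p >= 1L && substr(chr_seq, p, p) == s[L]) {
      s <- c(s[L], s[-L])
      p <- p - 1L
    }
    anchor <- if (p >= 1L) substr(chr_seq, p, p) else "N"
    x$pos[i] <- p
    x$seq[i] <- paste(s, collapse = "")
    if (x$itype[i] == "deletion") {
      x$ref_allele[i] <- paste0(anchor, x$seq[i])
      x$alt_allele[i] <- anchor
    } else {
      x$ref_allele[i] <- anchor
      x$alt_allele[i] <- paste0(anchor, x$seq[i])
    }
  }
  x
}

#' Validate the invariants of a normalized indel tibble
#'
#' Checks the structural invariants of the core representation: type/sign
#' agreement of `net_len`, `|net_len| == nchar(seq)`, and A/C/G/T-only event
#' sequences for simple indels.
#'
#' @param x A tibble from [normalize_indels()].
#' @return `x` invisibly; errors describe the first violated invariant.
#' @export
validate_indels <- function(x) {
  simple <- x$itype %in% c("insertion", "deletion")
  ok_sign <- ifelse(x$itype == "insertion", x$net_len > 0,
             ifelse(x$itype == "deletion", x$net_len < 0, TRUE))
  if (!all(ok_sign)) stop("indel type does not match the sign of net_len")
  if (!all(abs(x$net_len[simple]) == nchar(x$seq[simple]))) {
    stop("|net_len| must equal nchar(seq) for simple indels")
  }
  if (!all(grepl("^[ACGT]+$", x$seq[simple]))) {
    stop("seq must contain only A/C/G/T for simple indels")
  }
  invisible(x)
}

#' Genomic footprint of indels as 0-based half-open intervals
#'
#' The footprint is the interval used for region classification and TFBS
#' overlap: deleted bases for deletions (`[pos, pos + |seq|)`), the two bases
#' flanking the breakpoint for insertions (`[pos - 1, pos + 1)`), and the
#' trimmed REF span for complex records.
#'
#' @param x A normalized indel tibble.
#' @return A tibble `chrom`, `start`, `end` (0-based half-open), row-aligned
#'   with `x`.
#' @export
indel_footprint <- function(x) {
  len <- nchar(x$seq)
  start <- ifelse(x$itype == "deletion", x$pos,
           ifelse(x$itype == "insertion", pmax(x$pos - 1L, 0L),
                  x$pos - 1L))
  end <- ifelse(x$itype == "deletion", x$pos + len,
         ifelse(x$itype == "insertion", x$pos + 1L,
                x$pos - 1L + nchar(x$ref_allele)))
  tibble(chrom = x$chrom, start = as.integer(start), end = as.integer(end))
}

# identity key for exact matching: same position, type and sequence
indel_key <- function(x) {
  paste(x$chrom, x$pos, x$itype, x$seq, sep = "\r")
}
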