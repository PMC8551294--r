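#' Read indels from a VCF file
#'
#' Reads a VCF 4.x file (optionally bgzipped), splits multi-allelic records
#' into one row per ALT allele, normalizes every record with
#' [normalize_indels()], and drops SNV/MNV rows with a counter. Symbolic and
#' missing ALT alleles are skipped.
#'
#' @param path Path to the VCF file.
#' @param cohort Optional cohort label stored in the `cohort` column.
#' @param reference Optional named character vector of chromosome sequences
#'   for left alignment (see [normalize_indels()]).
#' @param keep_complex Keep records flagged `complex` (default `TRUE`); they
#'   are retained in totals but excluded from frame/structure analysis.
#' @param harmonize_chrom One of `"none"`, `"strip_chr"`, `"add_chr"`:
#'   chromosome-name harmonization applied once at load.
#' @return A normalized indel tibble with attributes `n_skipped_snv` and
#'   `n_skipped_other` recording dropped rows.
#' @export
read_indel_vcf <- function(path, cohort = NULL, reference = NULL,
                           keep_complex = TRUE,
                           harmonize_chrom = c("none", "strip_chr", "add_chr")) {
  harmonize_chrom <- match.arg(harmonize_chrom)
  if (!file.exists(path)) stop("VCF file not found: ", path, call. = FALSE)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) {  # single-record files drop to a named vector
    fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  }
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    out <- tibble(chrom = character(), pos = integer(),
                  ref_allele = character(), alt_allele = character(),
                  itype = character(), seq = character(),
                  net_len = integer(), cohort = character(),
                  sample_id = character())
    attr(out, "n_skipped_snv") <- 0L
    attr(out, "n_skipped_other") <- 0L
    return(out)
  }
  x <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
              ref = fix$REF, alt = fix$ALT) |>
    tidyr::separate_rows(alt, sep = ",")
  sym <- is.na(x$alt) | x$alt == "." | grepl("[<>\\[\\]*]", x$alt) |
    is.na(x$ref) | grepl("[^ACGTNacgtn]", x$ref)
  n_other <- sum(sym)
  x <- x[!sym, , drop = FALSE]

  x$chrom <- switch(harmonize_chrom,
    none = x$chrom,
    strip_chr = sub("^chr", "", x$chrom),
    add_chr = ifelse(grepl("^chr", x$chrom), x$chrom, paste0("chr", x$chrom))
  )

  out <- normalize_indels(x, reference = reference)
  n_snv <- sum(out$itype == "snv")
  out <- out[out$itype != "snv", , drop = FALSE]
  if (!keep_complex) {
    n_other <- n_other + sum(out$itype == "complex")
    out <- out[out$itype != "complex", , drop = FALSE]
  }
  out$cohort <- if (is.null(cohort)) NA_character_ else cohort
  out$sample_id <- NA_character_
  attr(out, "n_skipped_snv") <- n_snv
  attr(out, "n_skipped_other") <- n_other
  out
}

#' Write normalized indels to a minimal VCF
#'
#' Emits a VCF 4.2 file with the normalized `ref_allele`/`alt_allele`
#' representation, sorted by chromosome and position.
#'
#' @param x Normalized indel tibble.
#' @param path Output path.
#' @param contigs Optional named integer vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_indel_vcf <- function(x, path, contigs = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=indelscope")
  if (!is.null(contigs)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contigs), as.integer(contigs)))
  }
  hdr <- c(hdr, "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  x <- dplyr::arrange(x, chrom, pos)
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
                  x$chrom, x$pos, x$ref_allele, x$alt_allele)
  writeLines(c(hdr, body), path)
  invisible(path)
}
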