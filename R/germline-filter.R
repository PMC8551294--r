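#' Pairwise indel identity tests
#'
#' `match_exact()` implements the stringent identity rule used for germline
#' filtering: two indels are the same only if chromosome, anchored position,
#' indel type and event sequence all agree. `match_fuzzy()` implements the
#' relaxed cross-cohort rule: same chromosome, same type, and positions
#' within `i +/- window`. Both are vectorized over row-aligned tibbles and
#' recycle length-1 inputs.
#'
#' @param a,b Normalized indel tibbles of equal (or recyclable) length.
#' @param window Non-negative position window for fuzzy matching.
#' @return Logical vector.
#' @examples
#' a <- normalize_indels(tibble::tibble(chrom = "chr1", pos = 100,
#'                                      ref = "CA", alt = "C"))
#' match_exact(a, a) # TRUE
#' @export
match_exact <- function(a, b) {
  out <- a$chrom == b$chrom & a$pos == b$pos & a$itype == b$itype &
    a$seq == b$seq
  out & !is.na(out)
}

#' @rdname match_exact
#' @export
match_fuzzy <- function(a, b, window = 5L) {
  stopifnot(window >= 0L)
  a$chrom == b$chrom & a$itype == b$itype & abs(a$pos - b$pos) <= window
}

#' Remove germline indels from a predicted somatic call set
#'
#' Partitions the somatic set into indels with at least one exact germline
#' match (`removed`) and the rest (`retained`). A somatic indel matching
#' several germline records (possible after multi-allelic splitting) is
#' removed once. The germline overlap fraction is reported as a percentage
#' of the somatic input.
#'
#' @param somatic,germline Normalized indel tibbles.
#' @param dedup Collapse the somatic set to distinct (chrom, pos, type,
#'   sequence) events before filtering. Default `FALSE`: totals count indel
#'   events, so cross-sample recurrent indels contribute once each.
#' @return An object of class `germline_filter`: a list with `retained`,
#'   `removed`, `n_input`, `n_removed` and `overlap_pct` (`NA` for an empty
#'   somatic set). `glance()` returns the counts as a one-row tibble.
#' @export
filter_germline <- function(somatic, germline, dedup = FALSE) {
  if (dedup) {
    somatic <- somatic[!duplicated(indel_key(somatic)), , drop = FALSE]
  }
  hit <- indel_key(somatic) %in% indel_key(germline)
  out <- list(
    retained = somatic[!hit, , drop = FALSE],
    removed = somatic[hit, , drop = FALSE],
    n_input = nrow(somatic),
    n_removed = sum(hit),
    overlap_pct = if (nrow(somatic) == 0L) NA_real_
                  else pct(sum(hit), nrow(somatic))
  )
  class(out) <- "germline_filter"
  out
}

#' @export
print.germline_filter <- function(x, ...) {
  cat("<germline_filter> ", x$n_removed, "/", x$n_input,
      " somatic indels matched the germline panel (",
      ifelse(is.na(x$overlap_pct), "NA", format(x$overlap_pct)), "%)\n",
      sep = "")
  invisible(x)
}

# For sorted positions `sorted_pos`, does any lie within `pos +/- window`?
fuzzy_any <- function(pos, sorted_pos, window) {
  if (length(sorted_pos) == 0L) return(rep(FALSE, length(pos)))
  i <- findInterval(pos + window, sorted_pos)
  i > 0L & sorted_pos[pmax(i, 1L)] >= pos - window
}

#' Cross-cohort indel sharing under the position-window rule
#'
#' An indel of cohort A is shared if any indel of cohort B has the same
#' chromosome and type and a position within `window`; the summary is
#' symmetric and reports the shared subset of each cohort.
#'
#' @param a,b Normalized indel tibbles.
#' @param window Position window (default 5).
#' @param dedup Deduplicate each cohort by exact identity first (default
#'   `TRUE`).
#' @return An object of class `cohort_overlap`: list with `shared_a`,
#'   `shared_b`, and counts `n_a`, `n_b`, `n_shared_a`, `n_shared_b`.
#' @export
cohort_overlap <- function(a, b, window = 5L, dedup = TRUE) {
  stopifnot(window >= 0L)
  if (dedup) {
    a <- a[!duplicated(indel_key(a)), , drop = FALSE]
    b <- b[!duplicated(indel_key(b)), , drop = FALSE]
  }
  grp <- function(x) paste(x$chrom, x$itype, sep = "\r")
  b_split <- split(b$pos, grp(b))
  b_split <- lapply(b_split, sort)
  a_split <- split(a$pos, grp(a))
  a_split <- lapply(a_split, sort)
  hit_in <- function(x, lookup) {
    g <- grp(x)
    out <- logical(nrow(x))
    for (k in unique(g)) {
      idx <- g == k
      out[idx] <- fuzzy_any(x$pos[idx], lookup[[k]], window)
    }
    out
  }
  in_a <- hit_in(a, b_split)
  in_b <- hit_in(b, a_split)
  out <- list(
    shared_a = a[in_a, , drop = FALSE],
    shared_b = b[in_b, , drop = FALSE],
    n_a = nrow(a), n_b = nrow(b),
    n_shared_a = sum(in_a), n_shared_b = sum(in_b)
  )
  class(out) <- "cohort_overlap"
  out
}

#' @export
print.cohort_overlap <- function(x, ...) {
  cat("<cohort_overlap> shared: ", x$n_shared_a, "/", x$n_a, " of A, ",
      x$n_shared_b, "/", x$n_b, " of B\n", sep = "")
  invisible(x)
}
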