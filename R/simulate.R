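#' Configuration for the synthetic-cohort simulator
#'
#' Builds the fully-parameterised configuration consumed by
#' [simulate_bundle()]. The generator first samples a region class for each
#' indel, then a position uniformly within that class — the inverse of the
#' pipeline's direction, so that parameter recovery through the pipeline is
#' a genuine test. All probabilities are in `[0, 1]`; `seed` fully
#' determines the output.
#'
#' @param seed Integer seed; the single pseudo-random stream for the bundle.
#' @param n_genes Number of simulated genes.
#' @param chroms Chromosome names; genes are distributed round-robin.
#' @param exons_per_gene,exon_length,intron_length,utr5_length,utr3_length,
#'   intergenic_gap Integer ranges (min, max) for the gene-model geometry,
#'   in bases.
#' @param p_minus Probability a gene is on the minus strand.
#' @param p_alt_transcript Probability a gene carries an additional shorter
#'   (non-coding) transcript, exercising representative-transcript
#'   selection.
#' @param n_germline Size of the germline panel.
#' @param n_somatic Named integer vector: somatic indels per tumour cohort.
#' @param germline_contamination Probability a "somatic" call is a copy of a
#'   germline panel record (germline leakage).
#' @param p_deletion Probability an indel is a deletion (vs insertion).
#' @param p_intergenic Probability an indel falls outside every transcript.
#' @param region_probs Named probabilities (`cds`, `utr5`, `utr3`, `other`)
#'   of the region class, conditional on the indel being on a transcript.
#' @param p_fs_given_cds Probability a CDS indel is frameshift (length not a
#'   multiple of 3).
#' @param indel_len_geom_p Geometric parameter of the indel length
#'   distribution (`length = 1 + Geom(p)` capped at `max_indel_len`).
#' @param max_indel_len Maximum event length in bases.
#' @param p_tfbs_cds,p_tfbs_noncds Probability that a CDS / non-CDS indel
#'   overlaps a TFBS (realised by conditioning the position draw).
#' @param tfbs_density Fraction of the genome covered by TFBS intervals.
#' @param tfbs_width TFBS width range in bases.
#' @param germline List overriding `p_deletion`, `p_intergenic`,
#'   `region_probs`, `p_fs_given_cds`, `p_tfbs_cds`, `p_tfbs_noncds` for the
#'   germline panel.
#' @param phylop List with `mean_cds`, `mean_noncds`, `sd`: per-base
#'   conservation scores are Normal with the CDS mean at CDS positions.
#' @param ss8_freqs Named frequencies of the 8 DSSP states used to draw
#'   per-residue secondary structure.
#' @param ss_helix_bias Optional probability that an NFS coding deletion is
#'   placed on a helix residue (codon-exact placement); `NULL` disables the
#'   bias.
#' @param n_smg Number of genes written to the simulated
#'   significantly-mutated-gene list.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 40L,
                       chroms = c("chr1", "chr2"),
                       exons_per_gene = c(2L, 5L),
                       exon_length = c(150L, 300L),
                       intron_length = c(100L, 400L),
                       utr5_length = c(20L, 60L),
                       utr3_length = c(40L, 120L),
                       intergenic_gap = c(300L, 800L),
                       p_minus = 0.5,
                       p_alt_transcript = 0.25,
                       n_germline = 2000L,
                       n_somatic = c(cohortA = 5000L, cohortB = 5000L),
                       germline_contamination = 0.15,
                       p_deletion = 0.6,
                       p_intergenic = 0.25,
                       region_probs = c(cds = 0.12, utr5 = 0.02,
                                        utr3 = 0.06, other = 0.80),
                       p_fs_given_cds = 0.75,
                       indel_len_geom_p = 0.5,
                       max_indel_len = 10L,
                       p_tfbs_cds = 0.40,
                       p_tfbs_noncds = 0.25,
                       tfbs_density = 0.25,
                       tfbs_width = c(10L, 25L),
                       germline = list(p_deletion = 0.57,
                                       p_intergenic = 0.45,
                                       region_probs = c(cds = 0.01,
                                                        utr5 = 0.01,
                                                        utr3 = 0.03,
                                                        other = 0.95),
                                       p_fs_given_cds = 0.5,
                                       p_tfbs_cds = 0.38,
                                       p_tfbs_noncds = 0.17),
                       phylop = list(mean_cds = 4, mean_noncds = 0, sd = 1),
                       ss8_freqs = c(H = 0.30, G = 0.04, I = 0.01,
                                     E = 0.18, B = 0.02, T = 0.12,
                                     S = 0.10, C = 0.23),
                       ss_helix_bias = NULL,
                       n_smg = 10L) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              chroms = chroms, exons_per_gene = exons_per_gene,
              exon_length = exon_length, intron_length = intron_length,
              utr5_length = utr5_length, utr3_length = utr3_length,
              intergenic_gap = intergenic_gap, p_minus = p_minus,
              p_alt_transcript = p_alt_transcript,
              n_germline = as.integer(n_germline),
              n_somatic = n_somatic,
              germline_contamination = germline_contamination,
              p_deletion = p_deletion, p_intergenic = p_intergenic,
              region_probs = region_probs,
              p_fs_given_cds = p_fs_given_cds,
              indel_len_geom_p = indel_len_geom_p,
              max_indel_len = as.integer(max_indel_len),
              p_tfbs_cds = p_tfbs_cds, p_tfbs_noncds = p_tfbs_noncds,
              tfbs_density = tfbs_density, tfbs_width = tfbs_width,
              germline = germline, phylop = phylop,
              ss8_freqs = ss8_freqs, ss_helix_bias = ss_helix_bias,
              n_smg = as.integer(n_smg))
  probs <- c(cfg$p_minus, cfg$p_alt_transcript, cfg$germline_contamination,
             cfg$p_deletion, cfg$p_intergenic, cfg$region_probs,
             cfg$p_fs_given_cds, cfg$indel_len_geom_p, cfg$p_tfbs_cds,
             cfg$p_tfbs_noncds, cfg$tfbs_density)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(cfg$region_probs) - 1) > 1e-6) {
    stop("region_probs must sum to 1", call. = FALSE)
  }
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1", call. = FALSE)
  class(cfg) <- "sim_config"
  cfg
}

#' Preset configuration emulating the published cohort composition
#'
#' A named preset whose generative parameters equal the BRCA-row
#' percentages of the published summary tables: 16.74% germline leakage,
#' 58.67% deletions, 8.64% CDS / 0.66% 5'UTR / 3.45% 3'UTR share of
#' transcript indels, 74.19% FS among CDS indels, and TFBS-overlap
#' probabilities of 44.49% (CDS) and 25.40% (non-CDS). The germline panel
#' uses the corresponding germline-row values. Intended for end-to-end
#' demonstration and parameter-recovery checks.
#'
#' @param n_somatic Named somatic cohort sizes.
#' @param n_germline Germline panel size.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
paper_like_config <- function(n_somatic = c(cohortA = 20000L,
                                            cohortB = 20000L),
                              n_germline = 5000L, seed = 1L, ...) {
  sim_config(
    seed = seed, n_somatic = n_somatic, n_germline = n_germline,
    germline_contamination = 0.1674,
    p_deletion = 0.5867,
    p_intergenic = 0.3272,
    region_probs = c(cds = 0.0864, utr5 = 0.0066, utr3 = 0.0345,
                     other = 0.8725),
    p_fs_given_cds = 0.7419,
    p_tfbs_cds = 0.4449, p_tfbs_noncds = 0.2540,
    germline = list(p_deletion = 0.5704, p_intergenic = 0.6062,
                    region_probs = c(cds = 0.0028, utr5 = 0.0018,
                                     utr3 = 0.0255, other = 0.9699),
                    p_fs_given_cds = 0.4956,
                    p_tfbs_cds = 0.3796, p_tfbs_noncds = 0.1741),
    ...
  )
}

# ---- internal generator machinery -----------------------------------------

# compress sorted 1-based genomic positions into 0-based half-open intervals
compress_intervals <- function(pos) {
  if (length(pos) == 0L) return(tibble(start = integer(), end = integer()))
  pos <- sort(pos)
  brk <- c(TRUE, diff(pos) != 1L)
  grp <- cumsum(brk)
  tibble(start = pos[brk] - 1L,
         end = as.integer(tapply(pos, grp, max)))
}

sim_genes <- function(cfg) {
  cursor <- setNames(rep(0L, length(cfg$chroms)), cfg$chroms)
  rows <- vector("list", cfg$n_genes)
  for (g in seq_len(cfg$n_genes)) {
    chr <- cfg$chroms[((g - 1L) %% length(cfg$chroms)) + 1L]
    gap <- sample(cfg$intergenic_gap[1]:cfg$intergenic_gap[2], 1L)
    n_ex <- sample(cfg$exons_per_gene[1]:cfg$exons_per_gene[2], 1L)
    widths <- sample(cfg$exon_length[1]:cfg$exon_length[2], n_ex,
                     replace = TRUE)
    introns <- if (n_ex > 1L)
      sample(cfg$intron_length[1]:cfg$intron_length[2], n_ex - 1L,
             replace = TRUE) else integer()
    starts <- integer(n_ex)
    starts[1] <- cursor[[chr]] + gap
    if (n_ex > 1L) {
      for (j in 2:n_ex) starts[j] <- starts[j - 1L] + widths[j - 1L] + introns[j - 1L]
    }
    ends <- starts + widths
    exons <- tibble(start = starts, end = ends)
    L <- sum(widths)
    u5 <- sample(cfg$utr5_length[1]:cfg$utr5_length[2], 1L)
    u3 <- sample(cfg$utr3_length[1]:cfg$utr3_length[2], 1L)
    cds_len <- L - u5 - u3
    rem <- cds_len %% 3L
    u3 <- u3 + rem
    cds_len <- cds_len - rem
    strand <- if (stats::runif(1) < cfg$p_minus) "-" else "+"
    # exonic positions (1-based genomic) in transcription order
    gpos <- unlist(purrr::map2(starts + 1L, ends, seq.int))
    if (strand == "-") gpos <- rev(gpos)
    utr5_iv <- compress_intervals(gpos[seq_len(u5)])
    cds_gpos <- gpos[u5 + seq_len(cds_len)]
    cds_iv <- compress_intervals(cds_gpos)
    utr3_iv <- compress_intervals(gpos[u5 + cds_len + seq_len(u3)])
    tid <- sprintf("T%04dA", g)
    gid <- sprintf("G%04d", g)
    sym <- sprintf("GENE%04d", g)
    main <- tibble(
      transcript_id = tid, gene_id = gid, gene_symbol = sym,
      chrom = chr, strand = strand,
      tx_start = min(starts), tx_end = max(ends),
      exonic_length = L, cds_length = cds_len,
      coding = TRUE, valid = TRUE,
      exons = list(exons), cds = list(cds_iv),
      utr5 = list(utr5_iv), utr3 = list(utr3_iv),
      cds_gpos = list(cds_gpos)
    )
    if (stats::runif(1) < cfg$p_alt_transcript && n_ex > 1L) {
      alt_exons <- exons[-n_ex, , drop = FALSE]
      alt <- tibble(
        transcript_id = sprintf("T%04dB", g), gene_id = gid,
        gene_symbol = sym, chrom = chr, strand = strand,
        tx_start = min(alt_exons$start), tx_end = max(alt_exons$end),
        exonic_length = sum(alt_exons$end - alt_exons$start),
        cds_length = 0L, coding = FALSE, valid = TRUE,
        exons = list(alt_exons),
        cds = list(tibble(start = integer(), end = integer())),
        utr5 = list(tibble(start = integer(), end = integer())),
        utr3 = list(tibble(start = integer(), end = integer())),
        cds_gpos = list(integer())
      )
      main <- dplyr::bind_rows(main, alt)
    }
    rows[[g]] <- main
    cursor[[chr]] <- max(ends)
  }
  transcripts <- dplyr::bind_rows(rows)
  chrom_lengths <- cursor + 500L
  list(transcripts = transcripts, chrom_lengths = chrom_lengths)
}

sim_tfbs <- function(cfg, chrom_lengths) {
  w_mean <- mean(cfg$tfbs_width)
  gap_mean <- max(w_mean * (1 - cfg$tfbs_density) / max(cfg$tfbs_density, 1e-9),
                  2)
  pieces <- purrr::imap(as.list(chrom_lengths), function(len, chr) {
    n_est <- ceiling(len / (w_mean + gap_mean)) * 2L + 10L
    gaps <- stats::runif(n_est, 0.5 * gap_mean, 1.5 * gap_mean)
    widths <- sample(cfg$tfbs_width[1]:cfg$tfbs_width[2], n_est,
                     replace = TRUE)
    ends <- cumsum(gaps + widths)
    starts <- ends - widths
    keep <- ends <= len
    tibble(chrom = chr, start = as.integer(floor(starts[keep])),
           end = as.integer(floor(ends[keep])))
  })
  dplyr::bind_rows(pieces) |>
    dplyr::arrange(chrom, start) |>
    dplyr::filter(end > start)
}

# class interval tables used for placement
sim_class_intervals <- function(transcripts, chrom_lengths) {
  rep_tx <- transcripts[transcripts$coding, , drop = FALSE]
  take <- function(col) {
    purrr::map_dfr(seq_len(nrow(rep_tx)), function(i) {
      iv <- rep_tx[[col]][[i]]
      if (nrow(iv) == 0L) return(NULL)
      dplyr::mutate(iv, chrom = rep_tx$chrom[i],
                    transcript_id = rep_tx$transcript_id[i])
    })
  }
  introns <- purrr::map_dfr(seq_len(nrow(rep_tx)), function(i) {
    ex <- rep_tx$exons[[i]]
    if (nrow(ex) < 2L) return(NULL)
    ex <- dplyr::arrange(ex, start)
    tibble(start = ex$end[-nrow(ex)], end = ex$start[-1],
           chrom = rep_tx$chrom[i],
           transcript_id = rep_tx$transcript_id[i])
  })
  spans <- rep_tx[, c("chrom", "tx_start", "tx_end")]
  intergenic <- purrr::imap_dfr(as.list(chrom_lengths), function(len, chr) {
    sp <- spans[spans$chrom == chr, , drop = FALSE] |>
      dplyr::arrange(tx_start)
    bounds <- c(0L, rbind(sp$tx_start, sp$tx_end), len)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    tibble(chrom = chr, start = as.integer(starts), end = as.integer(ends),
           transcript_id = NA_character_) |>
      dplyr::filter(end - start > 30L)
  })
  list(cds = take("cds"), utr5 = take("utr5"), utr3 = take("utr3"),
       other = introns, intergenic = intergenic)
}

# overlap predicate used for ground-truth TFBS labels
sim_tfbs_hit <- function(chrom, pos, itype, len, tfbs) {
  start <- ifelse(itype == "deletion", pos, pmax(pos - 1L, 0L))
  end <- ifelse(itype == "deletion", pos + len, pos + 1L)
  fp <- tibble(chrom = chrom, start = start, end = end)
  if (nrow(tfbs) == 0L || nrow(fp) == 0L) return(rep(FALSE, nrow(fp)))
  hits <- interval_hits(fp, tfbs)
  out <- rep(FALSE, nrow(fp))
  out[unique(hits$q)] <- TRUE
  out
}

# draw anchored positions within class intervals, conditioning on the
# desired TFBS-overlap label by rejection (40 rounds, then accept realised)
sim_place <- function(rows, ivl, tfbs, max_rounds = 40L) {
  n <- nrow(rows)
  out <- tibble(pos = rep(NA_integer_, n), chrom = rep(NA_character_, n),
                transcript_id = rep(NA_character_, n))
  if (n == 0L) return(out)
  if (nrow(ivl) == 0L) stop("no intervals available for a region class",
                            call. = FALSE)
  fp_len <- ifelse(rows$itype == "deletion", rows$len, 2L)
  unresolved <- rep(TRUE, n)
  for (round in seq_len(max_rounds)) {
    idx <- which(unresolved)
    if (length(idx) == 0L) break
    for (fl in unique(fp_len[idx])) {
      sub <- idx[fp_len[idx] == fl]
      wts <- pmax(ivl$end - ivl$start - fl + 1L, 0L)
      if (sum(wts) == 0L) stop("region intervals too small for indel length ",
                               fl, call. = FALSE)
      j <- sample.int(nrow(ivl), length(sub), replace = TRUE, prob = wts)
      off <- floor(stats::runif(length(sub)) *
                     (ivl$end[j] - ivl$start[j] - fl + 1L))
      s <- ivl$start[j] + as.integer(off)   # 0-based footprint start
      out$pos[sub] <- ifelse(rows$itype[sub] == "deletion", s, s + 1L)
      out$chrom[sub] <- ivl$chrom[j]
      out$transcript_id[sub] <- ivl$transcript_id[j]
    }
    realized <- sim_tfbs_hit(out$chrom[idx], out$pos[idx],
                             rows$itype[idx], rows$len[idx], tfbs)
    unresolved[idx] <- realized != rows$want_tfbs[idx]
  }
  out
}

rand_bases <- function(lens) {
  total <- sum(lens)
  if (total == 0L) return(character(0))
  b <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
  grp <- rep.int(seq_along(lens), lens)
  vapply(split(b, grp), paste, character(1), collapse = "")
}

# truncated-geometric indel lengths with optional frame constraint
sim_lengths <- function(n, frame = c("any", "fs", "nfs"), p, max_len) {
  frame <- match.arg(frame)
  lens <- 1:max_len
  w <- stats::dgeom(lens - 1L, p)
  if (frame == "fs") {
    lens <- lens[lens %% 3L != 0L]; w <- stats::dgeom(lens - 1L, p)
  } else if (frame == "nfs") {
    lens <- lens[lens %% 3L == 0L]; w <- stats::dgeom(lens / 3L - 1L, p)
  }
  if (n == 0L) return(integer(0))
  sample(lens, n, replace = TRUE, prob = w)
}

# one fully-labelled indel set (used for the germline panel and for the
# freshly somatic part of each tumour cohort)
sim_indel_set <- function(n, pars, cfg, classes, tfbs, genes = NULL,
                          profiles = NULL) {
  region_names <- c(cds = "CDS", utr5 = "UTR5", utr3 = "UTR3",
                    other = "other_transcript", intergenic = "intergenic")
  empty <- tibble(chrom = character(), pos = integer(), itype = character(),
                  seq = character(), len = integer(), region = character(),
                  frame = character(), tfbs_overlap = logical(),
                  is_germline_copy = logical())
  if (n == 0L) return(empty)
  cls <- ifelse(stats::runif(n) < pars$p_intergenic, "intergenic",
                sample(names(pars$region_probs), n, replace = TRUE,
                       prob = pars$region_probs))
  itype <- ifelse(stats::runif(n) < pars$p_deletion, "deletion", "insertion")
  is_cds <- cls == "cds"
  fs <- is_cds & stats::runif(n) < pars$p_fs_given_cds
  len <- integer(n)
  len[is_cds & fs] <- sim_lengths(sum(is_cds & fs), "fs",
                                  cfg$indel_len_geom_p, cfg$max_indel_len)
  len[is_cds & !fs] <- sim_lengths(sum(is_cds & !fs), "nfs",
                                   cfg$indel_len_geom_p, cfg$max_indel_len)
  len[!is_cds] <- sim_lengths(sum(!is_cds), "any",
                              cfg$indel_len_geom_p, cfg$max_indel_len)
  want <- stats::runif(n) < ifelse(is_cds, pars$p_tfbs_cds, pars$p_tfbs_noncds)

  out <- tibble(chrom = NA_character_, pos = NA_integer_, itype = itype,
                seq = rand_bases(len), len = len,
                region = unname(region_names[cls]),
                frame = NA_character_, tfbs_overlap = NA,
                is_germline_copy = FALSE, .rows = n)

  # codon-exact helix-biased placement for NFS coding deletions, if enabled
  biased <- rep(FALSE, n)
  if (!is.null(cfg$ss_helix_bias) && !is.null(genes) && !is.null(profiles)) {
    biased <- is_cds & !fs & itype == "deletion"
    if (any(biased)) {
      pl <- sim_place_codon(sum(biased), cfg$ss_helix_bias, genes, profiles)
      out$chrom[biased] <- pl$chrom
      out$pos[biased] <- pl$pos
      out$len[biased] <- 3L
      out$seq[biased] <- rand_bases(rep(3L, sum(biased)))
    }
  }
  for (k in names(classes)) {
    sel <- cls == k & !biased
    if (!any(sel)) next
    pl <- sim_place(tibble(itype = itype[sel], len = len[sel],
                           want_tfbs = want[sel]),
                    classes[[k]], tfbs)
    out$chrom[sel] <- pl$chrom
    out$pos[sel] <- pl$pos
  }
  out$tfbs_overlap <- sim_tfbs_hit(out$chrom, out$pos, out$itype, out$len,
                                   tfbs)
  out$frame <- ifelse(out$region != "CDS", "not_coding",
                      ifelse(out$len %% 3L == 0L, "NFS", "FS"))
  out
}

# pick a residue (helix with probability `bias`) whose codon occupies three
# consecutive genomic bases, and delete exactly that codon
sim_place_codon <- function(n, bias, genes, profiles) {
  coding <- genes[genes$coding, , drop = FALSE]
  prof <- setNames(profiles$ss3, profiles$protein_id)
  out <- tibble(chrom = rep(NA_character_, n), pos = rep(NA_integer_, n))
  if (n == 0L) return(out)
  tx_idx <- sample.int(nrow(coding), n, replace = TRUE)
  for (i in seq_len(n)) {
    tx <- coding[tx_idx[i], ]
    gpos <- tx$cds_gpos[[1]]
    n_res <- length(gpos) %/% 3L
    first <- gpos[3L * seq_len(n_res) - 2L]
    last <- gpos[3L * seq_len(n_res)]
    contig <- abs(last - first) == 2L
    ss <- strsplit(prof[[tx$transcript_id]], "")[[1]][seq_len(n_res)]
    helix <- which(contig & ss == "H")
    other <- which(contig & ss != "H")
    pick_helix <- stats::runif(1) < bias
    pool <- if (pick_helix && length(helix)) helix
            else if (!pick_helix && length(other)) other
            else which(contig)
    r <- pool[sample.int(length(pool), 1L)]
    lo <- min(first[r], last[r])
    out$chrom[i] <- tx$chrom
    out$pos[i] <- lo - 1L
  }
  out
}

sim_ss_profiles <- function(transcripts, cfg) {
  coding <- transcripts[transcripts$coding, , drop = FALSE]
  n_res <- coding$cds_length %/% 3L
  ss8 <- vapply(n_res, function(k) {
    paste(sample(names(cfg$ss8_freqs), k, replace = TRUE,
                 prob = cfg$ss8_freqs), collapse = "")
  }, character(1))
  tibble(protein_id = coding$transcript_id, ss8 = ss8,
         ss3 = collapse_ss8_to_ss3(ss8), length = n_res)
}

sim_phylop <- function(cfg, chrom_lengths, cds_pos_by_chrom) {
  purrr::imap_dfr(as.list(chrom_lengths), function(len, chr) {
    score <- stats::rnorm(len, cfg$phylop$mean_noncds, cfg$phylop$sd)
    cp <- cds_pos_by_chrom[[chr]]
    if (!is.null(cp) && length(cp) > 0L) {
      score[cp] <- stats::rnorm(length(cp), cfg$phylop$mean_cds,
                                cfg$phylop$sd)
    }
    tibble(chrom = chr, pos = seq_len(len), score = round(score, 3))
  })
}

write_sim_gff3 <- function(transcripts, chrom_lengths, path) {
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", names(chrom_lengths),
                     as.integer(chrom_lengths)))
  genes <- transcripts |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(chrom = chrom[1], start = min(tx_start),
                     end = max(tx_end), strand = strand[1],
                     gene_symbol = gene_symbol[1], .groups = "drop")
  fmt <- function(chrom, type, start0, end0, strand, attrs, phase = ".") {
    sprintf("%s\tindelscope_sim\t%s\t%d\t%d\t.\t%s\t%s\t%s",
            chrom, type, start0 + 1L, end0, strand, phase, attrs)
  }
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, fmt(g$chrom, "gene", g$start, g$end, g$strand,
                          sprintf("ID=%s;Name=%s", g$gene_id, g$gene_symbol)))
    txs <- transcripts[transcripts$gene_id == g$gene_id, , drop = FALSE]
    for (j in seq_len(nrow(txs))) {
      tx <- txs[j, ]
      lines <- c(lines, fmt(tx$chrom, "mRNA", tx$tx_start, tx$tx_end,
                            tx$strand,
                            sprintf("ID=%s;Parent=%s;Name=%s",
                                    tx$transcript_id, tx$gene_id,
                                    tx$gene_symbol)))
      ex <- dplyr::arrange(tx$exons[[1]], start)
      for (k in seq_len(nrow(ex))) {
        lines <- c(lines, fmt(tx$chrom, "exon", ex$start[k], ex$end[k],
                              tx$strand,
                              sprintf("Parent=%s", tx$transcript_id)))
      }
      cd <- dplyr::arrange(tx$cds[[1]], start)
      if (nrow(cd) > 0L) {
        # phase in transcription order
        ord <- if (tx$strand == "-") rev(seq_len(nrow(cd))) else seq_len(nrow(cd))
        before <- cumsum(c(0L, (cd$end - cd$start)[ord]))[seq_len(nrow(cd))]
        phase <- (3L - before %% 3L) %% 3L
        for (k in seq_len(nrow(cd))) {
          kk <- which(ord == k)
          lines <- c(lines, fmt(tx$chrom, "CDS", cd$start[k], cd$end[k],
                                tx$strand,
                                sprintf("Parent=%s", tx$transcript_id),
                                phase = as.character(phase[kk])))
        }
      }
    }
  }
  writeLines(lines, path)
  invisible(path)
}

sim_write_vcf <- function(x, path, chrom_lengths) {
  if (nrow(x) == 0L) {
    v <- tibble(chrom = character(), pos = integer(),
                ref_allele = character(), alt_allele = character())
    return(write_indel_vcf(v, path, contigs = chrom_lengths))
  }
  anchor <- sample(c("A", "C", "G", "T"), nrow(x), replace = TRUE)
  v <- tibble(
    chrom = x$chrom, pos = x$pos,
    ref_allele = ifelse(x$itype == "deletion", paste0(anchor, x$seq), anchor),
    alt_allele = ifelse(x$itype == "deletion", anchor, paste0(anchor, x$seq))
  )
  write_indel_vcf(v, path, contigs = chrom_lengths)
}

#' Generate a complete synthetic input bundle
#'
#' Writes the full pipeline input set for one simulated study —
#' `genes.gff3`, `germline.vcf`, one VCF per tumour cohort, `tfbs.bed`,
#' `phylop.bedgraph`, `ss_profiles.tsv`, `smg_genes.txt` — together with
#' `truth.json`, which records every generative parameter and the
#' per-indel ground-truth labels (`is_germline_copy`, `region`, `frame`,
#' `tfbs_overlap`). Output is deterministic given `config$seed`: the same
#' configuration produces byte-identical files.
#'
#' Truth rows are ordered exactly like the VCF body lines of each cohort,
#' so `truth$cohorts[[k]][i, ]` describes the i-th record of the k-th
#' cohort VCF.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with `dir`, named `paths`, the simulated
#'   `transcripts`, `tfbs`, `chrom_lengths`, and `truth` (the list written
#'   to `truth.json`, with cohort tibbles).
#' @export
simulate_bundle <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- config
  withr::with_seed(cfg$seed, {
    gen <- sim_genes(cfg)
    transcripts <- gen$transcripts
    chrom_lengths <- gen$chrom_lengths
    if (cfg$region_probs[["cds"]] > 0 &&
        sum(transcripts$cds_length) == 0L) {
      stop("config requests CDS indels but the gene models have no CDS",
           call. = FALSE)
    }
    profiles <- sim_ss_profiles(transcripts, cfg)
    tfbs <- sim_tfbs(cfg, chrom_lengths)
    classes <- sim_class_intervals(transcripts, chrom_lengths)

    pars_somatic <- cfg[c("p_deletion", "p_intergenic", "region_probs",
                          "p_fs_given_cds", "p_tfbs_cds", "p_tfbs_noncds")]
    pars_germ <- utils::modifyList(pars_somatic, cfg$germline)

    germline <- sim_indel_set(cfg$n_germline, pars_germ, cfg, classes, tfbs) |>
      dplyr::arrange(chrom, pos)

    cohorts <- purrr::imap(as.list(cfg$n_somatic), function(n, nm) {
      n <- as.integer(n)
      n_copy <- stats::rbinom(1L, n, cfg$germline_contamination)
      if (n_copy > 0L && nrow(germline) == 0L) {
        stop("germline contamination requires a non-empty germline panel",
             call. = FALSE)
      }
      copies <- if (n_copy > 0L) {
        germline[sample.int(nrow(germline), n_copy, replace = TRUE), ] |>
          dplyr::mutate(is_germline_copy = TRUE)
      } else germline[0, ]
      fresh <- sim_indel_set(n - n_copy, pars_somatic, cfg, classes, tfbs,
                             genes = transcripts, profiles = profiles)
      dplyr::bind_rows(copies, fresh) |>
        dplyr::arrange(chrom, pos)
    })

    cds_pos_by_chrom <- transcripts[transcripts$coding, ] |>
      (\(tx) split(unlist(tx$cds_gpos), rep(tx$chrom, lengths(tx$cds_gpos))))()
    phylop <- sim_phylop(cfg, chrom_lengths, cds_pos_by_chrom)

    smg_genes <- sort(sample(unique(transcripts$gene_symbol),
                             min(cfg$n_smg, cfg$n_genes)))

    paths <- c(
      gff = file.path(dir, "genes.gff3"),
      germline = file.path(dir, "germline.vcf"),
      setNames(file.path(dir, paste0(names(cfg$n_somatic), ".vcf")),
               names(cfg$n_somatic)),
      tfbs = file.path(dir, "tfbs.bed"),
      phylop = file.path(dir, "phylop.bedgraph"),
      ss = file.path(dir, "ss_profiles.tsv"),
      smg = file.path(dir, "smg_genes.txt"),
      truth = file.path(dir, "truth.json")
    )
    write_sim_gff3(transcripts, chrom_lengths, paths[["gff"]])
    sim_write_vcf(germline, paths[["germline"]], chrom_lengths)
    for (nm in names(cfg$n_somatic)) {
      sim_write_vcf(cohorts[[nm]], paths[[nm]], chrom_lengths)
    }
    readr::write_tsv(tfbs, paths[["tfbs"]], col_names = FALSE,
                     progress = FALSE)
    bg <- tibble(chrom = phylop$chrom, start = phylop$pos - 1L,
                 end = phylop$pos, score = sprintf("%.3f", phylop$score))
    readr::write_tsv(bg, paths[["phylop"]], col_names = FALSE,
                     progress = FALSE)
    readr::write_tsv(profiles[, c("protein_id", "ss8")], paths[["ss"]],
                     col_names = FALSE, progress = FALSE)
    writeLines(smg_genes, paths[["smg"]])

    truth <- list(
      params = unclass(cfg),
      chrom_lengths = as.list(chrom_lengths),
      smg_genes = smg_genes,
      germline = germline,
      cohorts = cohorts
    )
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA, null = "null")
    invisible(list(dir = dir, paths = paths, transcripts = transcripts,
                   tfbs = tfbs, chrom_lengths = chrom_lengths,
                   truth = truth))
  })
}
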