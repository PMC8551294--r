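test_that("representative transcript is the longest, ties and priority", {
  tx <- dplyr::bind_rows(
    make_transcript(tibble::tibble(start = 0L, end = 1200L), tid = "T2",
                    gid = "G1"),
    make_transcript(tibble::tibble(start = 0L, end = 900L), tid = "T3",
                    gid = "G1"),
    make_transcript(tibble::tibble(start = 2000L, end = 2300L), tid = "T5",
                    gid = "G2"),
    make_transcript(tibble::tibble(start = 2400L, end = 2700L), tid = "T4",
                    gid = "G2")
  )
  rep1 <- select_representative_transcripts(tx)
  expect_equal(rep1$transcript_id[rep1$gene_id == "G1"], "T2")  # longest
  expect_equal(rep1$transcript_id[rep1$gene_id == "G2"], "T4")  # tie: id
  rep2 <- select_representative_transcripts(tx, priority = c("T3", "T5"))
  expect_equal(sort(rep2$transcript_id), c("T3", "T5"))

  bad <- tx[1, ]; bad$valid <- FALSE
  expect_warning(select_representative_transcripts(bad), "no valid")
})

test_that("frame rule: NFS iff net length is a multiple of three", {
  tx <- make_transcript(tibble::tibble(start = 0L, end = 300L))
  x <- make_indels("chr1", 50L,
                   c("deletion", "insertion", "insertion", "deletion"),
                   c("ACT", "G", "ACTGCA", "AC")) |>
    classify_region(tx) |>
    classify_frame()
  expect_equal(x$region, rep("CDS", 4))
  expect_equal(x$frame, c("NFS", "FS", "NFS", "FS"))
  y <- make_indels("chr1", 500L, "deletion", "ACT") |>
    classify_region(tx) |>
    classify_frame()
  expect_equal(y$frame, "not_coding")
})

test_that("boundary-spanning footprints take the higher-precedence region", {
  # plus strand, exon [0,300), utr5 10, utr3 20 -> CDS [10,280)
  tx <- make_transcript(tibble::tibble(start = 0L, end = 300L), u5 = 10L,
                        u3 = 20L)
  # deletion of bases 279-282 (1-based) straddles the CDS/UTR3 boundary
  x <- make_indels("chr1", 278L, "deletion", "ACTG") |> classify_region(tx)
  expect_equal(x$region, "CDS")
  # wholly inside 3' UTR
  y <- make_indels("chr1", 285L, "deletion", "AC") |> classify_region(tx)
  expect_equal(y$region, "UTR3")
  # insertion with flanks spanning the UTR5/CDS boundary
  z <- make_indels("chr1", 10L, "insertion", "A") |> classify_region(tx)
  expect_equal(z$region, "CDS")
})

test_that("every insertion breakpoint of a minus-strand gene classifies as the oracle says", {
  # two exons, minus strand: utr5 sits at high coordinates
  tx <- make_transcript(tibble::tibble(start = c(100L, 250L),
                                       end = c(180L, 330L)),
                        strand = "-", u5 = 12L, u3 = 21L)
  pos <- 90:340
  ins <- make_indels("chr1", pos, "insertion", "A")
  got <- classify_region(ins, tx)
  want <- vapply(seq_len(nrow(ins)), function(i)
    oracle_region(ins[i, ], tx)$region, character(1))
  expect_equal(got$region, want)
  expect_true(all(c("UTR5", "UTR3", "CDS", "other_transcript", "intergenic")
                  %in% unique(want)))
})

test_that("random fixtures: region classification matches the per-base oracle", {
  withr::local_seed(21)
  n_checked <- 0L
  for (rep in 1:15) {
    tx <- dplyr::bind_rows(rand_transcript(1L), rand_transcript(2L))
    # separate the two genes so models never overlap
    shift <- tx$tx_end[1] + 50L
    tx$tx_start[2] <- tx$tx_start[2] + shift
    tx$tx_end[2] <- tx$tx_end[2] + shift
    for (col in c("exons", "cds", "utr5", "utr3")) {
      tx[[col]][[2]] <- tx[[col]][[2]] + shift
    }
    ind <- rand_indels(20, pos_range = c(1L, max(tx$tx_end) + 20L))
    got <- classify_region(ind, tx)
    want <- purrr::map(seq_len(nrow(ind)), function(i)
      oracle_region(ind[i, ], tx))
    expect_equal(got$region, purrr::map_chr(want, "region"))
    expect_equal(got$gene_symbol, purrr::map_chr(want, "gene_symbol"))
    n_checked <- n_checked + nrow(ind)
  }
  expect_gte(n_checked, 200L)
})

test_that("affected residues follow codon arithmetic on both strands", {
  # single exon, plus strand, no UTRs: CDS offset k is genomic position k
  tx <- make_transcript(tibble::tibble(start = 0L, end = 300L))
  # deletion of codon 10 exactly (CDS offsets 28-30)
  del1 <- make_indels("chr1", 27L, "deletion", "AAA") |>
    classify_region(tx) |> classify_frame()
  r1 <- affected_residues(del1, tx)
  expect_equal(c(r1$start_residue, r1$end_residue), c(10L, 10L))
  expect_equal(r1$kind, "deleted_residues")
  # 3-bp deletion straddling codons 10/11 (offsets 29-31)
  del2 <- make_indels("chr1", 28L, "deletion", "AAA") |>
    classify_region(tx) |> classify_frame()
  r2 <- affected_residues(del2, tx)
  expect_equal(c(r2$start_residue, r2$end_residue), c(10L, 11L))
  # insertion between offsets 30 and 31 flanks residues 10-11
  ins <- make_indels("chr1", 30L, "insertion", "AAA") |>
    classify_region(tx) |> classify_frame()
  r3 <- affected_residues(ins, tx)
  expect_equal(c(r3$start_residue, r3$end_residue), c(10L, 11L))
  expect_equal(r3$kind, "insertion_flanks")
})

test_that("random fixtures: residue attribution matches the brute-force oracle", {
  withr::local_seed(22)
  n_checked <- 0L
  while (n_checked < 200L) {
    tx <- rand_transcript(1L)
    ind <- rand_indels(30, pos_range = c(tx$tx_start, tx$tx_end)) |>
      classify_region(tx) |>
      classify_frame()
    nfs <- ind[ind$frame == "NFS", , drop = FALSE]
    if (nrow(nfs) == 0L) next
    got <- suppressWarnings(affected_residues(nfs, tx))
    for (i in seq_len(nrow(nfs))) {
      want <- oracle_residues(nfs[i, ], tx)
      g <- got[got$indel_id == nfs$indel_id[i], ]
      expect_equal(c(g$start_residue, g$end_residue), want)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 200L)
})

test_that("mirroring a gene model to the opposite strand preserves classifications", {
  withr::local_seed(23)
  G <- 1000L  # mirrored genome length
  for (rep in 1:10) {
    tx <- rand_transcript(1L)
    ind <- rand_indels(25, pos_range = c(max(1L, tx$tx_start - 5L),
                                         tx$tx_end + 5L))
    got <- classify_region(ind, tx) |> classify_frame()

    mirror_ivl <- function(iv) {
      tibble::tibble(start = G - iv$end, end = G - iv$start) |>
        dplyr::arrange(start)
    }
    tx_m <- tx
    tx_m$strand <- ifelse(tx$strand == "+", "-", "+")
    tx_m$tx_start <- G - tx$tx_end
    tx_m$tx_end <- G - tx$tx_start
    for (col in c("exons", "cds", "utr5", "utr3")) {
      tx_m[[col]][[1]] <- mirror_ivl(tx[[col]][[1]])
    }
    ind_m <- ind
    # deletion span [pos+1, pos+L] mirrors to [G-pos-L+1, G-pos];
    # insertion breakpoint (pos, pos+1) mirrors to (G-pos, G-pos+1)
    L <- nchar(ind$seq)
    ind_m$pos <- ifelse(ind$itype == "deletion", G - ind$pos - L, G - ind$pos)
    got_m <- classify_region(ind_m, tx_m) |> classify_frame()
    expect_equal(got_m$region, got$region)
    expect_equal(got_m$frame, got$frame)
  }
})
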