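test_that("percentages round half-up to two decimals", {
  expect_equal(pct(5320, 61543), 8.64)
  expect_equal(pct(3947, 5320), 74.19)
  expect_equal(pct(1, 800), 0.13)      # 0.125 rounds up
  expect_equal(pct(415, 1000), 41.5)
  expect_true(is.na(pct(1, 0)))
  expect_true(is.na(pct(0, NA)))
  expect_equal(pct(0, 10), 0)
})

test_that("cohort summary counts are internally consistent", {
  withr::local_seed(51)
  tx <- dplyr::bind_rows(
    make_transcript(tibble::tibble(start = 0L, end = 300L), u5 = 20L,
                    u3 = 40L, tid = "T1", gid = "G1", sym = "AAA"),
    make_transcript(tibble::tibble(start = 500L, end = 800L), u5 = 10L,
                    u3 = 50L, tid = "T2", gid = "G2", sym = "BBB")
  )
  ind <- rand_indels(300, pos_range = c(1L, 900L))
  tfbs <- tibble::tibble(chrom = "chr1", start = seq(0L, 880L, 40L),
                         end = seq(15L, 895L, 40L))
  ann <- ind |> annotate_indels(tx) |> annotate_tfbs_overlap(tfbs)
  s <- summarize_cohort(ann, cohort = "x", n_total = 350L,
                        n_germline_matched = 50L)
  expect_equal(s$deletions + s$insertions + s$complex_indels,
               s$transcript_indels)
  expect_equal(s$fs_indels + s$nfs_indels, s$cds_indels)
  expect_equal(s$germline_pct, pct(50, 350))
  expect_equal(s$cds_pct, pct(s$cds_indels, s$transcript_indels))
  expect_equal(s$fs_pct, pct(s$fs_indels, s$cds_indels))
  expect_equal(s$deletion_pct, pct(s$deletions, s$transcript_indels))
  expect_lte(s$cds_tfbs_overlap, s$cds_indels)
  expect_equal(s$tfbs_overlap, s$cds_tfbs_overlap + s$non_cds_tfbs_overlap)

  empty <- summarize_cohort(ann[0, ], cohort = "none")
  expect_equal(empty$transcript_indels, 0L)
  expect_true(is.na(empty$cds_pct))
})

test_that("chi-squared wrapper matches the hand-computed Pearson statistic", {
  withr::local_seed(52)
  for (rep in 1:10) {
    m <- matrix(sample(5:80, 4), 2)
    got <- chi2_test(m, correct = FALSE)
    # independent formula-level computation
    e <- outer(rowSums(m), colSums(m)) / sum(m)
    stat <- sum((m - e)^2 / e)
    expect_equal(got$statistic, stat)
    expect_equal(got$p_value, stats::pchisq(stat, 1, lower.tail = FALSE))
    # invariance to row/column permutation
    expect_equal(chi2_test(m[2:1, 2:1])$statistic, got$statistic)
  }
  flat <- matrix(c(10, 20, 30, 60), 2, byrow = TRUE)  # identical proportions
  expect_equal(chi2_test(flat)$statistic, 0, tolerance = 1e-12)
  expect_equal(chi2_test(flat)$p_value, 1)
  expect_error(chi2_test(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chi2_test(matrix(1:3, 1)), "at least 2 x 2")
  td <- tidy(chi2_test(matrix(c(5, 10, 20, 10), 2)))
  expect_equal(names(td),
               c("statistic", "df", "p_value", "method", "correct"))
})

test_that("gene ranking is descending with alphabetical tie-break", {
  ann <- tibble::tibble(
    gene_symbol = c("B", "A", "A", "C", "B", "B"),
    region = "CDS"
  )
  tg <- top_genes(ann)
  expect_equal(tg$gene_symbol, c("B", "A", "C"))
  expect_equal(tg$n, c(3L, 2L, 1L))
  tie <- top_genes(tibble::tibble(gene_symbol = c("B", "A", "A", "B"),
                                  region = "CDS"))
  expect_equal(tie$gene_symbol, c("A", "B"))
  # brute-force recount
  withr::local_seed(53)
  ann2 <- tibble::tibble(gene_symbol = sample(LETTERS[1:5], 100, TRUE),
                         region = sample(c("CDS", "UTR3"), 100, TRUE))
  tg2 <- top_genes(ann2, region = "CDS")
  want <- table(ann2$gene_symbol[ann2$region == "CDS"])
  expect_equal(sum(tg2$n), sum(want))
  for (g in tg2$gene_symbol) {
    expect_equal(tg2$n[tg2$gene_symbol == g], unname(want[g]),
                 ignore_attr = TRUE)
  }
})

test_that("SMG summary equals a hand count and its published percentages", {
  ann <- tibble::tibble(
    gene_symbol = c("S1", "S1", "S2", "X1", "S2", "S1", NA),
    region = c("CDS", "UTR3", "CDS", "CDS", "other_transcript",
               "CDS", "intergenic"),
    overlaps_tfbs = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, FALSE),
    cohort = "demo"
  )
  expect_warning(t6 <- smg_table(ann, c("S1", "S2", "S3")), "not seen")
  expect_equal(t6$smg_indels, 5L)
  expect_equal(t6$smg_cds_indels, 3L)
  expect_equal(t6$smgs_with_cds_indels, 2L)
  expect_equal(t6$smg_cds_tfbs_overlap, 1L)
  expect_equal(t6$smg_non_cds_indels, 2L)
  expect_equal(t6$smg_non_cds_tfbs_overlap, 2L)
  expect_equal(t6$smg_cds_pct, pct(3, 5))
  # disjoint list gives all zeros
  t0 <- suppressWarnings(smg_table(ann, c("Z9")))
  expect_equal(t0$smg_indels, 0L)
  # published SMG count pair
  expect_equal(pct(349, 1032), 33.82)
})

test_that("hypergeometric enrichment matches exhaustive enumeration", {
  background <- paste0("g", 1:30)
  hits <- paste0("g", 1:8)
  sets <- list(setA = paste0("g", 5:14), setB = paste0("g", 25:30),
               setC = paste0("x", 1:4))
  expect_message(res <- enrich_gene_sets(hits, background, sets),
                 "skipping 1")
  # exhaustive enumeration of the tail for setA
  N <- 30; K <- 8; m <- 10
  k <- length(intersect(hits, sets$setA))
  tail_p <- sum(vapply(k:min(m, K), function(j)
    choose(m, j) * choose(N - m, K - j), 0)) / choose(N, K)
  expect_equal(res$p_value[res$set == "setA"], tail_p)
  expect_equal(res$p_adjusted, pmin(1, res$p_value * 2))
  # monotone adjustment
  expect_equal(order(res$p_adjusted), order(res$p_value))

  # hits disjoint from a set: tail p = 1
  res2 <- enrich_gene_sets(paste0("g", 1:4), background,
                           list(s = paste0("g", 20:25)))
  expect_equal(res2$p_value, 1)
  expect_false(res2$significant)
  # single set: adjusted equals raw
  res3 <- enrich_gene_sets(hits, background, list(only = paste0("g", 1:8)))
  expect_equal(res3$p_adjusted, res3$p_value)
  expect_true(res3$significant)
  expect_error(enrich_gene_sets(c("zzz"), background, sets), "subset")
})
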