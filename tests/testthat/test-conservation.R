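test_that("position collection: deletion spans and insertion flanks", {
  x <- make_indels("chr1", c(100L, 100L, 100L),
                   c("deletion", "insertion", "deletion"),
                   c("ACT", "G", "A"))
  p <- collect_positions(x)
  expect_equal(p$pos[p$indel_id == 1], c(101L, 102L, 103L))
  expect_equal(p$pos[p$indel_id == 2], c(100L, 101L))
  expect_equal(p$pos[p$indel_id == 3], 101L)
  # |positions| == |seq| for deletions, 2 for insertions
  counts <- dplyr::count(p, indel_id)
  expect_equal(counts$n, c(3L, 2L, 1L))
  # an insertion anchored at position 1 keeps both flanks; at 0 it clips
  edge <- collect_positions(make_indels("chr1", 0L, "insertion", "C"))
  expect_equal(edge$pos, 1L)
})

test_that("scores are collected with explicit missing accounting", {
  track <- tibble::tibble(chrom = "chr1", pos = c(101L, 102L),
                          score = c(2, -1))
  del <- make_indels("chr1", 100L, "deletion", "AC")
  s <- score_indels(del, track)
  expect_equal(s$score, c(2, -1))
  ins_far <- make_indels("chr1", 500L, "insertion", "A")
  s2 <- score_indels(ins_far, track)
  expect_equal(attr(s2, "n_missing"), 2L)
  expect_true(all(is.na(s2$score)))
})

test_that("score lists are invariant to indel input order", {
  withr::local_seed(41)
  track <- tibble::tibble(chrom = "chr1", pos = 1:500,
                          score = rnorm(500))
  x <- rand_indels(40, pos_range = c(1L, 480L))
  x$indel_id <- seq_len(nrow(x))
  a <- score_indels(x, track)
  b <- score_indels(x[sample.int(nrow(x)), ], track)
  a_sorted <- dplyr::arrange(a, indel_id, pos)
  b_sorted <- dplyr::arrange(b, indel_id, pos)
  expect_equal(a_sorted$score, b_sorted$score)
})

test_that("conserved-gene ranking matches a brute-force recount", {
  withr::local_seed(42)
  for (rep in 1:10) {
    track <- tibble::tibble(chrom = "chr1", pos = 1:400,
                            score = rnorm(400, mean = 4, sd = 2))
    ind <- rand_indels(40, pos_range = c(1L, 380L))
    ind$indel_id <- seq_len(nrow(ind))
    ind$region <- "CDS"
    ind$gene_symbol <- sample(c("AAA", "BBB", "CCC"), nrow(ind),
                              replace = TRUE)
    ind$overlaps_tfbs <- sample(c(TRUE, FALSE), nrow(ind), replace = TRUE)
    got <- rank_conserved_genes(ind, track, cutoff = 5)

    # brute force: loop every indel, every position, count distinct
    seen <- list()
    for (i in seq_len(nrow(ind))) {
      row <- ind[i, ]
      for (b in oracle_bases(row)) {
        sc <- track$score[match(b, track$pos)]
        if (!is.na(sc) && sc > 5) {
          stratum <- if (row$overlaps_tfbs) "cds_tfbs_overlap"
                     else "cds_no_tfbs_overlap"
          seen[[length(seen) + 1L]] <- c(stratum, row$gene_symbol, b)
        }
      }
    }
    want <- unique(do.call(rbind, seen))
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      want_counts <- as.data.frame(table(stratum = want[, 1],
                                         gene_symbol = want[, 2])) |>
        dplyr::filter(Freq > 0) |>
        dplyr::arrange(stratum, gene_symbol)
      got_sorted <- dplyr::arrange(got, stratum, gene_symbol)
      expect_equal(got_sorted$n_positions, want_counts$Freq,
                   ignore_attr = TRUE)
      # ranking is descending with alphabetical ties
      for (st in unique(got$stratum)) {
        sub <- got[got$stratum == st, ]
        expect_true(all(diff(sub$n_positions) <= 0))
      }
      # per-stratum totals equal the cohort-wide distinct-position count
      tot <- got |> dplyr::count(stratum, wt = n_positions)
      want_tot <- as.data.frame(table(want[, 1])) |> dplyr::arrange(Var1)
      expect_equal(sort(tot$n), sort(want_tot$Freq), ignore_attr = TRUE)
    }
  }
})

test_that("cutoff above the track maximum yields an empty ranking", {
  track <- tibble::tibble(chrom = "chr1", pos = 1:100, score = runif(100, 0, 2))
  ind <- rand_indels(10, pos_range = c(1L, 90L))
  ind$region <- "CDS"; ind$gene_symbol <- "AAA"; ind$overlaps_tfbs <- FALSE
  expect_equal(nrow(rank_conserved_genes(ind, track, cutoff = 5)), 0L)
})

test_that("score distributions: degenerate case and stochastic dominance", {
  # all scores equal: single-bin histogram, ECDF step at that value
  track <- tibble::tibble(chrom = "chr1", pos = 1:200, score = 1.5)
  ind <- rand_indels(20, pos_range = c(1L, 180L))
  ind$region <- "CDS"
  d <- score_distribution(ind, track)
  expect_equal(nrow(d$hist |> dplyr::distinct(bin)), 1L)
  expect_equal(unique(d$ecdf$score), 1.5)
  expect_equal(max(d$ecdf$ecdf), 1)

  # CDS scores ~ N(4,1) dominate N(0,1) everywhere on a shared grid
  withr::local_seed(43)
  n <- 4000L
  track2 <- tibble::tibble(chrom = "chr1", pos = 1:20000,
                           score = c(rnorm(10000, 4), rnorm(10000, 0)))
  hi <- make_indels("chr1", sample(1:9900, n, replace = TRUE), "deletion", "A")
  lo <- make_indels("chr1", sample(10001:19900, n, replace = TRUE),
                    "deletion", "A")
  hi$region <- "CDS"; lo$region <- "CDS"
  hi$cohort <- "high"; lo$cohort <- "low"
  d2 <- score_distribution(dplyr::bind_rows(hi, lo), track2)
  grid <- seq(-2, 6, by = 0.5)
  ec <- function(coh) {
    sub <- d2$ecdf[d2$ecdf$cohort == coh, ]
    stats::approxfun(sub$score, sub$ecdf, yleft = 0, yright = 1,
                     method = "constant")(grid)
  }
  expect_true(all(ec("high") <= ec("low") + 1e-9))
})

test_that("same-distribution cohorts stay under the two-sample KS critical gap", {
  withr::local_seed(44)
  n <- 10000L
  track <- tibble::tibble(chrom = "chr1", pos = 1:50000,
                          score = rnorm(50000))
  a <- make_indels("chr1", sample(1:49000, n, replace = TRUE), "deletion", "A")
  b <- make_indels("chr1", sample(1:49000, n, replace = TRUE), "deletion", "A")
  a$region <- "CDS"; b$region <- "CDS"
  a$cohort <- "a"; b$cohort <- "b"
  d <- score_distribution(dplyr::bind_rows(a, b), track)
  grid <- seq(-4, 4, by = 0.05)
  ec <- function(coh) {
    sub <- d$ecdf[d$ecdf$cohort == coh, ]
    stats::approxfun(sub$score, sub$ecdf, yleft = 0, yright = 1,
                     method = "constant")(grid)
  }
  gap <- max(abs(ec("a") - ec("b")))
  crit <- 1.36 * sqrt(2 / n)  # alpha = 0.05 two-sample critical value
  expect_lt(gap, crit * 1.5)
})
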