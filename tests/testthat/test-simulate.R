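small_cfg <- function(seed = 101L,
                      n_somatic = c(cohortA = 400L, cohortB = 300L), ...) {
  sim_config(seed = seed, n_genes = 12L, n_germline = 300L,
             n_somatic = n_somatic, ...)
}

test_that("the same seed produces a byte-identical bundle", {
  cfg <- small_cfg()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_bundle(cfg, d1)
  simulate_bundle(cfg, d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # a different seed changes the output
  d3 <- withr::local_tempdir()
  simulate_bundle(small_cfg(seed = 102L), d3)
  expect_false(identical(readLines(file.path(d1, "cohortA.vcf")),
                         readLines(file.path(d3, "cohortA.vcf"))))
})

test_that("every generated file parses with zero skipped records", {
  d <- withr::local_tempdir()
  b <- simulate_bundle(small_cfg(seed = 103L), d)
  tx <- read_transcripts(b$paths[["gff"]])
  expect_equal(sum(!tx$valid), 0L)
  for (v in c("germline", "cohortA", "cohortB")) {
    x <- read_indel_vcf(b$paths[[v]])
    expect_equal(attr(x, "n_skipped_snv"), 0L)
    expect_equal(attr(x, "n_skipped_other"), 0L)
    expect_equal(sum(x$itype == "complex"), 0L)
  }
  expect_silent(tf <- read_tfbs_bed(b$paths[["tfbs"]]))
  expect_gt(nrow(tf), 0L)
  expect_gt(nrow(read_conservation(b$paths[["phylop"]])), 0L)
  expect_gt(nrow(read_ss_profiles(b$paths[["ss"]])), 0L)
  expect_gt(length(read_gene_list(b$paths[["smg"]])), 0L)
})

test_that("zero contamination and empty cohorts are handled", {
  d <- withr::local_tempdir()
  b <- simulate_bundle(small_cfg(seed = 104L, germline_contamination = 0),
                       d)
  expect_equal(sum(b$truth$cohorts$cohortA$is_germline_copy), 0L)
  som <- read_indel_vcf(b$paths[["cohortA"]])
  germ <- read_indel_vcf(b$paths[["germline"]])
  f <- filter_germline(som, germ)
  # only coincidental exact matches are possible on a desk-scale genome
  expect_lt(f$n_removed / f$n_input, 0.01)

  d2 <- withr::local_tempdir()
  b2 <- simulate_bundle(small_cfg(seed = 105L,
                                  n_somatic = c(cohortA = 0L)), d2)
  x <- read_indel_vcf(b2$paths[["cohortA"]])
  expect_equal(nrow(x), 0L)
})

test_that("infeasible configurations are rejected before writing", {
  expect_error(sim_config(p_deletion = 1.4), "probabilities")
  expect_error(sim_config(region_probs = c(cds = 0.5, utr5 = 0.1,
                                           utr3 = 0.1, other = 0.1)),
               "sum to 1")
  expect_error(sim_config(n_genes = 0), "n_genes")
})

test_that("pipeline recovers the generative parameters (3-SE envelope)", {
  d <- withr::local_tempdir()
  n <- 10000L
  cfg <- sim_config(seed = 106L, n_genes = 30L, n_germline = 2000L,
                    n_somatic = c(tumor = n),
                    germline_contamination = 0.20,
                    p_deletion = 0.60, p_intergenic = 0.20,
                    region_probs = c(cds = 0.15, utr5 = 0.03, utr3 = 0.07,
                                     other = 0.75),
                    p_fs_given_cds = 0.70,
                    p_tfbs_cds = 0.45, p_tfbs_noncds = 0.22)
  b <- simulate_bundle(cfg, d)
  som <- read_indel_vcf(b$paths[["tumor"]], cohort = "tumor")
  germ <- read_indel_vcf(b$paths[["germline"]])
  tx <- read_transcripts(b$paths[["gff"]])
  tfbs <- read_tfbs_bed(b$paths[["tfbs"]])

  f <- filter_germline(som, germ)
  se <- function(p, m) sqrt(p * (1 - p) / m)
  expect_lt(abs(f$n_removed / f$n_input - 0.20), 3 * se(0.20, n) + 0.01)

  ann <- f$retained |> annotate_indels(tx) |> annotate_tfbs_overlap(tfbs)
  s <- summarize_cohort(ann)
  expect_lt(abs(s$deletion_pct / 100 - 0.60),
            3 * se(0.60, s$transcript_indels))
  expect_lt(abs(s$cds_pct / 100 - 0.15), 3 * se(0.15, s$transcript_indels))
  expect_lt(abs(s$fs_pct / 100 - 0.70), 3 * se(0.70, s$cds_indels))
  expect_lt(abs(s$cds_tfbs_overlap_pct / 100 - 0.45),
            3 * se(0.45, s$cds_indels))
  expect_lt(abs(s$non_cds_tfbs_overlap_pct / 100 - 0.22),
            3 * se(0.22, s$transcript_indels - s$cds_indels))
})

test_that("ground-truth labels equal the pipeline's assignments exactly", {
  d <- withr::local_tempdir()
  b <- simulate_bundle(small_cfg(seed = 107L), d)
  tx <- read_transcripts(b$paths[["gff"]])
  tfbs <- read_tfbs_bed(b$paths[["tfbs"]])
  for (coh in c("cohortA", "cohortB")) {
    x <- read_indel_vcf(b$paths[[coh]], cohort = coh) |>
      annotate_indels(tx) |>
      annotate_tfbs_overlap(tfbs)
    truth <- b$truth$cohorts[[coh]]
    expect_equal(x$region, truth$region)
    expect_equal(x$frame, truth$frame)
    expect_equal(x$overlaps_tfbs, truth$tfbs_overlap)
  }
})

test_that("CDS conservation enrichment is recovered from the track", {
  d <- withr::local_tempdir()
  cfg <- small_cfg(seed = 108L,
                   n_somatic = c(tumor = 1500L),
                   region_probs = c(cds = 0.5, utr5 = 0.05, utr3 = 0.15,
                                    other = 0.3),
                   phylop = list(mean_cds = 4, mean_noncds = 0, sd = 1))
  b <- simulate_bundle(cfg, d)
  track <- read_conservation(b$paths[["phylop"]])
  tx <- read_transcripts(b$paths[["gff"]])
  ann <- read_indel_vcf(b$paths[["tumor"]]) |> annotate_indels(tx)
  cds_scores <- score_indels(ann[ann$region == "CDS", ], track)
  m <- mean(cds_scores$score, na.rm = TRUE)
  n_sc <- sum(!is.na(cds_scores$score))
  expect_lt(abs(m - 4), 3 / sqrt(n_sc) + 0.05)
})

test_that("helix placement bias is recovered through structure attribution", {
  d <- withr::local_tempdir()
  cfg <- sim_config(seed = 109L, n_genes = 15L, n_germline = 50L,
                    n_somatic = c(tumor = 2500L),
                    germline_contamination = 0,
                    p_deletion = 1, p_intergenic = 0,
                    region_probs = c(cds = 1, utr5 = 0, utr3 = 0, other = 0),
                    p_fs_given_cds = 0,
                    ss_helix_bias = 0.6)
  b <- simulate_bundle(cfg, d)
  tx <- read_transcripts(b$paths[["gff"]])
  profiles <- read_ss_profiles(b$paths[["ss"]])
  ann <- read_indel_vcf(b$paths[["tumor"]]) |> annotate_indels(tx)
  spans <- affected_residues(ann, select_representative_transcripts(tx))
  states <- ss_states_for_indels(spans, profiles)
  helix_frac <- mean(states$state == "helix")
  expect_lt(abs(helix_frac - 0.6), 3 * sqrt(0.6 * 0.4 / nrow(states)) + 0.01)
})
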