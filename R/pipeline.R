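#' Run the full comparative-analysis pipeline
#'
#' Orchestrates every stage on a bundle of input files: read inputs,
#' filter germline leakage from each tumour cohort, annotate regions and
#' frames, compute TFBS overlap, conservation scoring, and write the report
#' table suite. All intermediate and final artifacts are plain TSV/JSON so
#' each stage is inspectable; reruns on identical inputs produce identical
#' bytes.
#'
#' Outputs written to `out_dir`:
#' * `annotated_<cohort>.tsv` — one row per retained indel with region,
#'   frame, gene and TFBS overlap;
#' * `table1.tsv` cohort totals and deletion/insertion split,
#'   `table2.tsv` CDS/FS/NFS summary, `table3.tsv` top genes by CDS indels,
#'   `table4.tsv` TFBS-overlap strata, `table5.tsv` conserved-position gene
#'   ranking, `table6.tsv` gene-list (SMG) summary (when a list is given);
#' * `ss_distribution.tsv` (when profiles are given),
#'   `phylop_ecdf.tsv`, `chi2_tests.tsv`, `metadata.json`.
#'
#' @param bundle Optional directory created by [simulate_bundle()]; file
#'   arguments default to its standard names.
#' @param gff,germline_vcf,tfbs,phylop,ss,smg Input paths (annotation,
#'   germline panel VCF, TFBS BED, conservation track, secondary-structure
#'   profiles, gene list). `ss` and `smg` are optional.
#' @param somatic_vcfs Named character vector of tumour-cohort VCF paths.
#' @param out_dir Output directory.
#' @param window Position window for the cross-cohort overlap row.
#' @param cutoff Conservation score cutoff for the gene ranking.
#' @param yates Apply the Yates correction in the 2x2 chi-squared tests.
#' @param dedup Deduplicate cohorts by exact identity before filtering.
#' @return Invisibly, a named list with all computed tibbles.
#' @export
run_pipeline <- function(bundle = NULL,
                         gff = NULL, germline_vcf = NULL,
                         somatic_vcfs = NULL, tfbs = NULL, phylop = NULL,
                         ss = NULL, smg = NULL,
                         out_dir, window = 5L, cutoff = 5, yates = FALSE,
                         dedup = FALSE) {
  if (!is.null(bundle)) {
    gff <- gff %||% file.path(bundle, "genes.gff3")
    germline_vcf <- germline_vcf %||% file.path(bundle, "germline.vcf")
    tfbs <- tfbs %||% file.path(bundle, "tfbs.bed")
    phylop <- phylop %||% file.path(bundle, "phylop.bedgraph")
    if (is.null(ss) && file.exists(file.path(bundle, "ss_profiles.tsv"))) {
      ss <- file.path(bundle, "ss_profiles.tsv")
    }
    if (is.null(smg) && file.exists(file.path(bundle, "smg_genes.txt"))) {
      smg <- file.path(bundle, "smg_genes.txt")
    }
    if (is.null(somatic_vcfs)) {
      all_vcf <- list.files(bundle, pattern = "\\.vcf$", full.names = TRUE)
      all_vcf <- setdiff(all_vcf, file.path(bundle, "germline.vcf"))
      somatic_vcfs <- setNames(all_vcf, sub("\\.vcf$", "", basename(all_vcf)))
    }
  }
  required <- c(gff = gff, germline_vcf = germline_vcf, tfbs = tfbs,
                phylop = phylop, somatic_vcfs)
  missing_in <- required[!file.exists(required)]
  if (length(missing_in) > 0L) {
    stop("input file(s) not found: ",
         paste(names(missing_in), missing_in, sep = " = ", collapse = "; "),
         call. = FALSE)
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  stage <- function(name, expr) {
    message("[", name, "] ...")
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  transcripts <- stage("read-annotation", read_transcripts(gff))
  tfbs_set <- stage("read-tfbs", read_tfbs_bed(tfbs))
  track <- stage("read-conservation", read_conservation(phylop))
  germline <- stage("read-germline", read_indel_vcf(germline_vcf,
                                                    cohort = "germline"))
  cohorts_raw <- stage("read-cohorts", purrr::imap(
    as.list(somatic_vcfs), function(p, nm) read_indel_vcf(p, cohort = nm)))
  profiles <- if (!is.null(ss)) stage("read-ss", read_ss_profiles(ss)) else NULL
  smg_genes <- if (!is.null(smg)) stage("read-smg", read_gene_list(smg)) else NULL

  rep_tx <- select_representative_transcripts(transcripts)

  filt <- stage("filter-germline", purrr::map(
    cohorts_raw, function(x) filter_germline(x, germline, dedup = dedup)))

  annotate_one <- function(x) {
    x |>
      annotate_indels(rep_tx) |>
      annotate_tfbs_overlap(tfbs_set)
  }
  ann <- stage("annotate", purrr::map(filt, function(f) annotate_one(f$retained)))
  ann_germ <- stage("annotate-germline", annotate_one(germline))
  for (nm in names(ann)) {
    readr::write_tsv(flatten_for_tsv(ann[[nm]]),
                     file.path(out_dir, paste0("annotated_", nm, ".tsv")),
                     progress = FALSE)
  }

  summaries <- purrr::imap(ann, function(a, nm) {
    summarize_cohort(a, cohort = nm,
                     n_total = filt[[nm]]$n_input,
                     n_germline_matched = filt[[nm]]$n_removed)
  })
  summaries$germline <- summarize_cohort(ann_germ, cohort = "germline",
                                         n_total = nrow(germline))

  # cross-cohort overlap row, for exactly two tumour cohorts
  overlap_row <- NULL
  if (length(ann) == 2L) {
    ov <- stage("cohort-overlap",
                cohort_overlap(filt[[1]]$retained, filt[[2]]$retained,
                               window = window, dedup = TRUE))
    shared_ann <- annotate_one(ov$shared_a)
    overlap_label <- paste(names(ann), collapse = " ∩ ")
    overlap_row <- summarize_cohort(shared_ann, cohort = overlap_label,
                                    n_total = ov$n_shared_a)
    summaries[[overlap_label]] <- overlap_row
  }
  summary_tbl <- dplyr::bind_rows(summaries)

  t1_cols <- c("cohort", "total_indels", "germline_matched", "germline_pct",
               "transcript_indels", "deletions", "deletion_pct",
               "insertions", "insertion_pct", "n_transcripts")
  t2_cols <- c("cohort", "n_transcripts_cds", "cds_indels", "cds_pct",
               "fs_indels", "fs_pct", "nfs_indels", "nfs_pct",
               "utr5_indels", "utr5_pct", "utr3_indels", "utr3_pct")
  t4_cols <- c("cohort", "transcript_indels", "tfbs_overlap",
               "tfbs_overlap_pct", "cds_indels", "cds_tfbs_overlap",
               "cds_tfbs_overlap_pct", "non_cds_tfbs_overlap",
               "non_cds_tfbs_overlap_pct")
  write_summary_tsv(summary_tbl[, t1_cols], file.path(out_dir, "table1.tsv"))
  write_summary_tsv(summary_tbl[, t2_cols], file.path(out_dir, "table2.tsv"))
  write_summary_tsv(summary_tbl[, t4_cols], file.path(out_dir, "table4.tsv"))

  all_ann <- c(ann, list(germline = ann_germ))
  t3 <- purrr::imap_dfr(all_ann, function(a, nm) {
    dplyr::mutate(top_genes(a, region = "CDS", n = 10L), cohort = nm,
                  .before = 1)
  })
  write_summary_tsv(t3, file.path(out_dir, "table3.tsv"))

  t5 <- stage("conservation-ranking", purrr::imap_dfr(
    all_ann, function(a, nm) {
      r <- rank_conserved_genes(a, track, cutoff = cutoff)
      r |> dplyr::group_by(stratum) |> dplyr::slice_head(n = 10L) |>
        dplyr::ungroup() |> dplyr::mutate(cohort = nm, .before = 1)
    }))
  write_summary_tsv(t5, file.path(out_dir, "table5.tsv"))

  t6 <- NULL
  if (!is.null(smg_genes)) {
    t6 <- purrr::imap_dfr(all_ann, function(a, nm)
      smg_table(a, smg_genes, cohort = nm))
    write_summary_tsv(t6, file.path(out_dir, "table6.tsv"))
  }

  # secondary-structure distribution of NFS coding indels
  ss_dist <- NULL
  if (!is.null(profiles)) {
    ss_dist <- purrr::imap_dfr(all_ann, function(a, nm) {
      spans <- affected_residues(a, rep_tx)
      if (nrow(spans) == 0L) return(NULL)
      ss_state_distribution(ss_states_for_indels(spans, profiles)) |>
        dplyr::mutate(cohort = nm, .before = 1)
    })
    write_summary_tsv(ss_dist, file.path(out_dir, "ss_distribution.tsv"))
  }

  dist <- stage("score-distribution", {
    pooled <- dplyr::bind_rows(purrr::imap(
      all_ann, function(a, nm) dplyr::mutate(a, cohort = nm)))
    score_distribution(pooled, track)
  })
  write_summary_tsv(dist$ecdf, file.path(out_dir, "phylop_ecdf.tsv"))

  chi2_rows <- NULL
  germ_row <- summaries$germline
  if (germ_row$deletions + germ_row$insertions > 0) {
    chi2_rows <- purrr::imap_dfr(ann, function(a, nm) {
      s <- summaries[[nm]]
      m <- matrix(c(s$deletions, s$insertions,
                    germ_row$deletions, germ_row$insertions),
                  nrow = 2, byrow = TRUE)
      two <- chi2_test(m, correct = yates)
      gof <- chi2_gof(c(s$deletions, s$insertions),
                      c(germ_row$deletions, germ_row$insertions))
      tibble(cohort = nm,
             comparison = "deletion_insertion_vs_germline",
             convention = c(two$convention, gof$convention),
             statistic = c(two$statistic, gof$statistic),
             df = c(two$df, gof$df),
             p_value = c(two$p_value, gof$p_value))
    })
    write_summary_tsv(chi2_rows, file.path(out_dir, "chi2_tests.tsv"))
  }

  meta <- list(
    package = "indelscope",
    version = as.character(utils::packageVersion("indelscope")),
    parameters = list(window = window, cutoff = cutoff, yates = yates,
                      dedup = dedup),
    inputs = as.list(required),
    chi2_convention = paste(
      "2x2 Pearson without continuity correction unless yates = TRUE;",
      "a goodness-of-fit of cohort deletion/insertion counts against the",
      "germline proportions is reported alongside"),
    stage_rows = c(purrr::map_int(cohorts_raw, nrow),
                   germline = nrow(germline))
  )
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(summaries = summary_tbl, top_genes = t3,
                 conserved_genes = t5, smg = t6, ss_dist = ss_dist,
                 score_dist = dist, chi2 = chi2_rows, annotated = ann,
                 annotated_germline = ann_germ, filters = filt))
}

# drop list-columns before writing an annotated tibble
flatten_for_tsv <- function(x) {
  x[, !vapply(x, is.list, logical(1)), drop = FALSE]
}
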