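# indelscope

Comparative analysis of somatic insertions and deletions (indels) in tumour
cohorts, in R.

Somatic indel callers leak germline variants: a fraction of "somatic" calls
are inherited indels that must be removed before any downstream comparison.
`indelscope` implements the full desk analysis that follows a somatic indel
call set: germline filtering by strict indel identity, classification of
each indel against a representative transcript (CDS, 5'/3' UTR, other
transcript sequence, intergenic), frameshift/non-frameshift calls, the
protein secondary-structure context of non-frameshift coding indels,
overlap with predicted transcription factor binding sites (TFBSs — the
"duon" question: coding sequence that doubles as regulatory sequence),
per-base conservation (phyloP) scoring of indel positions, and the cohort
summary tables, chi-squared comparisons, gene rankings and hypergeometric
gene-set enrichment built on top. A deterministic synthetic-cohort
simulator with per-indel ground-truth labels makes every stage testable
without any data download.

## The rules at the core

* **Indel normalization.** Every VCF record is reduced to a minimal
  anchored representation (shared trailing bases trimmed, then shared
  leading bases; left-aligned when a reference is supplied). An indel is
  the tuple (chrom, anchored position *i*, type, event sequence).
* **Germline identity (exact).** Two indels are the same only if position,
  type **and** sequence all agree; somatic calls with an exact germline
  match are removed, and the removed fraction is reported as a percentage
  of the call set.
* **Cross-cohort identity (fuzzy).** Two indels are shared between cohorts
  if they have the same type and positions within *i* ± 5.
* **Frame rule.** A coding indel is non-frameshift (NFS) iff its net length
  change is ≡ 0 (mod 3), else frameshift (FS).
* **Region classification.** Deletions are judged by their deleted-base
  span, insertions by the two bases flanking the breakpoint; a span
  crossing a boundary takes the highest-precedence region
  (CDS > UTR5 > UTR3 > other transcript sequence).
* **Conservation collection.** phyloP scores are collected at every deleted
  base for deletions and at the two flanking bases for insertions; genes
  are ranked by their number of coding indel positions with score > 5,
  split by TFBS overlap.
* **Secondary structure.** DSSP 8-state strings collapse to helix
  (H, G, I), strand (E, B) and loop (everything else).

## Worked example

```r
library(indelscope)

# simulate a study: two tumour cohorts plus a germline panel, with the
# preset whose generative parameters equal the published BRCA cohort
# composition (16.74% germline leakage, 58.67% deletions, 8.64% CDS,
# 74.19% FS among CDS, 44.49% CDS-TFBS overlap)
cfg <- paper_like_config(n_somatic = c(tumorA = 20000, tumorB = 15000),
                         seed = 7)
bundle <- simulate_bundle(cfg, "demo_bundle")

res <- run_pipeline(bundle = "demo_bundle", out_dir = "demo_report")
res$summaries[, c("cohort", "total_indels", "germline_pct",
                  "transcript_indels", "deletion_pct", "cds_pct", "fs_pct")]
#>            cohort total_indels germline_pct transcript_indels deletion_pct cds_pct fs_pct
#> 1          tumorA        20000        16.63             11073        58.69    8.89  73.27
#> 2          tumorB        15000        16.59              8405        58.70    8.54  76.32
#> 3        germline         5000           NA              2008        56.82    0.45  22.22
#> 4 tumorA ∩ tumorB        12059           NA              8536        61.35    1.78  72.37
```

The filter recovers the 16.74% leakage rate built into the generator
(16.63% and 16.59% observed), the deletion excess (58.7%) and the CDS share
(≈8.6%) of transcript indels, and the FS excess among coding indels
(73–76% versus ~50% in the germline panel). `demo_report/` contains the
full table suite (`table1.tsv` … `table6.tsv`), the secondary-structure and
phyloP distribution exports, chi-squared comparisons and a provenance
`metadata.json`.

Testing whether a cohort's deletion/insertion balance departs from the
germline panel:

```r
s <- res$summaries
glance(chi2_gof(c(s$deletions[1], s$insertions[1]),
                c(s$deletions[3], s$insertions[3])))
#>   statistic df      p_value                       method correct
#> 1  15.77567  1 7.131356e-05 gof_vs_reference_proportions   FALSE
```

Individual stages compose with the pipe:

```r
som  <- read_indel_vcf("tumorA.vcf", cohort = "tumorA")
germ <- read_indel_vcf("germline.vcf")
tx   <- read_transcripts("genes.gff3")
ann  <- filter_germline(som, germ)$retained |>
  annotate_indels(tx) |>
  annotate_tfbs_overlap(read_tfbs_bed("tfbs.bed"))
summarize_cohort(ann)
overlap_table(ann)
rank_conserved_genes(ann, read_conservation("phylop.bedgraph"), cutoff = 5)
```

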