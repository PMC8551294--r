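---
title: "Methods: somatic indel annotation and cohort comparison"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic indel annotation and cohort comparison}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its methods: the models and rules
it implements, the parameters that matter, the design decisions taken where
the conventions in the field are genuinely open, and what the synthetic
cohorts do and do not demonstrate about real data.

## The analysis problem

Somatic indel calling compares tumour and matched-normal sequencing, but
the resulting call sets are contaminated with germline indels — inherited
variants that the caller failed to subtract. Because germline indels have
survived selection they are systematically different from true somatic
events (fewer coding, fewer frameshift, less conserved positions), so
leaving them in biases every downstream comparison. The pipeline therefore
runs in a fixed order: **filter germline leakage → classify regions and
frames → overlap with TFBSs → conservation scoring → cohort summaries and
tests**.

## Coordinate conventions

All interval containers (exons, CDS, UTRs, TFBSs) are 0-based half-open
internally; VCF (1-based, anchor base before the event) and GFF3/GTF
(1-based closed) are converted at the I/O boundary. An indel's anchored
position `pos` is the base *before* the event, per VCF convention:

* a deletion of `L` bases removes 1-based positions `pos+1 … pos+L`;
* an insertion sits between `pos` and `pos+1`.

## Indel normalization and identity

`normalize_indels()` trims shared trailing bases first, then shared
leading bases (keeping the anchor), and optionally left-aligns against a
reference sequence. Normalization is idempotent, and reconstructing the
allele pair from `(pos, itype, seq)` and re-normalizing returns the same
record — both are enforced as property tests. Records whose trimmed
alleles both retain bases (MNV-like) are flagged `complex`: they stay in
cohort totals but are excluded from frame and structure analysis.
Equal-length records are SNVs and dropped with a counter at VCF load.

Normalizing before matching is a deliberate choice: the strict identity
rule — same chromosome, position, type and event sequence — is only
well-defined across callers once both sides use the same canonical
representation. The fuzzy rule used for cross-cohort sharing (same type,
positions within `i ± 5`) compares the same normalized anchors. The
window default of 5 follows the established practice for calling two
indel reports "the same" across datasets; exact matching ignores the
window entirely.

Deduplication is **off by default** in `filter_germline()`: cohort totals
count indel events, so a recurrent indel present in many samples
contributes once per occurrence. A `dedup` flag collapses to distinct
(chrom, pos, type, sequence) events instead; cross-cohort overlap
deduplicates by default since "shared indels" is a set-level statement.

## Region and frame classification

One representative transcript per gene — the longest by exonic length,
ties broken by smallest transcript id, with an optional priority list for
canonical tags — is used for all region calls. UTRs are derived as the
exonic bases outside the CDS, split 5'/3' by the transcript strand (on the
minus strand the 5' UTR occupies the higher genomic coordinates).

Deletions are classified by their deleted-base span; insertions by the two
bases flanking the breakpoint. Where a footprint crosses a boundary the
higher-precedence region wins: **CDS > UTR5 > UTR3 > other transcript
sequence**, with `intergenic` when no transcript span is touched at all.
The precedence order reflects that coding impact dominates interpretation;
the insertion convention (region containing either flanking base, ties by
precedence) mirrors the conservation flank rule below, so every module
judges an insertion by the same two bases.

A CDS indel is non-frameshift iff `|net_len| mod 3 == 0`, else frameshift.
Net length, not allele length, carries the rule, so it is unaffected by
the anchor base.

### Affected protein residues

For NFS coding indels the package maps genomic coordinates to CDS offsets
(strand-aware) and attributes residues as:

* deletions — every residue whose codon intersects a deleted base
  (codon-intersection is our rule; conventions differ for deletions that
  cut codons part-way, and enumerating intersected codons is the choice
  that agrees with a per-base brute force);
* insertions — the two residues flanking the breakpoint, clipped at the
  protein ends.

Residue states come from 8-state DSSP-style profiles collapsed to three
states (H/G/I → helix, E/B → strand, rest → loop). Cohort distributions
count one state per affected residue by default; a per-indel majority mode
(ties resolved helix > strand > loop) is available because published
three-state distributions do not always state which unit they count.
Structure profiles are an input (from DSSP on solved structures or from a
secondary-structure predictor); the package does not run BLAST/DSSP
itself.

## TFBS overlap

TFBS sets are externally predicted, non-overlapping intervals (verified at
load; touching intervals are legal under half-open coordinates). A
deletion overlaps a TFBS iff at least one deleted base falls inside one; an
insertion iff at least one flanking base does. Each indel counts once no
matter how many TFBSs it hits. Overlap is computed genome-wide and then
stratified (all transcript indels / CDS / non-CDS, optionally restricted
to a gene list); no locality constraint ties the TFBS to the indel's own
transcript. The ≥1-base rule and the flank convention are package choices
where zero-length breakpoints make "overlap" otherwise undefined.

## Conservation scoring

Per-base phyloP-style tracks are read from bedGraph or fixed-step wig into
a sparse position → score map. The collection rule: deletions contribute
every deleted position, insertions their two flanking positions (clipped
at chromosome starts). Positions absent from the track are dropped and
counted — never imputed as zero, since phyloP is signed and zero is a
meaningful value. Gene rankings count positions with score **strictly
greater** than the cutoff (default 5), once per (gene, position) so
recurrent indels do not double-count a base; a flag restores
per-occurrence counting. Distribution exports (histograms and ECDFs per
region group × indel type × cohort) are plain tables so plots are
reproducible from files.

## Cohort statistics

Every printed percentage is `100 · numerator/denominator` of counts present
in the same summary, rounded **half-up** to two decimals (so 0.125 → 0.13);
round-half-even would disagree with published tables in edge cases. CDS and
UTR shares use the transcript-indel denominator; deletion/insertion and
FS/NFS shares use their immediate parent counts; TFBS percentages use
stratum totals. Empty denominators report missing, never zero.

Chi-squared comparisons default to the Pearson r×c test without continuity
correction (`correct = TRUE` enables Yates for 2×2). Published cohort
p-values of this kind are sometimes produced by a different convention —
a one-sample goodness of fit of the cohort's deletion/insertion counts
against the reference panel's proportions — and the two can differ by an
order of magnitude on identical counts. The package exposes both
(`chi2_test()`, `chi2_gof()`) and the pipeline records both in
`chi2_tests.tsv`, with the convention named in each row, because printed
p-values alone cannot always be traced to one test.

Gene-set enrichment is a one-sided hypergeometric tail with Bonferroni
correction over the sets actually tested and a 0.001 significance cutoff.
It is a generic, local replacement for web-service enrichment tools, which
are versioned services whose term-level output is not reproducible
offline; users supply their own GMT collections.

## The synthetic-cohort simulator

`simulate_bundle()` writes a complete input bundle — gene models (GFF3),
germline panel and tumour cohorts (VCF), TFBS set (BED), conservation
track (bedGraph), secondary-structure profiles, a gene list — plus
`truth.json` with every generative parameter and per-indel labels
(`is_germline_copy`, `region`, `frame`, `tfbs_overlap`).

Design points:

* **Inverted generation.** Each indel first draws a region class, then a
  position uniformly within that class (footprint wholly inside the class
  interval), then the pipeline must recover the class frequencies from
  positions alone. Truth labels are decided by construction, not by
  running the annotator, so exact truth/pipeline agreement is a real
  integration test of both directions.
* **Germline leakage** is simulated by copying panel records into the
  tumour cohorts with the configured probability; the filter's removed
  fraction estimates it. On a desk-scale genome a small number of *fresh*
  somatic indels coincide with panel records by chance (same position,
  type and sequence), which inflates the removed fraction slightly; the
  large-cohort runs therefore use 80 genes (~1 Mb) where this excess is
  well under one part in a thousand. Real genomes make it negligible.
* **Event sequences** are i.i.d. uniform A/C/G/T with truncated-geometric
  lengths; CDS indels force FS/NFS status through the length mod 3.
* **TFBS overlap enrichment** is realised by rejection: positions are
  redrawn until the indel's overlap state matches its drawn label (40
  rounds, then the realised state becomes the label), so configured
  overlap probabilities are exact conditional on feasibility.
* **Conservation** is Normal per base, with a higher mean inside CDS
  (defaults N(4,1) vs N(0,1)), emulating the score enrichment of coding
  positions.
* **Secondary structure** is i.i.d. per residue from configurable 8-state
  frequencies; an optional helix bias places NFS coding deletions
  codon-exactly on helix residues with the configured probability, for
  recovery tests of the structure-attribution path.
* **Determinism.** One seeded stream per bundle; identical configurations
  produce byte-identical files.

`paper_like_config()` is the preset whose generative parameters equal a
published breast-carcinoma cohort composition — 16.74% germline leakage,
58.67% deletions, 8.64% CDS / 0.66% 5'UTR / 3.45% 3'UTR shares, 74.19% FS
among CDS, TFBS overlap 44.49% (CDS) and 25.40% (non-CDS) — with the
corresponding germline-panel values; it exists so end-to-end runs exercise
realistic proportions.

### What the simulator does not emulate

Mutational signatures and sequence-context effects, read-level evidence
and caller artefacts, overlapping genes and alternative coding isoforms,
realistic genome sequence content, and inter-sample structure (indels are
exchangeable events, not sample genotypes). Passing recovery tests
therefore demonstrates that the pipeline's estimators are unbiased under
the stated generative model, not that any biological claim holds for real
cohorts.

## Numerical and degenerate-input choices

* Empty somatic sets report a missing overlap fraction; empty strata
  report missing percentages.
* Insertions at position 0 clip their flank collection to existing
  positions; spans partially outside the CDS (after precedence) clip with
  a warning.
* Ties everywhere break deterministically (alphabetical gene symbol,
  lexicographic transcript id) so reruns are byte-identical.
* Overlapping conservation-track lines follow a stated last-wins policy
  with a warning; overlapping TFBS intervals are an input error.
* Multi-allelic VCF rows split per ALT; symbolic alleles are skipped with
  a counter.

## Problem sizes in the test suite

Oracle-equivalence suites run brute-force checks on 200+ randomized
fixtures per engine (both strands). Parameter recovery runs 10,000
somatic indels in the module suite and 50,000 in the acceptance suite
against a 3-standard-error envelope; score-distribution checks use 10,000
positions per cohort. These sizes put Monte-Carlo noise well below the
tested tolerances while keeping the default test run fast on one CPU.

## Known limitations

* One representative transcript per gene means indels in an alternative
  isoform's exclusive exons can classify as `other_transcript`; an
  any-transcript sensitivity mode is a natural extension.
* Frame classification uses net length only; stop-gain/stop-loss and
  splice-site consequences are out of scope.
* The germline filter is identity-based; it cannot remove germline
  variants absent from the panel (no allele-frequency modelling).
* Enrichment reproduces the statistic, not any particular web service's
  term database.
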