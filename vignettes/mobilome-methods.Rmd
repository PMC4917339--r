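---
title: "mobilome: methods, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mobilome: methods, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the statistical model behind the package, the
meaning and defaults of every tunable parameter, the numerical choices
that could plausibly have been made differently, what the synthetic
generator does and does not emulate, and the package's known
limitations. It is a methods description, not a tutorial; the README
contains a worked example.

## 1. Coordinate and data conventions

All internal coordinates are **0-based, half-open** `[start, end)`.
Conversion to and from 1-based conventions happens only at the SAM and
GFF3 parsing boundary. Genomes are named character vectors of uppercase
`ACGTN` sequence; interval sets are plain data frames with
`chrom`/`start`/`end` (plus `strand` where relevant), validated by
`genomic_intervals()`.

## 2. The split-read, TSD-validated insertion caller

### 2.1 Signal model

A TE insertion at genomic position `j` with a target site duplication
(TSD) of length `t` produces, in the inserted haplotype,

```
left flank | TSD | TE (or its reverse complement) | TSD | right flank
```

Reads sequenced across either junction fail to map end-to-end to the
reference and become **split reads**: part TE, part unique genomic
sequence. Two independent read clusters — one per junction — should
point at two genomic boundaries exactly `t` apart, and the reference
sequence between them *is* the TSD. Requiring both clusters and a
plausible TSD width is the caller's main false-positive defence.

### 2.2 Algorithm

Given alignments of an accession's reads to the reference (or raw reads
plus the built-in exact aligner):

1. **Unmapped extraction** (`extract_unmapped`): reads with the
   unmapped flag set, duplicates excluded.
2. **Extremity mapping** (`map_to_extremities`): local alignment to a
   library of the first and last `extremity_len` = 300 bp of each TE
   consensus. An alignment is evidence only if the matched block and
   the soft-clipped remainder are both at least `min_clip` = 20 nt and
   the configuration is junction-compatible: the matched block must be a
   read suffix when it hits a 5' extremity start, or a read prefix when
   it hits a 3' extremity end. The genomic side of the junction (left or
   right of the TE) and the insertion orientation follow
   deterministically from the TE side and the strand of the match.
3. **Recursive clipped-fragment remapping** (`map_clipped_fragment`):
   the clipped (genomic) fragment is aligned to the reference requiring
   a unique exact placement. If it fails, one base is trimmed from the
   junction-proximal end and the alignment retried, down to `min_clip`
   nt. Trimming only the junction-proximal end means the far end of the
   fragment stays anchored, so the junction estimate is recovered by
   adding the trim count back.
4. **Dual clustering and TSD calling** (`cluster_evidences`,
   `call_insertion`): junction estimates are clustered per family and
   genomic side by single linkage with gap ≤ `tsd_overlap_factor`
   × `t` = 2`t`; each cluster's boundary is its mode, with ties broken
   toward the TE (maximum for the left-of-TE side, minimum for the
   right-of-TE side). A call requires a left and right cluster on the
   same chromosome, each with ≥ `min_reads_discovery` = 5 reads, whose
   boundaries delimit a TSD of width in `[1, 2t]`. The reported TSD is
   the reference substring between the right-side and left-side
   boundaries.

### 2.3 Filters and genotyping

`apply_filters()` annotates (never deletes) calls with seven flags:
`in_mask` (aberrant-coverage masks from Section 3), `inner_pericentromere`,
`spans_donor` (within an annotated copy of the same family — likely an
alignment artefact of the donor element), `in_control` (also called in
a negative-control run, same family, padded overlap), `coverage_outlier`
(junction support > median + `mad_k`·MAD of genome coverage, a
duplication signature), `high_frequency` (carried by ≥
`cohort_freq_filter` = 50% of the cohort — likely a reference allele),
and `in_te_annotation` (inside an annotated element of the configured
superfamilies, default ATHILA and GYPSY, where mapping is unreliable).
Passing calls keep `status = "PASS"`; others get a comma-joined flag
list.

`genotype_matrix()` re-tests every discovered site in every accession
at a deliberately relaxed threshold: an accession is a carrier if ≥
`min_reads_genotype` = 2 junction reads fall within the TSD ±
`genotype_tol_bp` = 2 bp (summed over both sides — a site already
validated by dual clusters in the discovery accession does not need
dual-cluster evidence again to be scored present elsewhere; this
asymmetric 5-vs-2 scheme trades discovery specificity for genotyping
sensitivity). `allele_frequency_spectrum()` summarises carriers into
private / shared(2–10) / shared(>10) classes.

## 3. Copy number from binned depth

`bin_coverage()` counts aligned reference bases per `window_bp` =
100 bp window (duplicates skipped) and records each window's GC
fraction. `gc_correct()` applies the median-ratio correction within
integer GC percent classes,

    corr = raw * median(all windows) / median(windows of the same GC%),

with classes containing fewer than 10 windows left uncorrected (the
class median is too noisy to be a denominator). This preserves the
global median by construction.

`detect_aberrant_regions()` flags windows whose corrected count departs
from the genome median by more than `mad_k` = 3 **unscaled** MADs
(median of absolute deviations, *no* 1.4826 consistency factor — the
threshold is an empirical fence, not a Gaussian sigma estimate) in
**either** of two reference replicates, then merges flagged runs across
single-window gaps.

`family_copy_number()` estimates

    cn = n_ref_copies * (sum corr_acc / med_acc) / (sum corr_ref / med_ref)

over the unmasked windows of the family's annotated copies, excluding
copies shorter than `min_te_len_cnv` = 300 bp (or half the consensus
length in GWAS mode, `gwas_mode_half_length`). `cnv_permutation_test()`
is a sign-flip test on per-window accession-minus-reference differences:
under the no-change null each difference is symmetric about zero, so
random sign assignments generate the null of |mean difference|. The test
is run against each reference replicate separately and the **maximum**
of the two p-values is reported — a deliberate stringency choice: a
family must look changed relative to *both* replicates. p-values use the
standard +1 correction, `(1 + #{null ≥ obs}) / (n_perm + 1)`.
`empirical_fdr()` converts p to the fraction of a null distribution
(p-values of random window sets of matched size,
`cnv_null_pvalues()`) at or below it; `cnv_scan()` flags families with
FDR < `cnv_fdr_threshold` = 1e-5.

## 4. Downstream statistics

* **Positional nulls** (`randomize_positions`): observed insertion
  positions are re-placed uniformly into the *allowed* genome (total
  genome minus masks and any excluded regions), preserving counts.
  Errors, not empty results, when the allowed space vanishes.
* **Pericentromere test** (`pericentromere_test`): per-stratum observed
  vs null-expected counts with a null 95% interval (2.5/97.5 null
  quantiles) and a 1-df chi-square on the pooled
  pericentromeric/non-pericentromeric split.
* **Window enrichment** (`window_enrichment`): 10-kb window counts
  compared to the pooled null count distribution; a window is enriched
  when its count reaches the smallest `c` with `P(count ≥ c)` ≤
  `enrich_tail` = 5e-5 (the upper 0.005% tail).
* **Metagene assignment** (`metagene_assign`): features compete in the
  fixed hierarchy 5'UTR > 3'UTR > exon > intron > intergenic; distances
  to the nearest gene are signed with upstream negative relative to the
  gene's orientation. Introns are synthesized as inter-exon gaps when
  not annotated.
* **Expression ratio test** (`expression_ratio_test`): genes within
  1 kb of a genotyped insertion; the statistic is the carrier vs
  non-carrier median expression ratio, the null permutes carrier labels
  preserving carrier counts, and the per-gene p-values are jointly
  checked against uniformity with a two-sample Kolmogorov–Smirnov test
  against null-generated p-values. Genes with no contrast or a zero
  non-carrier median are excluded rather than producing infinities.
* **Methylation spreading** (`methylation_spread_classify`): flanking
  50-bp (`meth_window_bp`) windows are scanned outward; spreading stops
  at the first of **two consecutive** windows with carrier minus
  non-carrier methylation below `meth_diff_threshold` = 0.2 (one noisy
  window must not truncate a real spread). The extent classifies as
  none, short (≤ `spread_short_bp` = 300), long (> `spread_long_bp` =
  1000), or intermediate.
* **Partial Mantel** (`partial_mantel`): distance matrices |Δcn|,
  |Δclimate| and 1 − kinship; the partial correlation of the first two
  given the third over upper triangles; the null permutes accession
  order of the copy-number distance matrix. Exact enumeration of all
  n! permutations is available for n ≤ 8 (no +1 correction, the
  enumeration is complete); the sampled route requires n ≥ 10 and uses
  the +1 correction.
* **Closed forms**: `bonferroni_threshold(alpha, m) = alpha/m`;
  `variance_explained(maf, beta, sd_y) = 2·maf·(1−maf)·beta²/sd_y²`;
  `prob_missing(f, fn, n, k) = fn · C(n, n−k) · f^(n−k) · (1−f)^k`, the
  probability that an insertion segregating at frequency `f` appears in
  exactly `n−k` of `n` sampled accessions and is missed in all of them.
* **Benchmarking** (`benchmark_rates`): greedy one-to-one matching of
  calls to truth requiring the same family and both boundary
  displacements ≤ `match_tolerance_bp` = 100; `fn_rate = fn/n_truth`,
  `fdr = fp/(fp + tp)`.

## 5. The synthetic generator and oracle aligners

`sim_config()` controls a fully synthetic cohort: i.i.d. reference
sequence at a target GC (optionally with isochore-like GC *domains* —
fixed-length blocks drawn from `gc_domain_levels` or a clamped normal —
so that GC-correction tests have real window-level GC variation to
correct); TE families of 700–1500 bp with family-fixed TSD lengths of
3–15 bp and extremities rejected until pairwise identity < 0.8 (so
extremity mapping is unambiguous by construction); planted insertions
with ≥ 1 kb spacing and 500 bp chromosome margins, the TSD emitted on
both sides of the (possibly reverse-complemented) TE; paired-end FR
reads of fixed length with Gaussian fragment sizes, optional
substitution errors, and an optional linear GC retention bias with
exact-count top-up. `simulate_structured_matrices()` produces
copy-number, climate and kinship matrices over two populations
(within-population kinship 0.6, between 0.2) with a configurable climate
effect size; at `effect_size = 0` it is, by contract, a genuine null for
the partial Mantel test.

What it emulates: split-read geometry, TSD duplication, insertion
orientation, coverage binning, GC bias, population structure. What it
deliberately does **not** emulate: indels and structural read errors
(substitutions only), quality scores, chimeric fragments, repetitive
reference sequence beyond the planted TE copies, truncated or nested
insertions, and excision. Passing the test suite therefore shows the
*algorithms implement their contracts* and recover planted signals under
clean and mildly noisy conditions — not that the caller achieves any
particular sensitivity on real libraries.

The naive aligners define "mapping" as **unique exact occurrence**: a
fragment maps iff it has exactly one exact placement summed over both
strands of all chromosomes (palindromic placements count twice), else it
is unmapped. For whole-genome classification of constant-width reads the
implementation uses an exact k-mer dictionary of all read-length
reference substrings — mathematically identical to the per-fragment
contract, which remains the documented semantics and is what the
brute-force oracle tests exercise.

## 6. Numerical choices worth knowing about

* **Unscaled MAD** in masking and coverage-outlier flags (see 3).
* **+1-corrected permutation p-values** everywhere a sampled null is
  used; omitted only in the exact-enumeration partial Mantel.
* **Modal cluster boundaries with ties toward the TE**: when two
  junction positions are equally frequent, the boundary closer to the
  insertion is taken, which biases ties toward narrower (more
  conservative) TSDs.
* **Trim direction** in fragment remapping: junction-proximal only, so
  the distal anchor is never eroded and the junction arithmetic stays
  exact.
* **Max of two reference p-values** in the CNV test: deliberately
  conservative; under two independent reference replicates the test is
  super-uniform (empirical size ≈ 0.02 at nominal 0.05), which the test
  suite asserts as an invariant rather than "fixing".
* **±2 bp genotyping tolerance** absorbs off-by-one junction jitter
  without letting neighbouring sites merge.
* **Iteration counts**: defaults are desk-scale (`n_perm` = 999,
  randomization nulls of ~1e3–1e4) rather than the 1e6-scale runs a
  production study would use; every function takes the count as a
  parameter.
* **Resolved ambiguities**: extremity length is a config knob
  (`extremity_len` = 300) separate from the short-family CNV cutoff
  (`short_family_bp` = 350); the Bonferroni worked example uses m = 12
  climate variables; `prob_missing` generalizes the printed n = 12 case
  to arbitrary n and k via the binomial coefficient.

## 7. Known limitations

* The **partial Mantel permutation test inflates type-I error when both
  copy number and climate share strong structure** with kinship — a
  known property of the method, not of this implementation. The
  structured generator's defaults (`structured_share` = 0.1, climate
  population offset 0.5) were chosen so that its `effect_size = 0`
  output satisfies the generator's own null contract (empirical size
  ≈ 0.05–0.065 at nominal 0.05); with much stronger shared structure
  the test's size degrades and results should be interpreted with care.
* The caller assumes **unique flanking sequence**: insertions into
  repeats are invisible because clipped fragments never map uniquely.
* TSDs longer than `2t` of the family's characteristic length, nested
  insertions, and 5'-truncated copies that remove an extremity are out
  of scope.
* GC correction uses window GC, not fragment GC; a fragment-level bias
  is only corrected to the extent it is visible at 100-bp window
  resolution.
* The exact aligners are intended for synthetic data and oracle duty;
  real libraries need an external mapper, whose SAM output the package
  reads (`read_sam`).
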