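# mobilome

Split-read detection of non-reference transposable element (TE)
insertions with target site duplication (TSD) validation, family-level
copy-number estimation from binned read depth, and the downstream
population statistics of a mobilome survey — all in R, at desk scale,
with a built-in synthetic data generator so the whole pipeline is
testable without any external data.

## Who this is for

Population genomicists studying TE activity in resequencing panels
(e.g. plant accession collections): you have short-read alignments for
many accessions against one reference genome and want to know *where*
new TE copies have inserted, *which accessions carry them*, *how many
copies* of each family each accession has, and whether insertion
positions, expression effects, methylation spreading, or climate
associations depart from suitable nulls.

## The model

**Insertion detection.** A non-reference insertion of a TE with a
TSD of length `t` leaves two split-read signatures at the insertion
point: reads crossing the 5' junction carry genomic sequence followed by
the first bases of the TE, and reads crossing the 3' junction carry the
last bases of the TE followed by genomic sequence. The caller:

1. extracts unmapped, non-duplicate reads (SAM flag 4, flag 1024
   excluded);
2. force-maps them to a library of 300-bp TE extremities, keeping
   alignments with a matched block and a soft-clip both ≥ 20 nt in a
   junction-compatible configuration;
3. remaps each clipped fragment to the reference genome, recursively
   trimming one junction-proximal base at a time until the fragment maps
   uniquely (or falls below 20 nt);
4. clusters junction estimates per family and genomic side
   (single-linkage, gap ≤ 2`t`), takes the modal boundary of each
   cluster, and calls an insertion when the two boundaries delimit a
   putative TSD of width in `[1, 2t]`, each side supported by ≥ 5 reads.
   The TSD sequence is read directly off the reference between the two
   junctions.

Calls then pass seven annotation filters (assembly masks, inner
pericentromeres, donor-element spans, negative controls, coverage
outliers at median + 3·MAD, cohort frequency ≥ 0.5, and annotated
ATHILA/GYPSY elements), and are genotyped across the cohort at a relaxed
threshold (≥ 2 junction reads within ± 2 bp of the TSD).

**Copy number.** Read counts are binned in 100-bp windows, GC-corrected
by the median-ratio method over integer GC percent classes
(`corr = raw · m / m_GC`), and aberrant regions (|corr − median| >
3·MAD in either of two reference replicates, single-window gaps bridged)
are masked. Family copy number is the masked, median-normalised depth
ratio over the family's reference copies times the reference copy
count. Departures from the reference are tested with a sign-flip
permutation test against each of two reference replicates, taking the
*maximum* of the two p-values, and converted to an empirical FDR against
random window sets; a family is called variable when FDR < 1e-5.

**Downstream statistics.** Positional nulls by uniform re-placement
into the mappable, non-masked genome; pericentromeric enrichment by a
1-df chi-square on observed/expected counts; 10-kb window clustering by
the upper 0.005% tail of the pooled null count distribution; metagene
assignment with the hierarchy 5'UTR > 3'UTR > exon > intron >
intergenic; carrier/non-carrier expression-ratio permutation tests
summarised by a Kolmogorov–Smirnov uniformity check; methylation
spreading classified from 50-bp flanking windows (stop at two
consecutive windows with carrier − non-carrier difference < 0.2);
partial Mantel tests of copy number vs climate given kinship; and
closed forms for the Bonferroni threshold, variance explained
(`2·maf·(1−maf)·β²/σ²`), and the probability a polymorphic insertion is
absent from all sampled carriers (`fn^(n−k)`-style binomial form).

**Synthetic generator and oracle aligners.** `sim_config()` +
`simulate_reference()`, `simulate_te_families()`, `plant_insertions()`,
and `simulate_reads()` produce a reference genome (optionally with
isochore-like GC domains), TE families with fixed 3–15 bp TSDs,
accession genomes with planted TSD-flanked insertions, and error-free or
noisy paired-end reads. `naive_end_to_end_align()` /
`naive_local_align()` / `naive_genome_align()` are exact string-matching
aligners (a read maps iff it has exactly one exact placement across both
strands) used both by the pipeline on synthetic data and as independent
oracles in the tests.

## Worked example

Simulate a cohort member, detect its insertions, and benchmark against
the planted truth:

```r
library(mobilome)

sc  <- sim_config(rng_seed = 11, n_chroms = 2, chrom_len_bp = 1e6,
                  n_families = 10, insertions_per_accession = 30,
                  mean_coverage = 25)
ref <- simulate_reference(sc)          # 2 Mb reference, two chromosomes
lib <- simulate_te_families(sc)        # 10 families, TSDs of 3-15 bp
acc <- plant_insertions(ref, lib, sc)  # accession genome + truth table
rd  <- simulate_reads(acc$genome, sc)  # 25x error-free 100-bp pairs
reads <- c(rd$mate1, rd$mate2)
names(reads) <- make.unique(names(reads))

res <- detect_insertions(ref, lib, reads = reads, accession = "acc1")
br  <- benchmark_rates(acc$truth, res$calls)
br$tp / br$n_truth              # sensitivity: 1.0 on this cohort
br$tp / br$n_calls              # precision:   1.0
sum(br$matches$dist == 0) / br$tp  # exact-TSD fraction: 1.0
```

On this seed the caller recovers all 30 planted insertions with no
false positives and every TSD boundary exact (run time ≈ 90 s on one
CPU). A known arithmetic example: `bonferroni_threshold(0.01, 12)`
returns `8.333e-04`, and a truth set of 142 insertions with 64 misses
benchmarks at `fn_rate = 0.4507` (45%).

A command-line interface wrapping the same functions is available via
`mobilome_cli()` and the `inst/cli/mobilome` script (subcommands
`simulate`, `coverage`, `cnv`, `call`, `genotype`, `stats`,
`benchmark`; every run writes a `manifest.json` with input checksums,
the configuration, and the seed).

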