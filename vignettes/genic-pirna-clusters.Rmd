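---
title: "Profiling genic piRNA clusters: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling genic piRNA clusters: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pirnakit)
```

pirnakit analyses small-RNA libraries from germline tissue for the
hallmarks of Piwi-interacting RNA (piRNA) production at protein-coding gene
loci: reads of the piRNA size class mapping to *both* DNA strands of a
locus, a uridine bias at read position 1 (primary piRNAs), an adenine bias
at position 10 (secondary piRNAs), and an excess of sense/antisense read
pairs whose 5′ ends overlap by exactly 10 nt — the ping-pong amplification
signature. Around that core it provides the supporting analyses such a
study needs: unique-mappability masking, strand-resolved cluster boundary
calling, structural comparison of the locus between strains, allele-of-
origin accounting in hybrid offspring, and H3K9me3 ChIP-seq enrichment
comparison. This vignette documents the models, the parameters that matter,
the numerical choices, and what the simulation-based validation does and
does not establish.

## Coordinate and weighting conventions

All internal coordinates are 0-based half-open; GFF3/GTF and SAM (1-based)
are converted at the file boundary, BED/bedGraph pass through unchanged.
The 5′ end of a minus-strand alignment is the *highest* genomic coordinate
of its interval — the overlap arithmetic below depends on this. Identical
read sequences are collapsed once into a multiplicity (`count`), and every
downstream statistic is count-weighted. `N` bases never match anything,
in reads or genomes.

## Read classing and contaminant subtraction

Inputs are adapter- and quality-trimmed reads (trimming itself is out of
scope; any published trimmer upstream is fine). The piRNA class is
23–29 nt; size-distribution profiles use 20–29 nt so the miRNA-sized
shoulder stays visible. Contaminant subtraction removes any read contained
in an rRNA/tRNA/snRNA/miRNA library on either strand with at most
`max_mismatch` mismatches; the default is 0 because exact containment is
the only assumption-free choice — the tolerance is exposed as a flag rather
than silently fixed.

## Mapping model

`align_all()` is an exhaustive matcher (dictionary search at 0 mismatches,
sliding pattern comparison otherwise), not a heuristic aligner: at desk
scale (genomes up to ~10 Mb, reads ≤ 64 nt) it enumerates *every* placement
with at most 3 mismatches, which makes the downstream filters exactly
reproducible and testable against a brute-force oracle. External aligner
output can be substituted through `read_alignments()` (SAM/BAM) for larger
genomes; gapped/spliced alignment is deliberately not implemented, so
spliced RNA-seq must arrive pre-aligned.

Two filters implement the retention rules:

* `filter_unique_best_stratum()` keeps a read only when its
  minimal-mismatch stratum holds exactly one placement; ties are never
  broken — multi-best reads are discarded wholesale.
* `align_allele_specific()` re-aligns reads to a merged diploid genome
  (contigs prefixed by haplotype label) and keeps only single
  *perfect* placements. Reads from sequence identical between haplotypes
  necessarily place twice and drop out, so retained reads are attributable
  to one allele with structurally guaranteed 100% precision on error-free
  reads; sequencing errors simply reduce recall uniformly, and no error
  correction is attempted.

`compute_mappability()` marks a position 1 when the k-mer starting there
occurs exactly once among all forward-strand k-mers (k = 25 for
piRNA-length reads, 50 for mRNA/ChIP reads, matching k-mer-mappability
practice). Reverse-complement collapsing is off by default because the
forward-strand convention is what the standard tool computes; the flag
documents the ambiguity rather than hiding it.

## Ping-pong signature and biases

For plus-strand 5′ position $p^+$ with weight $w^+$ and minus-strand 5′
position $p^-$ with weight $w^-$, the overlap is $o = p^- - p^+ + 1$ and
bin $o \in \{1,\dots,20\}$ accumulates $w^+ w^-$. The summary score is

$$ z_{10} = \frac{h[10] - \overline{h[o \neq 10]}}{\mathrm{sd}(h[o \neq 10])} $$

with the sample (n−1) standard deviation. Position-level product weighting
and the 1…20 background window are stated explicitly because the signature
is often cited without formulas; the window is exposed as `max_overlap`.
With fewer than two distinct populated background bins the score is
undefined and flagged, never silently 0. The implementation is validated
bin-for-bin and to $10^{-12}$ in $z_{10}$ against an independent all-pairs
enumeration.

`nucleotide_bias()` reports the weighted fraction of reads with U/T at
position 1 and A at position 10 of the read-orientation sequence;
position 10 is computed over reads ≥ 10 nt only, since it does not exist
otherwise.

RPKM is $c \times 10^9 / (L \cdot D)$ for count $c$, feature length $L$ bp
and library depth $D$. For piRNA quantification the depth is the total
genome-mapped 23–29 nt read count after contaminant subtraction and unique
filtering; "sequencing depth" is genuinely ambiguous in common usage, so
the choice is recorded here and configurable. Reads overlapping exons of
two or more features are dropped as ambiguous rather than fractionally
assigned — the simplest reproducible rule, with fractional assignment left
to a future flag.

## Cluster profiling and the locus diff

`stranded_coverage()` builds per-base, per-strand tracks (and 5′-start
tracks used for read counting). `call_clusters()` merges covered positions
bridging gaps ≤ `max_gap` (default 1000 bp), drops intervals with fewer
than `min_reads` weighted reads (default 100) and flags a region
dual-strand when the minor/major strand read ratio reaches
`dual_ratio_threshold` (default 0.1). None of these thresholds has a
published value — "continuous mapping" is a qualitative notion — so they
are explicit parameters whose defaults reproduce contiguous cluster calls
on the simulator. "All mappers" tracks weight each placement $1/n_{best}$.

`extract_locus()` adds ±10 kb flanks (truncated and flagged at contig
edges). `pairwise_locus_diff()` compares two locus sequences by anchor
chaining rather than end-to-end dynamic programming: 21-mers unique within
each sequence and shared between them are collapsed into constant-offset
runs, the heaviest colinear chain of runs is selected, run interiors are
compared base-by-base (SNPs), and inter-run segments are aligned globally
with affine gaps (SNPs + indels at base resolution). Segments longer than
`max_align_len` (20 kb) or with a dynamic-programming area above
`max_align_area` ($4\times10^6$) — in practice satellite arrays, which are
anchor-free — contribute a single length-difference gap, matching the
dot-plot level of resolution at which such regions can honestly be
compared. Indels ≥ `gap_min` (500 bp) are additionally surfaced as "gaps"
(TE-insertion-scale events). Indel positions are left-anchored by the
alignment and may shift by a base or two where the flanking sequence is
locally repetitive; lengths are exact. Satellite array *length* comparison
is annotation-based (summed satellite feature length per haplotype): the
package measures arrays, it does not annotate repeats de novo.

## ChIP-seq enrichment

`binned_coverage()` accumulates fragment overlap per 10-bp bin (single-end
reads extended to a fixed fragment length, default 200 bp — the single-end
extension has no published value and must be chosen; paired spans are used
as-is). Duplicate-fragment removal and multi-mapper exclusion are on by
default for real data; the simulators draw fragments independently, so
pipelines on simulated data disable deduplication. RPGC divides by
`total_fragment_bases / effective_genome_size` so mean per-base coverage is
exactly 1 (an arithmetic identity, tested to $10^{-6}$); the effective
genome size defaults to the non-N base count. Input tracks are subtracted
bin-wise with negatives retained and counted, not clipped.

The enriched-region prefilter is intentionally simple: per-bin fragment
counts are tested one-sided against the library-scaled input expectation
under a Poisson model, with the expectation floored at the genome-wide mean
input count so sparse-input bins cannot manufacture significance;
Benjamini–Hochberg-adjusted p-values at or below `alpha` (0.05) define
significant bins, merged across single-bin gaps. This replaces a full peak
caller — the scientific claim downstream is the *between-sample comparison*,
which is a two-sided Mann–Whitney U test on per-region mean
treat-minus-input values: exact enumeration when $n_a n_b \le 10^4$ and
tie-free, otherwise the tie-corrected normal approximation; all-tied input
returns p = 1. ChIP-qPCR percent-input normalization and the
$2^{-\Delta C_t}$ relative-expression transform are provided as closed
forms.

## What the simulators emulate — and what they do not

The generators produce a diverged strain-genome pair and read libraries
with complete per-read truth, emulating the structure of the biological
system: a ~100 kb contig with a 20 kb dual-strand cluster containing a gene
model, a full-length 5403 bp TE insertion upstream of the gene in one
haplotype only, a flanking satellite array (370 bp unit) at a ~3-fold
copy-number difference (15 vs 45 copies — scaled down from tens of
kilobases so the default genome stays desk-sized, preserving the fold),
~1% SNPs, short 1–6 bp indels, and one planted 69 bp indel; dual-strand
piRNA libraries with configurable ping-pong fraction and 1U/10A biases
(the biased base is substituted with probability $f$, else drawn uniformly
from the other three bases, so $f$ is exactly recoverable by the
estimator); synthetic ncRNA contaminants (random sequences labelled as
rRNA/tRNA/snRNA/miRNA — deliberately not real sequences); hybrid libraries
with a configurable minor-allele fraction (0 emulates crosses without
maternal piRNA deposition); and ChIP treat/input libraries with fold
enrichment over target regions.

Because the TE insertion exists in one haplotype only, the TE-bearing
cluster span has *unequal* allele-informative recall between haplotypes,
which would bias allele percentages; the generator therefore also emits a
structurally symmetric homologous span (the gene body, SNPs only) on which
allele accounting is unbiased — the analogue of restricting real analyses
to comparably mappable regions.

The simulators do **not** model base-call errors by default (the
perfect-match allele filter makes the error-free case the reference
condition; an error flag exists for sensitivity studies), quality scores,
ligation or amplification biases, transcription-coupled read clustering
within a locus, or long-read data. Passing tests therefore demonstrate
algorithmic correctness and statistical calibration under these idealised
conditions, not robustness to every artefact of real libraries.

## Validation problem sizes

The test suite validates each statistic against an independent oracle
(all-pairs enumeration for ping-pong, byte-matrix sliding comparison for
alignment, k-mer tabulation for mappability, exhaustive label permutation
for Mann–Whitney) on toy genomes of 3–5 kb with tens of reads, and runs
calibration studies at the package's study conditions: 100 null seeds for
the ping-pong z-score (|z₁₀| < 3 in ≥ 95%), 20 signal seeds
(z₁₀ > 5 in all), bias recovery at n = 10⁴ within 3σ binomial,
minor-allele recovery at 2.7%/5.4% with ≥ 10⁴ informative reads, exact
69/5403 bp structural recovery over 20 genome-pair seeds, and a
200-seed null false-positive study of the enrichment caller. The
acceptance script (`scripts/acceptance.R`) re-runs the study-condition
analyses end to end and records the resulting numbers.

## Known limitations

* The exhaustive aligner is quadratic in genome size × read count; beyond
  ~10 Mb use an external aligner and ingest SAM/BAM.
* The locus diff reports anchor-free regions (long satellite arrays) only
  as length differences, and indel positions can shift by a base in locally
  repetitive flanks.
* The Poisson bin caller is a prefilter, not a peak caller; its regions
  should not be interpreted as a peak set.
* Transcript-level piRNA mapping treats the transcript set like a genome
  (unique-within-set rule); isoform-aware assignment is out of scope.
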