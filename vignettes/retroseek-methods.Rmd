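---
title: "Methods: retroduplication discovery and its downstream statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: retroduplication discovery and its downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(retroseek)
```

# The problem

A retroduplication (retrocopy) arises when a spliced mRNA is reverse
transcribed and reinserted into the genome, typically by the LINE-1
machinery. The new copy lacks introns, often carries a poly-A tail and
short target-site duplications (TSDs), and lands far from its parent gene.
A retrocopy that is present in an individual but absent from the reference
genome leaves two diagnostic read signatures:

1. **Exon-exon junction reads.** Exome reads from the retrocopy that cross
   a splice boundary cannot map to the (intron-containing) reference, but
   map cleanly onto a sequence built by joining the two exon flanks.
2. **Discordant read pairs.** Whole-genome pairs with one read inside the
   parent gene (cross-mapped from the retrocopy) and its mate at the distant
   insertion site.

`retroseek` implements both detectors, the decoy-library false-discovery
control that makes the first one trustworthy, and the population-genetic,
association and enrichment statistics that consume the resulting callset.

# Junction libraries and the calling rule

For every protein-coding gene, the **true junction library** joins the last
`flank` (default 100) bases of an upstream exon to the first `flank` bases
of a downstream exon, for *all* ordered exon pairs in transcription order,
not only adjacent ones. Retrocopies are frequently 5'-truncated and may
omit exons, and ordering — not adjacency — is what the biology fixes; this
is a deliberate design choice, flagged for sensitivity analysis, since a
per-transcript adjacent-only library is also defensible. Exons shorter than
`flank` contribute their full length. Junctions with identical sequences
(duplicate exon structures) are deduplicated, keeping the first id.

Each read realigned to a junction is scored by `d1` and `d2`, the aligned
bases on either side of the junction offset (soft-clipped and inserted
bases excluded), and the mismatch rate `r`. A read supports a junction iff
`min(d1, d2) >= d` and `r <= r_max`, both boundaries inclusive. A gene is
called in a sample iff it has **two non-overlapping supporting junctions**
and **one junction with two or more distinct reads**. "Non-overlapping" is
implemented as: all four flank segments of the two junctions are genomically
disjoint. This subsumes "sharing no exon segment" and naturally handles the
two flanks of one exon: junctions (e1,e2) and (e2,e3) are compatible when
exon 2 is at least `2*flank` long, because they use opposite ends of it.

## Decoy libraries and parameter tuning

Five **decoy libraries** are built from exons shifted inward by
e ∈ {1, 2, 3, 6, 12} bases on both sides. No genuine read spans a decoy
junction cleanly, so any decoy call is a false positive. The calling
parameters are tuned by grid search — `d` over 1..15, `r_max` over 0 to
0.05 in steps of 0.005 — keeping only grid points at which *every* decoy
library is silent in *every* sample, and among those maximizing the number
of true-library calls. Ties go to the strictest point (largest `d`, then
smallest `r_max`), matching the principle of moving toward more restrictive
criteria whenever the decoys allow it. The `r` step of 0.005 is the
coarsest grid that distinguishes integer mismatch counts on a 76 bp read.

## The zero-decoy FDR model

After tuning, zero false calls are observed in all `n` samples. Modelling
the per-sample false-call count as Poisson(λ), the probability of that
observation is `exp(-λ)^n`; setting it to `1 - confidence` gives
`λ = -log(1 - confidence) / n`. At `n = 2533` and 95% confidence this is
1.2×10⁻³ per sample, i.e. `-log(0.05) ≈ 3` projected false calls overall;
at 99% confidence the projection is `-log(0.01) ≈ 4.6`, which over 503
called parent genes bounds the gene-level FDR below 2%. The package
implements exactly this closed form.

## The built-in matcher

The real pipeline realigns unmapped reads with an external aligner; this
package ships a seed-and-extend matcher (`align_to_junctions`) so that the
whole pipeline is hermetic. It performs end-to-end, gap-free alignment with
up to `floor(0.05 * L)` substitutions on both strands: the read is cut into
`max_mismatch + 1` non-overlapping seeds, so wherever the read fits within
budget, at least one seed matches exactly; candidates are verified
literally. Reads overhanging a junction sequence (possible only when an
exon is shorter than the read) are not matched — the synthetic generator
keeps exons longer than the read so this limitation is inert in tests.

# Insertion sites from discordant pairs

Discordant pairs (`mapq >= 15` on both mates, mate on another chromosome or
at least 1 kb from the gene) are collected only around parent genes already
called from junction evidence, pooled per population. Distal-read 5'
positions are clustered per side — left-side support reads on the + strand
pointing toward the site, right-side on the − strand — by average-linkage
agglomeration with a 500 bp cutoff (base R `hclust`/`cutree`; a from-scratch
agglomeration oracle in the tests confirms equality for n ≤ 12).

The cutoff is motivated by the expected distance between two reads
supporting the same insertion point. Under uniform fragment placement the
5' offset of a supporting read from the point spans `[-(IS-RL), +(IS-RL)]`
for insert size IS and read length RL, so the expected absolute difference
of two such offsets is `(2(IS-RL)+1)/3` — about 134 bp at IS = 300,
RL = 100, comfortably below 500 bp for all realistic geometries, with
headroom for insert-size spread and TSDs. A Monte-Carlo oracle over this
uniform model agrees to within 0.01%.

A two-sided call needs two or more reads on *both* sides; the nearest
compatible left/right clusters (inner edges within the cutoff, overlap
allowed — TSDs make clusters overlap) are paired greedily, nearest first.
Unpaired clusters with four or more reads and nothing on the other side
become single-sided calls — the signature of a co-inserted L1 long enough
that opposite-flank mates fall inside the repeat and cannot be placed.
Calls are merged across populations when gene and orientation agree and the
intervals overlap (two-sided) or lie within 500 bp (single-sided);
alternative loci are excluded.

# Population genetics

The carrier-frequency matrix holds, per parent gene and population, the
fraction of individuals carrying a retroduplication of that gene. On it:

* **Fixation index.** `F_ST = [p(1-p) - Σ c_i p_i (1-p_i)] / [p(1-p)]`
  over the five superpopulations, with `c_i` the relative superpopulation
  sizes and `p = Σ c_i p_i`; concavity of `p(1-p)` keeps it in [0, 1], and
  it is defined as 0 when `p` is 0 or 1 (no variation, no differentiation).
  Significance comes from shuffling individual labels across the whole
  cohort (population sizes preserved — the spec's wording admits within- or
  whole-cohort shuffling; whole-cohort is adopted as the stronger null),
  with the conservative `(r+1)/(n+1)` empirical p-value and
  Benjamini-Hochberg adjustment across genes.
* **Population trees.** Manhattan distance between population columns,
  average-linkage clustering. Distances are snapped to 12 significant
  digits so genuinely tied distances stay tied regardless of gene row
  order (floating-point summation order must not pick the topology).
  Cluster support is the ordinary bootstrap probability (BP) over gene-row
  resampling, and the approximately unbiased (AU) value from multiscale
  resampling: replicate sizes `ceiling(ρM)` for ten ρ in [0.5, 1.4],
  `z(ρ) = Φ⁻¹(1-BP(ρ))` fit to `v√ρ + c/√ρ` by weighted least squares
  (weights `n·φ(z)²/(BP(1-BP))`), `AU = 1 - Φ(v - c)`. Clusters with
  degenerate BP (0 or 1) at more than half the scales are reported at their
  BP value with a warning, since the fit is then unidentified.

# Expression association

Within one population (to avoid stratification confounding): a two-sided
Wilcoxon rank-sum test per parent gene between carriers and non-carriers
(exact enumeration when both groups have ≤ 10 members and no ties — the
boundary chosen so small fixtures are exactly reproducible), BH adjustment,
and Fisher's combined test `X² = -2Σ log p` on the unadjusted p-values as
an omnibus. Fisher's method assumes independence and is applied without
correction — a documented limitation, matching its use upstream of this
package. A signed-rank re-test pairs per-gene carrier/non-carrier medians.
The expression-rank analysis asks whether parent genes are highly expressed
among all genes: per-gene `p = #{median_g ≥ median_parent} / (G + 1)`
(the count includes the parent, so the maximum among G = 999 genes scores
exactly 1/1000), Fisher-combined. "Median" is used throughout where the
source material says "medium", the only sensible reading.

# Genomic-feature enrichment

Sites are widened to a fixed width (500 bp for feature tracks, 1000 bp for
genomic elements) about their midpoints, then shuffled on their own
chromosomes — lengths preserved, assembly gaps excluded by rejection
sampling, chromosome-end overhang prevented by shrinking the placement
interval rather than clipping. The observed statistic (partial-overlap
element count, base overlap, or sites-in-region count) is compared with the
null mean; enrichment is the log2 fold change, significance the smaller
empirical tail with the `(r+1)/(n+1)` floor, Bonferroni-corrected across
the tracks of one invocation. Aggregation profiles tile 200 bp bins around
site midpoints, smooth with a centered running mean of 10 bins (partial
windows at the edges), and normalize by the mean of the outermost 20 bins
per side, floored at a configurable ε to guard sparse tracks.
Retroduplication deletions are reported where an annotated processed
pseudogene covers at least 50% of a deletion call.

# SNP-genotyping erosion

A retrocopy carrying an alternative allele corrupts genotyping in its
parent gene: its reads cross-map onto the parent locus, shifting the allele
fraction (e.g. to 1/3 for an RR individual with one alt retrocopy
chromosome). The module draws pileups from the pooled chromosome mixture
(all retrocopy reads cross-map by default — the worst case; a mappability
fraction relaxes it), calls genotypes by maximum binomial likelihood with
alt-read probabilities {error, 1/2, 1-error} under a uniform prior (chosen
to isolate the likelihood effect), and reports miscall rate and mean call
quality across a depth grid. The qualitative claim this module exists to
check — deeper sequencing makes the contaminated call more confidently
wrong — is exactly what the simulation shows; the underlying published
curves come from an undocumented model, so this one is declared, not
inferred.

# The synthetic-data generator

Everything above is exercised on synthetic data emulating the study
conditions: exome reads at 65.7× and 76 bp, whole-genome pairs at 7.4× and
100 bp, 26 populations in 5 superpopulations. The toy scale is 2
chromosomes × 1 Mb with 30 genes of 4-8 exons (150-300 bp exons, so most
adjacent junction pairs are disjoint and events are callable) and 10
individuals per population; this runs the full junction stage in a few
minutes on one CPU. Insert sizes are truncated-normal, mean 300 sd 50,
floored at twice the read length. Carrier frequencies default to 0.05-0.3
per planted gene — high enough that a 260-individual cohort yields hundreds
of carrier events to measure recovery on, while the `"spectrum"` design
offers a rare-allele frequency profile for statistics that need realism.
5'-truncation keeps at least four exons so every planted event retains two
disjoint junctions; events that cannot be called in principle would only
mask genuine misses in the recovery metric.

Reads are emitted as truth-consistent alignments directly (hermetic tests;
a FASTQ escape hatch is easy to add, and the SAM writer/reader pair covers
the file boundary). The generator does **not** emulate the human repeat
landscape, GC-biased coverage, indel errors, chimeric fragments, or
reference errors — so passing tests demonstrate the correctness of the
algorithms under their stated model, not robustness to every artifact of
real data. Conversely the decoy mechanism, the clustering geometry, the
permutation nulls and the erosion model are exercised end-to-end exactly as
they would run on real inputs.

# Numerical and design choices

* All intervals inside the package are Bioconductor `GRanges` (1-based,
  closed) — the host language's single canonical convention; BED/GFF/SAM
  conversions happen at the I/O boundary via `rtracklayer`/`Rsamtools`.
* Empirical p-values always use the `(r+1)/(n+1)` floor; permutation and
  bootstrap streams are seeded per analysis from one caller-supplied seed.
* The tuning tie-break (largest `d`, then smallest `r_max`) makes the
  result independent of sample order; the call counter is deterministic.
* Degenerate inputs: genes with fewer than two exons contribute no
  junctions; shifted decoy exons of non-positive length are dropped; empty
  position sets cluster to nothing; `F_ST` of a monomorphic gene is 0;
  zero-variance expression genes are skipped with a log entry; empty
  signal tracks yield an all-zero profile with guarded normalization.
* The published per-sample rate printed for the 99% confidence level
  (2.7×10⁻³) does not follow from the stated formula, which gives
  1.8×10⁻³; the package implements the formula. The 95%-level numbers
  match it exactly.

# Problem sizes used in the shipped checks

The test-suite and the acceptance script use: the default 260-individual
cohort (~340 eligible planted events) for recovery and decoy silence; 200
genes × 1,000 bootstraps for tree support; 500-1,000 label shuffles for
F_ST; 2×10⁵ Monte-Carlo draws for the support-distance oracle; 10,000
pileup replicates per depth for erosion. These sizes were chosen so each
property is measured with comfortable margin while the whole suite stays
pleasant to run on a laptop.
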