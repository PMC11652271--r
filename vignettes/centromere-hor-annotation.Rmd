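---
title: "Annotating centromeric higher-order repeats with centrosat"
author: "centrosat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating centromeric higher-order repeats with centrosat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centrosat)
```

## The problem

Human centromeres are built from alpha-satellite monomers: ~171-bp repeat
units that within one centromere share roughly 50--90% sequence identity.
Distinct monomers are arranged into higher-order repeat (HOR) units — e.g.
a run of monomers 1-2-3-4-5 — and these HOR units repeat in tandem with
95--100% identity over megabases. Because the HOR unit, not the monomer, is
the unit of homogenization, annotating centromeres means (i) finding the
alpha-satellite sequence, (ii) decoding it into a monomer-identifier
sequence, and (iii) mining that identifier sequence for (possibly nested)
tandem structure. `centrosat` implements this pipeline for both long reads
and assemblies, plus the cross-sample bookkeeping needed to compare HOR
content between individuals and populations, and a simulator that plants
known structure so every stage can be tested by parameter recovery.

## Pipeline overview

Two front ends feed one annotation core:

* **Reads**: `kmerFeatures()` builds canonical 5-mer frequencies
  (strand-collapsed, so exactly $4^5/2 = 512$ features, each count divided
  by read length), `trainTwoStage()` fits a two-step PCA + linear-SVM
  classifier (alpha vs non-alpha, then chromosome), and `classifyReads()`
  labels incoming reads. Training reads are simulated from an annotated
  reference by `simulateTrainingReads()`: 10--25 kb fragments of the
  satellite arrays, equal counts per chromosome, half reverse-complemented,
  ten replicate rounds, and an equal number of negatives sampled outside
  the satellite regions.
* **Assemblies**: `scanTemplateHits()` locates template-sized
  alpha-satellite windows on both strands (seed-and-extend; identity floor
  0.70 by default, low enough to admit 50--90%-divergent monomers and high
  enough to reject random DNA), `mergeHits()` merges hits separated by less
  than 5 kb and discards merged regions under 10 kb, and
  `buildSatelliteArray()` concatenates the surviving regions into one
  plus-oriented array per chromosome, recording junction ("break") offsets
  and an invertible mapping back to assembly coordinates.

The annotation core is `decomposeBlocks()` +
`labelMonomers()` + `htrmMine()`, wrapped by `annotateSequence()`.

## Block decomposition and monomer labeling

`decomposeBlocks()` tiles a sequence into consecutive template-sized blocks
by dynamic programming: every block is scored as a full global alignment of
the alpha-satellite template and the block boundaries minimize the total
edit cost. This is the StringDecomposer contract, implemented internally
(in C++) so the pipeline is self-contained at desk scale; block lengths
stay near 171 bp and drift only with indels.

Each block is then compared with every monomer template using the identity

$$\mathrm{identity}(s_\mathrm{block}, s_\mathrm{monomer}) =
  1 - \frac{\mathrm{ed}(s_\mathrm{block}, s_\mathrm{monomer})}
           {\max(l_\mathrm{block}, l_\mathrm{monomer})}$$

where $\mathrm{ed}$ is the unit-cost Levenshtein distance. The block takes
the arg-max template id (ties break to the lowest id); a best identity
below 0.90 yields the token `"unknown"` — such blocks are often
transposable elements or other interjected sequence. Note the convention:
identity is the *normalized distance subtracted from one*, so that equal
sequences score 1 and "below 90%" reads naturally; this is the only reading
under which taking the largest identity and a 90% floor is coherent.

Monomer templates can be supplied (any FASTA) or inferred from an array by
`inferMonomerTemplates()`: blocks are clustered on an identity-weighted
similarity graph (edges at $\ge$ 0.9 identity by default) with Louvain
modularity maximization, and each community is represented by its member
with the smallest summed edit distance to the rest. Representatives are
numbered 1..k by first appearance along the array, matching the
monomer-pattern notation 1-2-3-....

## Hierarchical tandem repeat mining

`htrmMine()` turns a monomer token sequence into HOR patterns by recursive
run compression:

1. Find tandem runs (a unit of length $u$ repeating $\ge 2$ times),
   shortest unit first. `"unknown"` tokens never match anything, so they
   terminate runs but do not reset tallies.
2. Among overlapping candidates prefer the run covering the most tokens,
   then the leftmost. Compress each selected run into a single symbol and
   re-mine the reduced sequence until no run remains.

Two choices matter and are deliberate:

* **Symbols match modulo repeat count, by structure.** A compressed symbol
  carries the subpattern it compresses; two symbols match during run
  detection when their structures agree, regardless of count. This is what
  lets a 10-mor `[(1-2)x3-5-6-4-3]` and a 12-mor `[(1-2)x4-5-6-4-3]` be
  annotated as occurrences of the *same* 6-monomer HOR with different
  expanded monomer lengths — the locally nested HOR (LN-HOR)
  representation. Matching on flattened patterns instead would fuse
  adjacent differently-nested blocks into spurious outer runs.
* **Every compression level contributes a pattern.** The nested dimer in
  the example above is itself a HOR (a local expansion of monomers 1-2)
  with its own repeat tally; its parent counts one unit per occurrence.

Patterns are grouped under `canonicalizePattern()`: the lexicographically
minimal tuple over all rotations of the unit and of its reversal, so
1-2-3-4, 4-1-2-3, 3-4-1-2, 2-3-4-1 and 4-3-2-1 are one HOR class. Naming
follows `R<rank>L<length>` within a sample and `M<rank>L<length>` after
cross-sample aggregation (`nameHors()`, `aggregateHors()`), rank being
repeat count in decreasing order; rank ties break by smaller unit length,
then canonical tuple order — an artifact convention, since ties are not
resolved by the published naming scheme.

The annotation reports non-overlapping top-level unit occurrences; every
token is thereby in a unit, unknown, or unassigned, and the three coverage
fractions returned by `tokenCoverage()` sum to one.

## Quantification and genotypes

For sample $k$ with sequencing coverage $c_k$, `quantifySample()` computes
the estimated HOR array size $s_{i,k} = l_{i,k}/c_k$ (total bases of
HOR-carrying reads over coverage) and the n-number $n_{j,k} = r_{j,k}/c_k$
(HOR unit count over coverage); both scale exactly as $1/c_k$. Coverage is
a required per-sample input. `filterRareHors()` implements the rare-HOR
rule exactly as stated: HOR $j$ is excluded iff in *every* sample its
n-number stays strictly below 10% of the summed n-numbers of its
chromosome's HORs in that sample. Under the strict inequality a HOR sitting
at exactly 10% everywhere is retained.

`callVhors()` computes mean fold changes $mf_{j,k} = n_{j,k}/
\overline{n_j}$ (mean 1 by construction, asserted to $10^{-9}$ in the
tests) and flags a HOR variable (v-HOR) when the standard deviation of its
fold changes exceeds 0.5. Whether that is the population ($\div n$) or
sample ($\div n-1$) standard deviation is unstated in the published rule;
the package defaults to population and records the choice in its output —
for two samples with n-numbers (1, 3) the population convention gives
exactly 0.5 (not variable under the strict threshold) while the sample
convention gives 0.707 (variable).

`clusterGenotypes()` formalizes "samples group into two or three clusters":
Ward hierarchical clustering of z-scored n-number vectors, the cluster
count chosen between 2 and 3 by mean silhouette width. With three clusters
the heterozygote logic is applied: a cluster is called AB when for every
HOR its mean n-number lies within 20% (relative, configurable) of the
pairwise mean of the other two clusters' means; the remaining clusters are
AA/BB. Cluster labels C0, C1, ... are assigned by decreasing overall mean
n-number, which makes memberships invariant to sample order.
`comparePopulations()` wraps the two tests used for population contrasts —
a two-sided Wilcoxon rank sum test on n-numbers (normal approximation with
continuity correction, so tied-heavy data are handled uniformly) and a
one-sided binomial test of a genotype count against a null proportion —
and `alleleFrequency()` does the diploid allele arithmetic (homozygotes
count twice, heterozygotes once).

## Landscape analyses

`clusterUnitsCrossLandscape()` compares the same HOR across array
"landscapes": all unit DNA sequences are encoded as 0--1 difference
vectors against their consensus and k-means-clustered. The consensus is
the majority base at every position of a center-star alignment seeded on
the medoid; each unit is then globally aligned to the consensus and scored
0/1 per consensus position (deletions count as difference; insertions fall
between consensus columns and are not encoded — the vector length equals
the consensus length). "The smallest k that represents the difference
among landscapes" is operationalized as the smallest $k \in [2, 6]$ whose
cluster-landscape association (Cramér's V) exceeds a configurable
threshold (0.3 by default), both echoed in the output. All-identical units
are refused as degenerate. The published workflow used Kalign, needle and
k-means scripts; here the alignment steps are internal contracts
(center-star consensus, unit-cost global alignment) so the analysis runs
without external tools, and externally computed alignments can be
substituted upstream.

`reconstructAncestralHor()` reconstructs an ancestral HOR from outgroup
monomers (another chromosome of the same suprachromosomal family; e.g.
Chr19 monomers for SF1 targets like Chr5/Chr10, Chr17 for SF3 targets like
Chr11 — user-overridable). The outgroup monomers are grouped by cutting a
neighbor-joining tree of edit distances at its longest edges into the
stated number of groups (the group count comes from the family's ancestral
HOR and is a required parameter, since it is not tabulated per family);
group consensuses are the ancestral monomers; a joint tree of target and
ancestral monomers gives the correspondence as the nearest ancestral
monomer by tree (cophenetic) distance, with exact ties flagged rather than
silently assigned. The ancestral HOR is the concatenation of corresponding
ancestral monomers in target HOR order, and an identity matrix against
HOR-cluster consensuses summarizes their relationships. A distance-tree
contract replaces maximum-likelihood inference deliberately: at monomer
scale (171 bp, moderate divergence) the grouping and correspondence are
distance-driven, and the package stays dependency-free.

`recentExpansionTrack()` reports, for a sliding window of 10 HOR units
(slide 1), the number of unit pairs whose DNA matches exactly — 10
identical units give $\binom{10}{2} = 45$. An alternative reading (units
having at least one exact twin) is available via `mode = "units"`.
`mpLengthDistribution()` summarizes per-unit expanded monomer lengths
(e.g. the 12/16/20-mor variants of a nested HOR) as a histogram, modal
peak, and per-sample ratio vectors suitable for k-means grouping of
samples.

## The simulator: what it emulates, and what it does not

`simSpec()`/`genMonomers()`/`genArray()`/`genReads()`/`genCohort()`
generate synthetic centromeres with planted truth. Defaults are the study
conditions the package is specified against: 171-bp monomers at a 0.70
pairwise cross-identity target (inside the 50--90% band), per-base unit
mutation rate 0.01 (unit-to-unit identity ~98%, inside the 95--100% band),
reads of 10--25 kb, and half of each read set reverse-complemented.
Monomers are derived from a hidden base consensus — also returned, as the
synthetic analog of the alpha-satellite template — with the per-monomer
substitution fraction $p$ solved from the expected pairwise difference
rate $2p(1-p) + \tfrac{2}{3}p^2$ so realized identities center on the
target. Mutations are substitutions by default (indels behind
`indelRate`), which keeps unit-interval truth exact while the indel mode
stresses the decomposer. Diploid cohorts assign each sample two haplotypes
from two allele arrays and count the HOR units fully contained in reads
sampled at half coverage per haplotype, so AB samples carry half the
allele-specific units of homozygotes by construction — the relation the
genotype caller must recover.

What the simulator does *not* emulate: sequencing error profiles (reads
are exact substrings), satellite-adjacent repeat families (negatives are
uniform random DNA), layered age gradients within arrays, and assembly
error. Passing recovery tests therefore demonstrates correctness of the
algorithms under the stated repeat structure, not robustness to every
artifact of real HiFi data.

## Numerical and scale choices

* Edit distance is plain unit-cost Levenshtein (no affine gaps); `N`
  compares literally (mismatching every other base). An early-abandon
  cutoff makes the many below-threshold comparisons cheap without
  changing any value within the bound.
* Coordinates are 1-based closed in memory (the Bioconductor convention
  used by every container here); BED files on disk are 0-based half-open.
* Test and example problem sizes are desk-scale by design: arrays of
  50--500 units, cohorts of 30 samples, three-chromosome classifier
  genomes with ~100 kb per chromosome. The recovery properties asserted —
  exact planted-pattern recovery at $\le 2\%$ token noise, $\ge 95\%$
  read-classification and genotype-assignment accuracy — are the ones the
  method needs at scale, checked where they can be recomputed in minutes.
* All generators and stochastic steps (SVM training folds, Louvain,
  k-means) sit behind explicit integer seeds; rerunning with the same
  seed reproduces outputs byte for byte.

## Known limitations

* The HTRM run-selection tie-break (maximal coverage, then leftmost) can
  segment transition zones between differently nested blocks at a shifted
  phase; the canonical pattern and counts are unaffected, but unit
  boundaries within such zones are one legal parse among several.
* `inferMonomerTemplates()` subsamples arrays to a quadratic-stage budget
  (400 blocks by default); extremely rare monomers may be missed on very
  long arrays unless the budget is raised.
* The heterozygote test assumes the two homozygous clusters are present;
  a cohort of only AB samples clusters as one group and is reported
  without a zygosity call.
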