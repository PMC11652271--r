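# centrosat

Annotation and population analysis of alpha-satellite higher-order repeats
(HORs) in human centromeres.

Human centromeres are megabase-scale arrays of ~171-bp **alpha-satellite
monomers** (50–90% identity to each other) organized into **higher-order
repeat units** — ordered runs of distinct monomers, written 1-2-3-4-5 —
that repeat in tandem at 95–100% identity. The HOR unit, not the monomer,
is what homogenizes and varies between people, so comparing centromeres
means decoding sequence into monomer identifiers and mining that identifier
sequence for (possibly nested) tandem structure. `centrosat` is for
researchers doing exactly that on long reads (HiFi-like, 10–25 kb) and
chromosome-level assemblies: it extracts and classifies alpha-satellite
reads, builds per-chromosome satellite arrays, decomposes them into
monomers, mines HORs hierarchically, quantifies HOR content across samples
and populations, and analyzes HOR landscapes across assemblies. A synthetic
centromere simulator with planted ground truth makes every stage testable
by parameter recovery.

## The method in brief

* **Read classification** — canonical 5-mer frequencies (strand-collapsed:
  4^5/2 = 512 features, counts divided by read length), PCA retaining
  components with > 95% explained variance, and a linear SVM; applied in
  two steps (alpha vs non-alpha, then chromosome of origin).
* **Array building** — template hits on both strands (seed-and-extend,
  identity floor 0.70), hits < 5 kb apart merged, merged regions < 10 kb
  discarded, survivors concatenated into one plus-oriented array per
  chromosome with junction ("break") bookkeeping.
* **Monomer decoding** — a dynamic-programming tiling of the sequence into
  template-sized blocks minimizing total edit cost (the StringDecomposer
  contract), then per-block identity
  `1 − ed(s_block, s_monomer) / max(l_block, l_monomer)` against every
  monomer template; arg-max labels, `unknown` below 0.90.
* **HOR mining (HTRM)** — recursive compression of tandem runs, shortest
  unit first; compressed symbols match modulo repeat count so 10-mor and
  12-mor variants of one nested HOR group together; patterns are
  canonicalized over rotations and reversals (1-2-3-4 ≡ 4-1-2-3 ≡ 4-3-2-1)
  and named `R<rank>L<len>` per sample / `M<rank>L<len>` aggregated.
* **Quantification** — estimated array size `s = l/c` and n-number
  `n = r/c` (coverage-normalized counts), the 10%-of-chromosome rare-HOR
  filter, mean-fold-change dispersion with the std > 0.5 v-HOR rule,
  genotype clustering (Ward + silhouette, heterozygote = pairwise-mean
  test), Wilcoxon and one-sided binomial population contrasts.
* **Landscapes** — 0–1 difference vectors of HOR units against a consensus,
  k-means across landscapes; ancestral HOR reconstruction from outgroup
  monomers via neighbor-joining groups; a sliding-window exact-match
  "recent expansion" track; monomer-length (12/16/20-mor) distributions.

## Worked example

```r
library(centrosat)

# simulate a centromere: 5 monomers, HOR pattern 1-2-3-4-5, 200 units
spec <- simSpec(monomerCount = 5, pattern = 1:5, nUnits = 200,
                mutationRate = 0.01, seed = 42)
gm  <- genMonomers(spec)
arr <- genArray(spec, gm$monomers)

# decompose the array into blocks, label monomers, mine HORs
res <- annotateSequence(arr$sequence, gm$template, gm$monomers,
                        source = "chr5_array")
res$monomers
#> MonomerSequence from chr5_array | 1000 tokens ( 5 distinct monomers, 0 unknown )
#>  head: 1-2-3-4-5-1-2-3-4-5-1-2 ...

patterns <- nameHors(horPatterns(res$annotation), chromPrefix = "5")
patterns
#>   canonical L nested count rank   name
#> 1 1-2-3-4-5 5          200    1 5_R1L5

tokenCoverage(res$annotation, res$monomers)
#>     inUnit    unknown unassigned
#>          1          0          0

# n-number of the top HOR at 20x coverage
quantifySample(c(`5_R1L5` = patterns$count[1]), coverage = 20)$n
#> 5_R1L5
#>     10
```

The 1,026,000-bp simulated array decomposes into 1000 blocks, every block
is labeled with its planted monomer, and mining recovers the planted
5-monomer HOR exactly: one pattern, 200 units, full token coverage. At 20×
coverage its n-number (count over coverage) is 10.

A command-line wrapper over the same functions is installed at
`inst/scripts/centrosat.R` (subcommands `simulate`, `build-array`,
`infer-monomers`, `annotate`, `train-classifier`, `classify`).

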