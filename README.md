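# gbsqtl

Linkage-map construction and QTL mapping for full-sib families from two
outbred diploid parents (CP populations), starting from
genotyping-by-sequencing (GbS) allele read counts.

## The problem

In a cross between two heterozygous parents, markers segregate in
parent-specific patterns — 1:1 from either parent alone (ABxAA, AAxAB),
1:2:1 from both (ABxAB) — and GbS adds two complications: genotypes must
be called from noisy per-allele read counts, and *null* alleles (O, an
allele yielding no reads) create loci where AO reads like AA and OO reads
like a missing value.  When one parent contributes far more informative
markers than the other (62% vs 20% on the most extreme group of the
raspberry reference cross this package emulates), standard interval
mapping software computes QTL genotype probabilities from a handful of
neighbouring markers and produces irregular LOD profiles with ambiguous
peaks.

`gbsqtl` implements the full analysis path:

- **Genotype calling**: read-support filters (mean depth ≥ 10/individual,
  quality ≥ 10,000, heterozygosity < 90%), then per-SNP classification by
  an errors-in-both-variables ("functional regression") line fit on
  square-root count axes, with fit assessment (reject monomorphic,
  R² < 50%, parent-incompatible).
- **Chromosome allocation** by marker regression (one-way ANOVA of the
  major-allele proportion P_A on anchor-map marker classes; allocate when
  exactly one group has R² > 25%).
- **Null alleles**: ABxAO loci (offspring 2:1:1) split into a 1:1 "n1"
  and a dominant 3:1 "n3" derived marker; AOxBO loci (parents different
  homozygotes, offspring 1:1:1 + excess missing) recoded as four-class
  "n4" markers with OO imputed for reliably scored offspring.
- **Two-point linkage**: EM maximum-likelihood recombination fractions
  and linkage LODs over all phases, for every informative pair type.
- **Ordering**: weighted (LOD or LOD²) least-squares metric MDS in 2 or 3
  dimensions with outlier removal, a principal curve for the linear
  order, and mean nearest-neighbour fit (NNfit) to pick the best order.
- **Map checking**: a hidden Markov model over the four offspring
  inheritance states AC, AD, BC, BD reconstructs each offspring's
  chromosome configuration; recombination counts (HMM_mean) drive greedy
  local order improvement (marker exclusion diagnostics, adjacent swaps,
  triplet reorderings).
- **QTL mapping**: HMM genotype probabilities on a 1 cM grid,
  LOD = (n/2) log10(RSS0/RSS1) from the class-means regression,
  %variance explained, one- and two-LOD support intervals, key-parent
  calls from parental contrasts, and genome-wide thresholds from 200
  trait permutations.
- **Ripening traits**: principal coordinates of city-block distances
  between 1–7 ripening-score profiles, ANOVA-based axis selection, and
  interpolated times to reach stages 2–6.
- **Synthetic crosses**: `simulate_cross()` generates read-count data
  with known inheritance, marker composition, null alleles and QTLs, so
  the whole pipeline is testable end to end.

## Worked example

Simulate the imbalanced-map study (an LG2-like 107.1 cM group, 62/20/18
marker composition, n = 184, complete marker data, one additive QTL of
~15% variance at 67 cM), then scan:

```r
library(gbsqtl)

cfg   <- qtl_study_config("imbalanced", seed = 3)
cross <- simulate_cross(cfg)

mk    <- cross$markers
model <- build_inheritance_model(mk[c("marker", "pos")],
                                 setNames(mk$classmap, mk$marker),
                                 eps = 0.002)
gp    <- genotype_probs(model, cross$true_calls, step = 1)
trait <- setNames(cross$trait$trait, cross$trait$individual)
scan  <- scan_qtl(gp, trait, lg = "LG2")
scan
#> <qtl_scan> LG2: peak LOD 9.95 at 70 cM (22% variance, key parent Latham)
#>   1-LOD support [65, 74] cM; 2-LOD [65, 76] cM; nearest marker s2_136
```

The scan finds the planted QTL within a few cM of 67 cM, estimates its
size, brackets it with support intervals, and attributes the effect to
the correct parent.  `tidy(scan)` returns the per-position profile
(position, LOD, %var, the four class means AC/AD/BC/BD and their SEs),
`glance(scan)` the one-row peak summary, and `autoplot(scan)` the LOD
profile.  `run_pipeline()` chains every stage (filter → allocate → call →
null-recode → two-point → MDS → HMM check → scan) from a raw count table
and an anchor map.

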