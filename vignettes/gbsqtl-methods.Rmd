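---
title: "Methods: linkage mapping and QTL analysis for outbred F1 crosses from GbS read counts"
author: "gbsqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linkage mapping and QTL analysis for outbred F1 crosses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A full-sib family from two outbred diploid parents (a CP population, in the
raspberry reference cross the cultivars Glen Moy and Latham) segregates in
parent-specific patterns: a marker can be heterozygous in the first parent
only (ABxAA, offspring 1:1), in the second only (AAxAB), in both (ABxAB,
1:2:1), or involve a *null* allele O that produces no sequencing reads.
Genotyping by sequencing (GbS) yields, per SNP and individual, a pair of
allele read counts rather than a genotype, and the two parents typically
contribute very unequal numbers of informative markers.  This package
implements the complete analysis path from read counts to QTL calls:

1. read-support filtering and genotype calling (`filter_snps()`,
   `call_genotypes()`);
2. allocation of SNPs to chromosomes against an anchor map
   (`allocate_snps()`);
3. detection and recoding of null-allele configurations
   (`detect_abxao()`, `split_abxao()`, `detect_aoxbo()`, `impute_oo()`);
4. two-point linkage (`pairwise_linkage()`), marker ordering by weighted
   MDS with a principal curve (`order_markers()`), and map checking with a
   hidden Markov model (`improve_order()`);
5. HMM-based QTL interval mapping with permutation thresholds
   (`genotype_probs()`, `scan_qtl()`, `permutation_threshold()`);
6. construction of QTL-ready traits from ordinal ripening-score profiles
   (`pco_scores()`, `select_axes()`, `interpolate_stage_times()`).

A synthetic-cross generator (`simulate_cross()`) emulates the statistical
structure of the reference population so that every stage can be exercised
and validated without access to the original data.

## Genotype calling from read counts

Individuals at one SNP are points $(\sqrt{x}, \sqrt{y})$ on square-root
major/minor count axes.  Homozygotes hug the horizontal or vertical axis;
heterozygotes form an inclined line whose spread along the line comes from
library-size variation between individuals.  The inclined line is fitted by
*functional regression* — an errors-in-both-variables (orthogonal) fit with
unit error-variance ratio, appropriate because both counts carry sampling
noise — through a presumed-heterozygote seed set (minor-allele fraction in
[0.15, 0.85], at least 4 reads), iterating fit → classify → refit to
convergence (at most 10 iterations, slope tolerance $10^{-6}$).  Each
individual is then called AA, BB or AB by the nearest of the horizontal
axis, vertical axis and inclined line (perpendicular distance); both counts
$\le 1$ is missing; distance ties resolve to AB, the conservative choice
for linkage.

Pre-filtering keeps SNPs with a mean of 10 or more reads per individual
(total $\ge 1840$ at $n = 184$), quality score $\ge 10{,}000$, and
provisional heterozygosity below 90% (provisional heterozygote = both
alleles at $\ge 2$ reads, among individuals with $\ge 2$ reads total; the
rule needs a pre-calling definition and this is the natural one).
Classifications are rejected when monomorphic, when the regression of the
per-individual major-allele proportion $P_A$ on the call classes explains
less than 50% of the variance, or when clearly incompatible with the
parental calls.  A class must exceed max(3, 5% of called offspring) to
count as segregating: every genuine class in the supported configurations
is $\ge 25\%$ of offspring, while miscall noise sits far below 5%.

## Allocation to chromosomes

For each SNP, $P_A$ is tested against every anchor-map marker by one-way
ANOVA (marker regression, the parametric analogue of the Kruskal–Wallis
interval test).  The SNP joins a linkage group when exactly one group shows
$R^2 > 25$; ties across groups give "multi-LG", otherwise the SNP stays
unallocated.  $R^2 = 25$ exactly does not allocate (the rule is strict).
Anchors need at least 50 joint non-missing observations — an added floor
against spurious $R^2$ from sparse overlap.  Offspring only are used; the
two parents are not part of the segregating sample.

## Null alleles

An ABxAO locus looks heterozygous in one parent and homozygous in the
other, yet shows three offspring classes near 2:1:1 (underlying genotypes
AA:AO:AB:BO are 1:1:1:1).  Detection is a chi-square goodness-of-fit test
that must *not* reject at $\alpha = 0.001$ (the published ratios are only
approximate, so a conservative level keeps real loci).  The locus is split
into two derived markers: "n1" scores presence of the heterozygous
parent's private allele (1:1) and "n3" dominant presence of the shared
allele (3:1), because AA and AO phenotypes cannot be told apart.

An AOxBO locus shows parents as *different* homozygotes with three
offspring classes near 1:1:1 plus excess missing values (the OO class
yields no reads).  Detection requires four pieces of evidence: the 1:1:1
fit, the parental phenotypes, each allele's read counts associating
($R^2 > 25$) with a *different* parent's anchor classes, and
above-median missingness.  Offspring whose overall missing rate is below
10% have their missing call imputed as OO; others stay missing (their
missingness is more plausibly technical).  The marker is then coded with
four classes like an ABxCD cross ("n4").

## Two-point linkage

Every marker is represented internally by its *class map*: the phenotype
class emitted by each of the four offspring inheritance states AC, AD, BC,
BD (first parent's homolog A/B times second parent's C/D).  This single
representation covers the plain types, the n1/n3 splits and the n4 coding,
so one EM routine serves all supported pairs.  For a pair, the likelihood
of the observed class pairs is maximized over the recombination fraction
$r$ by EM (start 0.25, tolerance $10^{-6}$, at most 200 iterations,
$\hat r$ clamped to $[10^{-6}, 0.4999]$), independently for the four
relative phase assignments; the best phase wins and
$\mathrm{LOD} = \log_{10} L(\hat r) / L(0.5)$.  Pairs heterozygous in
different single parents carry no recombination information and are
assigned LOD 0.  The EM is verified in the test suite against an
independent grid-search of the same likelihood.

Pre-ordering filters collapse duplicate call vectors, exclude markers with
more than 40 missing values in the first mapping round (45 or more in the
second, once null-recoded markers have been added), and drop markers with
extreme segregation distortion (chi-square against the type's expected
ratio, $p < 10^{-4}$).

## Marker ordering

Two-point distances (Haldane by default, $d = -50\ln(1-2r)$; Kosambi
optional — the reference analyses are JoinMap-based, whose convention is
Haldane) are embedded by weighted least-squares metric MDS: the stress
$\sum_{i<j} w_{ij} (\delta_{ij} - d_{ij}(X))^2$ is minimized by SMACOF
majorization (classical-scaling start on a shortest-path-completed matrix,
at most 300 iterations, relative stress change $10^{-8}$), with weights
LOD or LOD$^2$ and zero weight on uninformative pairs.  Markers whose mean
weighted residual exceeds 3 robust SDs (median + 3 MAD) are removed once
and the MDS rerun; if that severs the only bridge to a set of markers,
those markers are left unplaced too.  A cubic-smoothing-spline principal
curve (10 iterations, projection onto a dense polyline) turns the 2-d or
3-d configuration into a linear order; arc-length positions are rescaled
by a weighted regression through the origin of two-point distances on
arc-length separations.

Candidate orders (LOD vs LOD$^2$, 2-d vs 3-d) are compared by the mean
nearest-neighbour fit (NNfit): per marker, the absolute difference between
the observed two-point distance and the map separation to the nearest
informative neighbour on each side.  The order with minimal mean NNfit is
selected; ties break toward LOD$^2$ and 3 dimensions, the majority choice
in the reference analysis.  Stress itself is not comparable across
weightings, which is why NNfit is the criterion.  Maps are oriented to
agree with the anchor map by Spearman correlation.

## The inheritance HMM

The hidden state of an offspring at a locus is one of AC, AD, BC, BD.
Transitions between adjacent loci factorize into independent parental
switches with the interval's recombination fraction $r_k$ (sex-averaged,
from the map function and fitted positions); emissions give the state's
implied class with probability $1-\varepsilon$ and each other class of the
marker's alphabet with $\varepsilon/(c-1)$; missing observations are
uninformative.  $\varepsilon$ defaults to 0.01 — a typical GbS miscall
rate, configurable.  Phases along a group are resolved by a maximum
spanning tree (by LOD) over each parent's informative markers, propagating
homolog orientation from the first marker.  Forward–backward runs scaled
(no log-sum tricks needed), and both the likelihood and the Viterbi path
are validated against exhaustive enumeration over all $4^m$ paths in the
test suite.

Map checking counts Viterbi-inferred homolog switches (the $(m-1) \times
o$ recombination matrices, resolved to intervals, split by parent).
`HMM_mean` is the total divided by the number of offspring.  Order
improvement greedily applies the adjacent swap or triplet reordering that
most reduces the total recombination count, re-deriving interval distances
from the fitted positions, until no move helps; exclusion benefits per
marker are reported but never auto-applied.  Two numerical choices matter
here.  First, interval $r_k$ come from positions rather than raw adjacent
two-point estimates: at 2 cM spacing and $n = 184$ an adjacent pair has a
~15% chance of zero observed recombinants, collapsing $\hat r$ to 0 and
distorting the Viterbi costs.  Second, with $\varepsilon > 0$ the
recombination-count criterion can genuinely prefer reinterpreting a
terminal-marker crossover as a genotyping error after a local swap, so
even a correct order may admit a few count-reducing swaps — consistent
with the reference analysis, which reports a small number of local swaps
on its best maps.  The strict "true order is a local optimum" property
holds at $\varepsilon = 0$ and is tested there.

## QTL interval mapping

Pseudo-loci with uninformative emissions are inserted on a 1 cM grid and
forward–backward posteriors give each offspring's four genotype-class
probabilities at every position.  The trait is regressed on the four
probabilities (class-means parameterization, no separate intercept — the
probabilities sum to one), giving

$$\mathrm{LOD} = \frac{n}{2}\log_{10}\frac{RSS_0}{RSS_1}, \qquad
  \%\mathrm{var} = 100\,(1 - RSS_1/RSS_0),$$

with $RSS_0$ from the overall-mean model (the classical regression form of
interval mapping; %var is unadjusted).  Rank-deficient positions (under 2)
are skipped with a warning; partially rank-deficient fits keep the
estimable class means.  The peak is the leftmost maximum; one- and two-LOD
support intervals are the maximal contiguous grid runs within 1 (or 2) LOD
of the peak.  The key parent is decided by t-tests at $\alpha = 0.05$ on
the two parental contrasts, $(AC+AD)/2 - (BC+BD)/2$ for the first parent
and $(AC+BC)/2 - (AD+BD)/2$ for the second, using the full covariance of
the estimated means — with soft genotype probabilities the class-mean
estimates can be strongly correlated, and ignoring that misstates the
contrast variance.  Genome-wide significance uses 200 trait permutations:
the empirical 95th percentile of the per-permutation maximum LOD over all
linkage groups.

The neighbour-window comparator (`neighbor_window_probs()`) computes the
same posteriors from only the $k = 5$ markers nearest each grid position
(matching default interval-mapping software, which uses up to five
neighbouring markers in total).  On maps where most markers segregate from
one parent, such windows often contain no information about the other
parent, and the LOD profile becomes visibly irregular; the full HMM, which
propagates information along the whole chromosome, stays smooth.  Profile
roughness is quantified as the mean absolute second difference of the LOD
sequence.

## Ripening traits

Plot-level scores on the 1–7 developmental scale (1 = bud break, 2 = open
flowers, 3 = fruit set, 4 = green fruit, 5 = green/red, 6 = red, 7 =
over-ripe) are summarised two ways.  First, classical principal
coordinates of the city-block (L1) distance matrix between plot profiles;
axes are scaled eigenvectors ordered by eigenvalue, negative eigenvalues
(the L1 matrix need not be Euclidean) are reported and their axes dropped,
and each axis is oriented so that high values mean slower ripening
(negative correlation with the plot's mean score), making "high PCO1 =
longer ripening period" reproducible across runs.  Axes differing among
offspring genotypes by one-way ANOVA at $p < 0.001$ are kept, and genotype
means over replicate plots become trait values.  Second, the time to reach
each of stages 2–6 is linearly interpolated between the last date below
and the first date at-or-above the stage; a stage present at the first
scoring date gets that date, a stage never reached is missing, and
decreasing scores are cleaned by a running maximum.

## The synthetic-cross generator

`sim_config()` defaults define the emulated population: 184 offspring,
seven linkage groups with the published lengths (114.1, 107.1, 128.2,
91.5, 85.4, 88.6, 100.2 cM), and the imbalanced composition reported for
the most extreme group — 62% first-parent-only, 20% second-parent-only,
18% other, split 8% ABxAB, 7% ABxAO, 3% AOxBO (the within-"other" split
is not published; these proportions echo the published per-group class
tables).  The balanced counterpart (`sim_config_balanced()`) uses
28/28/44, split 24/14/6.  One hundred markers per group is the package's
default study size; the simulation-study configurations
(`qtl_study_config()`) use 200 markers so that five-marker windows span
about the same map interval as on the dense real maps.

Meioses are two-state Markov chains per parent along the map (inverse
Haldane switch probabilities, no interference, sex-averaged).  Read
depths are negative binomial (dispersion 5) with mean 30, scaled by a
per-individual lognormal library-size factor (sdlog 0.4).  The size
factors matter twice: real GbS libraries differ strongly in yield, and
that spread is precisely what elongates the heterozygote cluster along
the inclined line and makes the functional-regression fit identifiable —
with equal library sizes the heterozygote cloud is nearly isotropic and
the fitted line direction is unstable.  The magnitude reflects a
population from which failed low-yield libraries have already been
removed, as is routine.  Parents get a fixed size factor of 4 and no
dropout (they are pooled from several sequencing runs).  Genotypes emit
counts as a binomial split of the locus depth: heterozygotes at $p = 1/2$,
homozygotes all-but-errors at rate $\varepsilon = 0.01$; null alleles
contribute no reads, so AO runs at half depth and OO at zero (missing
downstream).  QTL effects add the class mean of the true inheritance
state at the QTL position plus Gaussian noise; `qtl_means_for_pvar()`
calibrates class means to a target variance fraction (the simulation
studies use 15%, the size of the largest published ripening-axis QTL).
Ripening profiles threshold a latent logistic progression whose midpoint
shifts with the QTL state, guaranteeing monotone scores.

What the generator does *not* emulate: crossover interference, sequence-
level artefacts (restriction-site dropout, alignment error, allele-specific
amplification bias), segregation distortion, linked or epistatic QTL, and
environment-by-genotype structure in the trait.  Passing tests therefore
demonstrate correctness of the algorithms under the stated statistical
model, not robustness to every artefact of real GbS data.  One behaviour
of real data the pipeline *does* reproduce: at a ~1% miscall rate the
two-point map lengths inflate relative to truth, the long-standing
motivation for HMM-based map checking.

## Problem sizes and runtimes

The validation studies use the scales above: 20 replicates per map for
QTL recovery and profile-roughness comparisons, 200 permutations for the
genome-wide threshold on the full 7-group genome (100 markers per group),
50 replicates of 100-marker groups for order recovery, and 20 trials of
injected-swap repair on 30-marker groups with 2 cM spacing (equal spacing
keeps the true order identifiable at $n = 184$; with random positions,
near-coincident markers make some true orders genuinely data-ambiguous).
Mendelian-ratio checks run at $n = 5000$.  All complete in minutes on a
single core.

## Known limitations

- Map lengths estimated from called genotypes inflate with the miscall
  rate, as in all two-point-based pipelines; positions are best read
  comparatively, not absolutely.
- Viterbi recombination counts undercount crossovers for a parent with
  sparse informative coverage; `HMM_mean` is a map-quality diagnostic,
  not an unbiased crossover-rate estimator.
- The permutation threshold is a genome-level surrogate: its value
  depends on total map length, marker informativeness and grid step.
- Phase resolution assumes the LOD-weighted spanning tree is reliable;
  with very weak linkage a parent's phases can fragment (such markers are
  reported unplaced rather than guessed).
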