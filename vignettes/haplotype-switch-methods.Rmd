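---
title: "Methods: detecting a temporal haplotype switch in a breeding panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting a temporal haplotype switch in a breeding panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haploswitch)
```

## The problem

Breeding programs reshape crop genomes over decades. When a large
non-recombining region — typically pericentromeric — carries a beneficial
allele, the whole region sweeps through the germplasm as a unit: a
*haplotype switch*. In a panel of inbred accessions with known release
years, such a switch leaves a characteristic joint signature:

* **diversity over time**: polymorphism information content (PIC) in the
  region is low in the earliest release periods (old haplotype nearly
  fixed), rises mid-sweep (both haplotypes segregate), and falls again in
  the newest periods (new haplotype nearly fixed);
* **differentiation**: windowed FST between early- and late-released
  groups is extreme across the whole region and drops sharply at its
  edges;
* **expression**: genes inside the region whose regulation differs
  between haplotypes show a haplotype-dependent expression pattern that
  is consistent across tissues.

`haploswitch` implements each stage of this analysis as a tested package
function, and ships a generator that produces panels with a planted
sweep so every stage can be validated against ground truth.

## Statistics

**PIC.** For a locus with allele frequencies $p_i$,
$\mathrm{PIC} = 1 - \sum_i p_i^2 - \sum_{i<j} 2 p_i^2 p_j^2$; for a
biallelic SNP this is maximal (0.375) at $p = 0.5$ and 0 when
monomorphic. `rolling_pic()` averages per-SNP PIC in rolling windows of
a fixed SNP count (full-scale convention: 10,000 SNPs); allele
frequencies are taken over non-missing calls. The rolling step is not
fixed by convention; the default is one tenth of the window, which gives
smooth tracks without per-SNP cost.

**Weir–Cockerham FST.** `wc_fst_per_snp()` computes the 1984
moment-estimator variance components $a$ (among populations), $b$
(among individuals within populations) and $c$ (within individuals)
from genotype counts, including observed heterozygotes — inbred panels
simply contribute a small $\bar h$. Windowed values
(`windowed_fst()`) use the ratio-of-sums convention
$\hat\theta_W = \sum a / \sum (a+b+c)$ over the defined SNPs of each
window; per-SNP negative estimates are retained, not truncated. SNPs
monomorphic across both groups are undefined and excluded; windows with
no defined SNP are omitted.

**AMOVA.** `amova()` partitions variance among/within groups from the
matrix of mean squared allele-count differences over shared non-missing
SNPs (the method itself does not fix a distance; this one is standard
for SNP dosage data, bounded, and robust to missingness). Negative
variance-component estimates are reported raw but truncated to zero when
percentages are formed, so percentages are interpretable ([0, 100],
summing to 100). The permutation p-value shuffles group labels.

**Ordination and clustering.** `ibs_distance()` is the proportion of
allele differences over shared SNPs — the panel's ordination distance
throughout (the conventional choice for SNP panels; symmetric and
bounded). `pcoa()` is classical scaling; axes with negative eigenvalues
are reported but dropped. `find_clusters()` runs best-of-$n$ k-means on
leading principal components and scores
$\mathrm{BIC}(k) = n\ln(\mathrm{WSS}_k/n) + k\ln n$. Two deliberate
consequences: the BIC argmin over-segments weakly structured panels when
few PCs are retained (the penalty is weak relative to noise-splitting
gains), which is why `choose_k_elbow()` — the maximal discrete second
difference of the curve — is provided as the advisory rule, and why the
pipeline always accepts a user override of $k$. "Iterations" of the
k-means workflow are implemented as random restarts (`n_starts`);
mean-imputation of missing calls is used only inside the PCA step, never
for the statistics. `dapc()` is PCA reduction followed by linear
discriminant analysis, with a guard against retaining as many PCs as
accessions; `xval_n_pcs()` picks the PC count by stratified-holdout
cross-validation (ties toward fewer PCs).

## Block delineation and haplotype assignment

`delineate_block()` formalizes "the region with FST above the
threshold": windows $\ge$ threshold (default 0.7) form runs, runs
separated by at most `max_gap` (default 2) sub-threshold windows merge —
tolerating isolated dips inside an otherwise high region — and the
longest merged run in bp with at least `min_windows` (default 5)
contributing windows is the block, with boundaries at the first
contributing window's start and the last one's end. Ties go to the
leftmost run; secondary runs are reported separately because real scans
show additional high-FST loci elsewhere. How exact published block
boundaries were called from a windowed track is generally not stated;
the thresholded-run rule is one defensible formalization and is the one
tested here.

`assign_haplotypes()` makes haplotype assignment reproducible: PCoA of
the block SNPs' IBS distances, k-means on the leading coordinates, and
cluster naming through *anchor* accessions of known haplotype. A cluster
containing anchors of two different haplotypes is an error instructing
the user to raise $k$ — mirroring the practice of raising $k$ until the
cluster of interest is stable. Accessions far from their centroid
(configurable z-score, off by default) can be left unassigned rather
than forced, since panels contain rare recombinant or minority
haplotypes that belong to no cluster.

`project_accessions()` transfers labels to an external collection on the
SNPs shared by (chrom, pos, ref, alt), after per-SNP filters (minor
allele count $\ge 1$, missingness $\le 20\%$) and exclusion of external
accessions with more than 20% missing calls in the region. Cross-build
coordinates are not lifted over internally; a common build is required
(a region mapping must be applied upstream). `geographic_frequency()`
tabulates per-country carrier frequencies and excludes
country/category cells below `min_n = 15` accessions rather than
zero-filling them.

## Haplotype-dependent expression

Genes are filtered to the expressed subset (cpm strictly above 1 in
strictly more than 30% of accessions in at least one tissue). The caller
uses an explicit effect-size rule rather than clustering membership:
per gene and tissue, the standardized mean difference (SMD) of
log2(cpm + 1) between the two main haplotype groups, calling a gene
haplotype-dependent only if $|\mathrm{SMD}| \ge 2$ with the same sign in
*every* tissue. Clustering (`cluster_genes()`, default $k = 4$) is
retained as corroboration — cluster membership alone is seed- and
$k$-sensitive, while the SMD rule is deterministic and thresholded.
Carriers of minority haplotypes are excluded from the SMD computation
since their expression follows neither main pattern. The log base and
pseudocount of "log cpm" are conventions; base 2 with pseudocount 1 is
used and both are configurable.

## The generator and what it does (not) emulate

`simulate_panel()` draws background SNPs independently per accession
from Beta-distributed reference-allele frequencies and copies block SNPs
verbatim from the accession's haplotype vector, so the block is
perfectly non-recombining and carries all the LD in the data. The target
haplotype is assigned with probability
$1/(1+e^{-s(y - m)})$ from the release year $y$. Defaults (chosen once
as the package's study conditions): 200 accessions spread evenly over
the seven release periods 1830–2014; one 500 Mbp chromosome with 20,000
background SNPs; block 50–150 Mbp with 2,000 SNPs; divergence $d = 0.5$
(fraction of block SNPs fixed-different between haplotypes); sweep
midpoint 1975, rate 0.15/yr; residual heterozygosity 0.005; missingness
0.02 — roughly a 100-fold size reduction from a full panel so the whole
validation suite runs in minutes. The external collection defaults to
six countries of 60 accessions with target-haplotype frequencies from
0.85 down to 0.05, emulating a geographic origin gradient; the
expression spec defaults to 850 block genes of which 46 are up- and 2
down-regulated in the target haplotype (effect 4 log2 units, noise
$\sigma = 0.5$, six tissues).

Deliberate non-realisms: no background LD (the tested procedures are
frequency- and distance-based, not LD-decay-based), no recombination map,
no pedigree, Gaussian expression noise instead of count noise. Passing
tests therefore validate the statistical machinery and the pipeline
logic, not robustness to background LD or count overdispersion.

## Numerical and scale choices

* **Scan windows are density-matched.** The full-scale FST convention
  (100 kbp windows, 10 kbp step) holds ~36 SNPs per window at ~1 SNP per
  2.8 kbp. At the generator's density (1 SNP per ~25 kbp) the same
  windows often contain no informative SNP and the track fragments, so
  all desk-scale analyses scan with 1 Mbp windows and 250 kbp step — the
  same SNPs-per-window — and boundary accuracy is assessed in units of
  that step. The window/step ratio of 4 keeps the edge-smearing bias of
  the thresholded-run boundary below one step. `windowed_fst()` keeps
  the full-scale default for full-scale data.
* **Trajectory envelopes are simultaneous.** The generating logistic
  implies a binomial count per release period; the validation envelope
  uses Bonferroni-adjusted binomial quantiles across the seven periods so
  the *whole* trajectory lies inside with 95% probability. Pointwise 95%
  bands would fail a seven-period trajectory ~30% of the time by
  construction and would say nothing about the pipeline.
* **Degenerate inputs.** Monomorphic SNPs never trigger LD pruning
  drops; all-missing SNPs are dropped from window means; identical
  accessions yield zero distances and identical ordination coordinates;
  k-means at infeasible $k$ (fewer distinct points) falls back to the
  feasible maximum; WSS = 0 selects $k = 1$ by the BIC tie rule
  (ties always resolve toward smaller $k$).
* **Strictness at thresholds** follows the printed filter definitions:
  heterozygosity strictly below 2%, MAF strictly above 0.025, expression
  strictly above 1 cpm in strictly more than 30% of accessions. MAF is
  computed from allele counts so exactly-at-threshold fractions compare
  as printed.
* **Validation problem sizes** (chosen once): 1,000-SNP panels for the
  windowed-PIC oracle; 100 seeded 10-accession × 20-SNP instances for
  the Weir–Cockerham component oracle (tolerance 1e-12); 20 seeded
  default panels for end-to-end block recovery; 10 seeded expression
  runs of 40 planted effects among 800 nulls.

## Known limitations

Only two-population FST components are implemented (no $r > 2$
hierarchical estimator); multi-allelic sites are skipped, not split;
missing data are never imputed — every statistic is defined over
non-missing calls; LD pruning is greedy and window-local, matching
common practice but not globally optimal; the BIC variant is intended
for run-to-run comparability, not comparability across implementations.
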