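# haploswitch

Temporal haplotype-block analysis of crop breeding panels.

Breeding panels of inbred accessions spanning decades of release years
encode how selection reshaped a crop's genome. When a large
non-recombining (typically pericentromeric) region carries a beneficial
allele, the entire region is swept through the germplasm as one unit — a
*haplotype switch*. `haploswitch` provides the full analysis chain for
detecting and characterizing such a switch from biallelic SNP genotypes,
release-year metadata and (optionally) gene expression:

* **Genotype I/O and filtering** — VCF or delimited matrices coded as
  alternative-allele dosage \{0, 1, 2, NA\}; heterozygosity/MAF/missingness
  filters, LD pruning, seeded SNP subsampling, release-period grouping.
* **Windowed scans** — polymorphism information content
  (PIC = 1 − Σp² − Σ<sub>i&lt;j</sub>2p²<sub>i</sub>p²<sub>j</sub>) and
  reference-allele frequency in rolling SNP-count windows; Weir–Cockerham
  (1984) FST in bp windows by ratio of summed variance components
  θ̂ = Σa / Σ(a+b+c); genome-wide pairwise group FST; two-level AMOVA
  with permutation test.
* **Population structure** — identity-by-state distances, PCoA,
  k-means over principal components with BIC model selection and an
  elbow heuristic, DAPC with cross-validated PC retention.
* **Block delineation and haplotype assignment** — thresholded-run
  delineation of the high-FST block, anchor-based haplotype assignment
  (clusters named through accessions of known haplotype), frequency
  trajectories over release periods, projection onto external germplasm
  collections, per-country carrier frequencies with a minimum-n
  exclusion rule, graphical-genotype export.
* **Haplotype-dependent expression** — expressed-gene filtering on cpm,
  expression ordination, gene clustering, and a standardized-mean-
  difference caller requiring a consistent effect sign across all
  tissues.
* **Synthetic data** — a generator producing panels with a planted
  logistic sweep (plus external collections and haplotype-coupled
  expression) and full ground truth, so every stage is verifiable
  without external downloads.

## Worked example

The numbered scripts under `analysis/` run the whole study on the
default synthetic conditions (200 accessions, 1830–2014, one 500 Mbp
chromosome, 50–150 Mbp block swept from ~0% to ~100% with midpoint
1975); each writes its tables under `results/`:

```sh
Rscript analysis/01_simulate.R            # panel + ground truth
Rscript analysis/02_structure.R           # PCoA, k-means/BIC, DAPC, AMOVA
Rscript analysis/03_genome_scan.R         # PIC / ref-freq / FST tracks
Rscript analysis/04_haploblock.R          # block, assignment, trajectory
Rscript analysis/05_genebank_projection.R # external collection projection
Rscript analysis/06_expression.R          # haplotype-dependent genes
```

Output of a full run (seed 1):

```
panel: 200 accessions x 22000 SNPs; target haplotype carried by 118
PCo1 explains 13.8% of the variation
BIC argmin at k = 2; elbow suggests k = 2
AMOVA: 5.3% of variance among periods (p = 0.010)
FST track: 1401 windows; 398 windows >= 0.7
haplo_block 5H:49750001-150000000 (100.25 Mbp, 398 windows >= 0.70)
haplotype assignment accuracy vs truth: 1.000
      period  n n_period frequency
   1830-1959  0       29 0.0000000
   1960-1969  4       29 0.1379310
   1970-1979 10       29 0.3448276
   1980-1989 22       29 0.7586207
   1990-1999 27       28 0.9642857
   2000-2009 27       28 0.9642857
   2010-2014 28       28 1.0000000
789 of 850 genes expressed (> 1 cpm in > 30% of accessions in >= 1 tissue)
haplotype-dependent genes: 46 up, 2 down in the target haplotype
```

Reading the output: the detected block boundaries fall within one scan
step (250 kbp) of the true 50–150 Mbp block; every accession receives its
true haplotype; the trajectory of the new haplotype (label 2) climbs
along the generating logistic from 0 to fixation; and the expression
caller recovers exactly the planted 46 up- and 2 down-regulated genes.
The methods vignette (`vignettes/haplotype-switch-methods.Rmd`) explains
each statistic, the generator's assumptions and the numerical choices.

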