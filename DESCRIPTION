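Package: haploswitch
Title: Temporal Haplotype-Block Analysis of Crop Breeding Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for tracking haplotype turnover in temporally structured
    breeding panels of inbred crop accessions. Provides genotype-matrix input,
    filtering and LD pruning; windowed diversity and differentiation scans
    (polymorphism information content, reference-allele frequency,
    Weir-Cockerham FST); population-structure inference (identity-by-state
    distances, principal coordinate analysis, k-means with BIC model selection,
    discriminant analysis of principal components, two-level AMOVA);
    delineation of non-recombining haplotype blocks from FST tracks;
    anchor-based haplotype assignment with temporal frequency trajectories and
    projection onto external germplasm collections; detection of
    haplotype-dependent gene expression from counts-per-million matrices; and a
    synthetic-data generator that emulates a logistic haplotype sweep with full
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    MASS,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
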