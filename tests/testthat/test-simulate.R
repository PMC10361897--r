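test_that("the generator is fully reproducible from its seed", {
  cfg <- sim_config(seed = 7, n_accessions = 40, n_background_snps = 500,
                    n_block_snps = 100, chrom_length_bp = 1e7,
                    block_start_bp = 2e6, block_end_bp = 4e6)
  s1 <- simulate_panel(cfg)
  s2 <- simulate_panel(cfg)
  expect_identical(s1$genotypes$calls, s2$genotypes$calls)
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$truth$haplotype, s2$truth$haplotype)
  e1 <- simulate_external_collection(cfg)
  e2 <- simulate_external_collection(cfg)
  expect_identical(e1$genotypes$calls, e2$genotypes$calls)
  x1 <- simulate_expression(s1$truth, cfg)
  x2 <- simulate_expression(s2$truth, cfg)
  expect_identical(x1$expression$cpm, x2$expression$cpm)
})

test_that("the block is copied verbatim from haplotype vectors", {
  cfg <- sim_config(seed = 8, n_accessions = 30, n_background_snps = 500,
                    n_block_snps = 200, chrom_length_bp = 1e7,
                    block_start_bp = 2e6, block_end_bp = 4e6,
                    divergence = 1, het_rate = 0, missing_rate = 0)
  sim <- simulate_panel(cfg)
  in_block <- sim$genotypes$variants$pos >= 2e6 &
    sim$genotypes$variants$pos <= 4e6
  bl <- sim$genotypes$calls[, in_block]
  hap <- sim$truth$haplotype
  one <- which(hap == 1L); two <- which(hap == 2L)
  # no recombination: same-haplotype accessions are identical in the block
  for (i in one[-1]) expect_identical(bl[i, ], bl[one[1], ])
  for (i in two[-1]) expect_identical(bl[i, ], bl[two[1], ])
  # divergence 1: different haplotypes differ at every block SNP
  expect_true(all(bl[one[1], ] != bl[two[1], ]))
})

test_that("the logistic sweep is calibrated at its midpoint", {
  per <- data.frame(start = 1975, end = 1975, label = "1975")
  cfg <- sim_config(seed = 9, n_accessions = 400, n_background_snps = 100,
                    n_block_snps = 50, chrom_length_bp = 1e7,
                    block_start_bp = 2e6, block_end_bp = 4e6,
                    year_range = c(1975, 1975), periods = per)
  sim <- simulate_panel(cfg)
  n2 <- sum(sim$truth$haplotype == 2L)
  ci <- stats::qbinom(c(0.025, 0.975), 400, 0.5)
  expect_gte(n2, ci[1])
  expect_lte(n2, ci[2])
})

test_that("external collections honour per-country frequencies and thinning", {
  ext_spec <- data.frame(country = c("AAA", "BBB"), n = c(100, 200),
                         target_freq = c(0, 0.8))
  cfg <- sim_config(seed = 10, n_accessions = 30, n_background_snps = 400,
                    n_block_snps = 150, chrom_length_bp = 1e7,
                    block_start_bp = 2e6, block_end_bp = 4e6,
                    external = ext_spec)
  ext <- simulate_external_collection(cfg, snp_keep_frac = 0.5)
  hap <- ext$truth$haplotype
  is_b <- ext$passport$country == "BBB"
  expect_true(all(hap[!is_b] == 1L))  # frequency 0 -> no carriers
  n2 <- sum(hap[is_b] == 2L)
  ci <- stats::qbinom(c(0.025, 0.975), 200, 0.8)
  expect_gte(n2, ci[1]); expect_lte(n2, ci[2])
  # thinned SNPs are a subset of the panel's by (chrom, pos)
  pan <- simulate_panel(cfg)$genotypes$variants
  expect_true(all(paste(ext$genotypes$variants$chrom,
                        ext$genotypes$variants$pos) %in%
                    paste(pan$chrom, pan$pos)))
  bad <- ext_spec; bad$target_freq[1] <- 1.2
  expect_error(sim_config(seed = 1, external = bad), "\\[0, 1\\]")
})

test_that("planted expression effects have the configured size", {
  cfg <- sim_config(seed = 11, n_accessions = 60, n_background_snps = 200,
                    n_block_snps = 100, chrom_length_bp = 1e7,
                    block_start_bp = 2e6, block_end_bp = 4e6,
                    expression = list(n_genes = 60, n_up = 8, n_down = 2,
                                      effect = 4, sigma = 0.5, n_tissues = 3,
                                      baseline_mean = 3, baseline_sd = 1))
  sim <- simulate_panel(cfg)
  xp <- simulate_expression(sim$truth, cfg)
  lg <- log_cpm(xp$expression)
  carrier <- sim$truth$haplotype == 2L
  up <- xp$gene_truth$status == "up"
  diffs <- vapply(which(up), function(g) {
    mean(lg$cpm[g, carrier, ]) - mean(lg$cpm[g, !carrier, ])
  }, 0)
  n_c <- min(sum(carrier), sum(!carrier)) * 3
  expect_true(all(abs(diffs - 4) < 2 * 0.5 / sqrt(n_c) + 0.1))

  # a null generator produces no calls at any positive threshold
  asg <- structure(data.frame(accession = names(sim$truth$haplotype),
                              haplotype = sim$truth$haplotype,
                              cluster = 1L, dist_to_centroid = 0,
                              is_anchor = FALSE),
                   class = c("haplotype_assignment", "data.frame"))
  for (s in 1:10) {
    cfg0 <- sim_config(seed = 100 + s, n_accessions = 60,
                       n_background_snps = 200, n_block_snps = 100,
                       chrom_length_bp = 1e7, block_start_bp = 2e6,
                       block_end_bp = 4e6,
                       expression = list(n_genes = 80, n_up = 0, n_down = 0,
                                         effect = 0, sigma = 0.5,
                                         n_tissues = 3, baseline_mean = 3,
                                         baseline_sd = 1))
    x0 <- simulate_expression(sim$truth, cfg0)
    r0 <- haplotype_dependent_genes(x0$expression, asg, 2L,
                                    smd_threshold = 1)
    expect_true(all(r0$direction == "none"))
  }
})

test_that("invalid configurations are rejected before generation", {
  expect_error(sim_config(seed = 1, block_start_bp = 2e8, block_end_bp = 1e8),
               "inside the chromosome")
  expect_error(sim_config(seed = 1, divergence = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(seed = 1, n_haplotypes = 1), "at least 2")
  expect_error(sim_config(seed = 1,
                          expression = list(n_genes = 10, n_up = 8,
                                            n_down = 4, effect = 1,
                                            sigma = 1, n_tissues = 2,
                                            baseline_mean = 3,
                                            baseline_sd = 1)),
               "exceeds")
  expect_error(sim_config(seed = 1,
                          expression = list(n_genes = 10, n_up = 1,
                                            n_down = 0, effect = 1,
                                            sigma = 0, n_tissues = 2,
                                            baseline_mean = 3,
                                            baseline_sd = 1)),
               "sigma")
})
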