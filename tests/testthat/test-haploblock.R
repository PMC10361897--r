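fake_track <- function(values, step = 10, size = 10) {
  starts <- seq(1, by = step, length.out = length(values))
  window_track(
    data.frame(chrom = "5H", start_bp = starts, end_bp = starts + size - 1,
               mid_bp = starts + (size - 1) / 2,
               n_snps = 1L, value = values),
    window_spec("bp", size, step), "FST")
}

test_that("block delineation merges runs and picks the longest", {
  tr <- fake_track(c(rep(0.1, 5), rep(0.9, 10), rep(0.1, 5)))
  b <- delineate_block(tr, threshold = 0.7, min_windows = 5, max_gap = 2)
  expect_equal(b$window_idx, 6:15)
  expect_equal(b$start_bp, tr$start_bp[6])
  expect_equal(b$end_bp, tr$end_bp[15])

  expect_null(delineate_block(fake_track(rep(0.2, 20)), threshold = 0.7))

  gap <- fake_track(c(rep(0.9, 4), 0.5, rep(0.9, 4)))
  b2 <- delineate_block(gap, threshold = 0.7, min_windows = 5, max_gap = 1)
  expect_equal(b2$n_windows, 8)
  expect_equal(b2$start_bp, gap$start_bp[1])
  expect_equal(b2$end_bp, gap$end_bp[9])
  # with no gap bridging the runs are too short to qualify
  expect_null(delineate_block(gap, threshold = 0.7, min_windows = 5,
                              max_gap = 0))
})

test_that("raising the threshold never widens the block", {
  set.seed(15)
  vals <- pmin(1, pmax(0, c(stats::runif(30, 0, 0.5),
                            stats::runif(30, 0.6, 1),
                            stats::runif(30, 0, 0.5))))
  tr <- fake_track(vals)
  prev_span <- Inf
  for (th in c(0.5, 0.6, 0.7, 0.8, 0.9)) {
    b <- delineate_block(tr, threshold = th, min_windows = 3, max_gap = 2)
    span <- if (is.null(b)) 0 else b$end_bp - b$start_bp
    expect_lte(span, prev_span)
    prev_span <- span
  }
})

test_that("block SNP extraction respects closed flanked bounds", {
  gm <- make_gm(matrix(0L, 2, 5), pos = c(89L, 95L, 150L, 210L, 300L))
  block <- list(chrom = "1H", start_bp = 100, end_bp = 200)
  sub <- extract_block_snps(gm, block, flank_bp = 10)
  expect_equal(sub$variants$pos, c(95L, 150L, 210L))  # 89 is outside
  expect_error(extract_block_snps(gm, list(chrom = "9H", start_bp = 1,
                                           end_bp = 2), 0), "no SNPs")
  # oracle: direct linear position scan on a simulated panel
  sim <- small_sweep_sim(41)
  blk <- sim$truth$block
  sub2 <- extract_block_snps(sim$genotypes, list(chrom = blk$chrom,
                                                 start_bp = blk$start_bp,
                                                 end_bp = blk$end_bp),
                             flank_bp = 10000)
  vr <- sim$genotypes$variants
  expect_equal(n_variants(sub2),
               sum(vr$chrom == blk$chrom & vr$pos >= blk$start_bp - 10000 &
                     vr$pos <= blk$end_bp + 10000))
})

test_that("anchored assignment recovers simulated haplotypes", {
  sim <- small_sweep_sim(42)
  block_gm <- extract_block_snps(sim$genotypes, sim$truth$block, 0)
  asg <- assign_haplotypes(block_gm, k = 2, anchors = sim$anchors, seed = 2)
  truth <- sim$truth$haplotype[asg$accession]
  expect_equal(mean(asg$haplotype == truth), 1)
  # anchors carry their declared label
  expect_equal(asg$haplotype[match(names(sim$anchors), asg$accession)],
               unname(sim$anchors))
})

test_that("assignment handles degenerate and conflicting anchor cases", {
  ident <- make_gm(matrix(rep(c(0L, 2L), 10), 6, 20, byrow = TRUE))
  asg <- assign_haplotypes(ident, k = 1,
                           anchors = c(ACC001 = 3L), seed = 1)
  expect_true(all(asg$haplotype == 3L))
  expect_true(all(asg$cluster == 1L))
  # two anchors of different haplotypes forced into one cluster -> error
  expect_error(assign_haplotypes(ident, k = 2,
                                 anchors = c(ACC001 = 1L, ACC002 = 2L),
                                 seed = 1),
               "increase k")
})

test_that("assignment labels are invariant to accession order", {
  sim <- small_sweep_sim(43, n_accessions = 80, n_background_snps = 2000,
                         n_block_snps = 500, chrom_length_bp = 5e7,
                         block_start_bp = 5e6, block_end_bp = 1.5e7)
  block_gm <- extract_block_snps(sim$genotypes, sim$truth$block, 0)
  asg1 <- assign_haplotypes(block_gm, 2, sim$anchors, seed = 9)
  set.seed(99)
  perm <- sample(accession_ids(block_gm))
  asg2 <- assign_haplotypes(subset_gm(block_gm, accessions = perm),
                            2, sim$anchors, seed = 9)
  m <- match(asg1$accession, asg2$accession)
  expect_equal(asg1$haplotype, asg2$haplotype[m])
})

test_that("trajectories normalize within periods and track the sweep", {
  asg <- structure(data.frame(accession = paste0("A", 1:4),
                              haplotype = rep(2L, 4), cluster = 1L,
                              dist_to_centroid = 0, is_anchor = FALSE),
                   class = c("haplotype_assignment", "data.frame"))
  meta <- empty_meta(paste0("A", 1:4))
  meta$release_year <- c(2001L, 2003L, 2005L, 2007L)
  tra <- haplotype_trajectory(asg, meta, "decade")
  row <- tra[tra$period == "2000-2009", ]
  expect_equal(row$frequency, 1)
  expect_equal(row$n, 4)
  expect_true(all(tra$n_period[tra$period != "2000-2009"] == 0))

  sim <- small_sweep_sim(44)
  block_gm <- extract_block_snps(sim$genotypes, sim$truth$block, 0)
  asg2 <- assign_haplotypes(block_gm, 2, sim$anchors, seed = 3)
  tra2 <- haplotype_trajectory(asg2, sim$meta, "decade")
  sums <- tapply(tra2$frequency, tra2$period, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # later periods carry the target haplotype at higher frequency
  f2 <- tra2$frequency[tra2$haplotype == 2]
  expect_gt(f2[length(f2)], f2[1])
})

test_that("external projection labels anchor copies and applies filters", {
  sim <- small_sweep_sim(45)
  blk <- sim$truth$block
  panel_block <- extract_block_snps(sim$genotypes, blk, 10000)
  ext <- simulate_external_collection(sim_config(seed = 45),
                                      snp_keep_frac = 0.6)
  ext_block <- extract_block_snps(ext$genotypes, blk, 10000)

  # plant an exact copy of an anchor and an over-missing accession
  anchor1 <- names(sim$anchors)[1]
  copy <- panel_block$calls[anchor1, colnames(ext_block$calls), drop = FALSE]
  rownames(copy) <- "COPY01"
  holey <- copy
  holey[1, seq_len(floor(0.25 * ncol(holey)))] <- NA
  rownames(holey) <- "HOLEY1"
  ext2 <- genotype_matrix(rbind(ext_block$calls, copy, holey),
                          ext_block$variants, build = "synthetic")
  proj <- project_accessions(panel_block, ext2, sim$anchors, k = 2,
                             seed = 5)
  expect_equal(proj$haplotype[proj$accession == "COPY01"],
               unname(sim$anchors[anchor1]))
  expect_true("HOLEY1" %in% attr(proj, "excluded_accessions"))
  expect_false("HOLEY1" %in% proj$accession)
  expect_gt(attr(proj, "shared_snps"), 100)

  # per-accession projection accuracy against simulator truth
  truth <- ext$truth$haplotype[proj$accession]
  ok <- !is.na(truth)
  expect_gte(mean(proj$haplotype[ok] == truth[ok]), 0.99)

  mismatched <- ext_block
  mismatched$build <- "otherbuild"
  expect_error(project_accessions(panel_block, mismatched, sim$anchors, 2),
               "builds differ")
  tiny <- subset_gm(ext_block, variants = 1:50)
  expect_error(project_accessions(panel_block, tiny, sim$anchors, 2),
               "< 100")
})

test_that("geographic frequencies exclude small country cells", {
  passport <- data.frame(
    accession = paste0("E", 1:34),
    country = c(rep("AAA", 14), rep("BBB", 20)),
    cultivation_status = "landrace", stringsAsFactors = FALSE)
  asg <- structure(data.frame(accession = passport$accession,
                              haplotype = c(rep(2L, 14),
                                            rep(c(2L, 1L), 10)),
                              cluster = 1L, dist_to_centroid = 0,
                              is_anchor = FALSE),
                   class = c("haplotype_assignment", "data.frame"))
  gf <- geographic_frequency(asg, passport, target_label = 2L,
                             category = "cultivation_status", min_n = 15)
  expect_equal(gf$country, "BBB")
  expect_equal(gf$frequency, 0.5)
  expect_equal(attr(gf, "excluded")$country, "AAA")
  expect_error(geographic_frequency(asg, passport, 2L, "no_such_column"),
               "unknown passport category")
})

test_that("graphical genotypes recode bijectively and group by haplotype", {
  sim <- small_sweep_sim(46, n_accessions = 30, n_background_snps = 1000,
                         n_block_snps = 300, chrom_length_bp = 5e7,
                         block_start_bp = 5e6, block_end_bp = 1.5e7)
  blk <- sim$truth$block
  hap <- sim$truth$haplotype
  gg <- graphical_genotypes(sim$genotypes, blk, flank_bp = 0, n_snps = 100,
                            seed = 7, order_by = hap)
  expect_equal(ncol(gg), 102)
  expect_false(is.unsorted(gg$haplotype))  # contiguous grouping
  # coding bijection against the underlying calls
  sub <- extract_block_snps(sim$genotypes, blk, 0)
  sub <- subsample_variants(sub, 100, seed = 7)
  first <- gg$accession[1]
  codes <- c(`ref-hom` = 0L, het = 1L, `alt-hom` = 2L)
  decoded <- unname(codes[unlist(gg[1, -(1:2)])])
  expect_equal(decoded, unname(sub$calls[first, ]))
  gg2 <- graphical_genotypes(sim$genotypes, blk, flank_bp = 0, n_snps = 100,
                             seed = 7, order_by = hap)
  expect_identical(gg, gg2)
})
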