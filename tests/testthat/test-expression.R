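toy_expr <- function(cpm_by_tissue, chrom = "5H") {
  # cpm_by_tissue: list of genes x accessions matrices
  arr <- simplify2array(cpm_by_tissue)
  genes <- data.frame(id = rownames(cpm_by_tissue[[1]]), chrom = chrom,
                      pos = seq_len(nrow(cpm_by_tissue[[1]])) * 1000)
  expression_matrix(arr, genes, names(cpm_by_tissue))
}

test_that("log transform is the documented base-2 shift", {
  m <- matrix(c(0, 1, 7, 3), 2, 2,
              dimnames = list(c("g1", "g2"), c("a1", "a2")))
  ex <- toy_expr(list(t1 = m))
  lg <- log_cpm(ex)
  expect_equal(as.vector(lg$cpm[, , 1]), c(0, 1, 3, 2))
  expect_true(lg$logged)
  expect_identical(log_cpm(lg)$cpm, lg$cpm)  # no double transform
  bad <- ex
  bad$cpm[1] <- -1
  expect_error(log_cpm(bad), "negative")
  expect_error(log_cpm(ex, pseudocount = 0), "pseudocount")
})

test_that("expressed-gene filter applies strict > thresholds per tissue", {
  n_acc <- 20
  g_keep <- c(rep(2, 7), rep(0, 13))     # 35% of accessions above 1 cpm
  g_edge <- c(rep(2, 6), rep(0, 14))     # exactly 30% -> dropped
  g_flat <- rep(1, n_acc)                # cpm exactly 1 -> dropped
  m <- rbind(keep = g_keep, edge = g_edge, flat = g_flat)
  colnames(m) <- paste0("a", seq_len(n_acc))
  ex <- toy_expr(list(t1 = m, t2 = m * 0))
  kept <- filter_expressed(ex, min_cpm = 1, min_frac = 0.30)
  expect_equal(attr(kept, "kept_genes"), "keep")
  # idempotent and order-invariant
  expect_equal(attr(filter_expressed(kept), "kept_genes"), "keep")
  perm <- ex
  perm$cpm <- perm$cpm[c(3, 1, 2), , , drop = FALSE]
  perm$genes <- perm$genes[c(3, 1, 2), ]
  expect_equal(attr(filter_expressed(perm), "kept_genes"), "keep")
})

test_that("expression ordination separates archetypes and handles degeneracy", {
  set.seed(71)
  n_g <- 50; n_a <- 30
  base <- matrix(stats::rnorm(n_g * n_a, 3, 0.3), n_g, n_a,
                 dimnames = list(sprintf("g%02d", 1:n_g),
                                 sprintf("a%02d", 1:n_a)))
  grp <- rep(c(0, 4), each = n_a / 2)
  shifted <- base + matrix(grp, n_g, n_a, byrow = TRUE)
  ex <- toy_expr(list(t1 = 2^shifted - 1))
  ord <- pcoa_expression(ex, tissue = 1, mode = "accessions")
  pc1 <- ord$coordinates[, 1]
  expect_true(max(pc1[1:15]) < min(pc1[16:30]) ||
                min(pc1[1:15]) > max(pc1[16:30]))

  const <- toy_expr(list(t1 = matrix(1, 4, 5,
                                     dimnames = list(paste0("g", 1:4),
                                                     paste0("a", 1:5)))))
  ordc <- pcoa_expression(const, 1)
  expect_true(all(ordc$coordinates == 0))

  dup <- toy_expr(list(t1 = cbind(base, dup = base[, 1])))
  ordd <- pcoa_expression(dup, 1)
  expect_equal(ordd$coordinates[1, ], ordd$coordinates[n_a + 1, ],
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("gene clustering recovers planted archetypes and is seeded", {
  set.seed(72)
  n_a <- 24
  arch1 <- matrix(stats::rnorm(30 * n_a, 2, 0.2), 30, n_a)
  arch2 <- matrix(stats::rnorm(20 * n_a, 8, 0.2), 20, n_a)
  m <- rbind(arch1, arch2)
  dimnames(m) <- list(sprintf("g%02d", 1:50), sprintf("a%02d", 1:n_a))
  ex <- toy_expr(list(t1 = 2^m - 1))
  cl <- cluster_genes(ex, k = 2, seed = 3)
  expect_equal(length(unique(cl[1:30])), 1)
  expect_equal(length(unique(cl[31:50])), 1)
  expect_false(cl[1] == cl[31])
  expect_identical(cl, cluster_genes(ex, k = 2, seed = 3))
  expect_equal(length(unique(cluster_genes(ex, k = 1, seed = 1))), 1)
  expect_error(cluster_genes(ex, k = 51, seed = 1), "exceeds")
})

test_that("SMD caller requires consistent cross-tissue effects", {
  set.seed(73)
  n_a <- 24
  hap <- rep(c(1L, 2L), each = n_a / 2)
  asg <- structure(data.frame(accession = sprintf("a%02d", 1:n_a),
                              haplotype = hap, cluster = hap,
                              dist_to_centroid = 0, is_anchor = FALSE),
                   class = c("haplotype_assignment", "data.frame"))
  mk <- function(delta_by_gene, flip_t2 = FALSE) {
    lapply(c(t1 = 1, t2 = 2), function(t) {
      d <- if (flip_t2 && t == 2) -delta_by_gene else delta_by_gene
      m <- matrix(stats::rnorm(4 * n_a, 3, 0.3), 4, n_a) +
        outer(d, as.numeric(hap == 2L))
      dimnames(m) <- list(paste0("g", 1:4), sprintf("a%02d", 1:n_a))
      pmax(2^m - 1, 0)
    })
  }
  ex <- toy_expr(mk(c(4, -4, 0, 0)))
  rep_ <- haplotype_dependent_genes(ex, asg, target_label = 2L,
                                    smd_threshold = 2)
  expect_equal(rep_$direction, c("up-in-target", "down-in-target",
                                 "none", "none"))
  # a constant gene is never called
  exc <- toy_expr(list(t1 = matrix(5, 2, n_a,
                                   dimnames = list(c("g1", "g2"),
                                                   sprintf("a%02d", 1:n_a)))))
  repc <- haplotype_dependent_genes(exc, asg, 2L)
  expect_true(all(repc$direction == "none"))
  expect_true(all(repc$min_abs_smd == 0))
  # sign flip in one tissue breaks the consistency rule
  exf <- toy_expr(mk(c(4, 4, 4, 4), flip_t2 = TRUE))
  repf <- haplotype_dependent_genes(exf, asg, 2L)
  expect_true(all(repf$direction == "none"))
  # antisymmetry under swapping the groups
  r12 <- haplotype_dependent_genes(ex, asg, 2L, other_label = 1L)
  r21 <- haplotype_dependent_genes(ex, asg, 1L, other_label = 2L)
  expect_equal(attr(r12, "smd"), -attr(r21, "smd"), tolerance = 1e-12)
  # minimum group size guard
  tiny <- asg
  tiny$haplotype[hap == 2L] <- NA
  tiny$haplotype[1:2] <- 2L
  expect_error(haplotype_dependent_genes(ex, tiny, 2L), ">= 3")
})

test_that("expression long-format TSV round-trips", {
  set.seed(74)
  m1 <- matrix(stats::runif(12, 0, 10), 3, 4,
               dimnames = list(paste0("g", 1:3), paste0("a", 1:4)))
  m2 <- m1 * 2
  ex <- toy_expr(list(crown = m1, root = m2))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expression_long(ex, path)
  back <- read_expression_long(path)
  expect_equal(back$cpm, ex$cpm, tolerance = 1e-12)
  expect_equal(back$tissues, ex$tissues)
})
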