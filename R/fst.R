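#' Per-SNP Weir-Cockerham variance components between two groups
#'
#' Computes the Weir & Cockerham (1984) moment-estimator variance
#' components for each SNP between two disjoint accession groups:
#' `a` (among populations), `b` (among individuals within populations) and
#' `c` (within individuals), from genotype counts including observed
#' heterozygotes (inbred panels simply yield a small mean heterozygosity).
#' The per-SNP estimate is `theta = a / (a + b + c)` where the denominator
#' is positive; SNPs monomorphic in both groups, or with fewer than two
#' informative accessions in either group, are flagged undefined.
#'
#' @param gm a `genotype_matrix`
#' @param group_a,group_b disjoint vectors of accession ids (or indices)
#' @return data.frame with one row per SNP: `a`, `b`, `c`, `theta`,
#'   `defined`, `n1`, `n2`
#' @export
wc_fst_per_snp <- function(gm, group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    stop("both groups must be non-empty")
  }
  ga <- gm$calls[group_a, , drop = FALSE]
  gb <- gm$calls[group_b, , drop = FALSE]
  if (length(intersect(rownames(ga), rownames(gb)))) {
    stop("groups must be disjoint")
  }
  comp <- wc_components(ga, gb)
  vr <- gm$variants
  data.frame(chrom = vr$chrom, pos = vr$pos,
             a = comp$a, b = comp$b, c = comp$c,
             theta = comp$theta, defined = comp$defined,
             n1 = comp$n1, n2 = comp$n2)
}

# vectorized WC84 two-population components from two call matrices
# (accessions x SNPs); p is the alternative-allele frequency.
wc_components <- function(ga, gb) {
  n1 <- colSums(!is.na(ga))
  n2 <- colSums(!is.na(gb))
  p1 <- (2 * colSums(ga == 2L, na.rm = TRUE) + colSums(ga == 1L, na.rm = TRUE)) /
    (2 * pmax(n1, 1))
  p2 <- (2 * colSums(gb == 2L, na.rm = TRUE) + colSums(gb == 1L, na.rm = TRUE)) /
    (2 * pmax(n2, 1))
  h1 <- colSums(ga == 1L, na.rm = TRUE) / pmax(n1, 1)
  h2 <- colSums(gb == 1L, na.rm = TRUE) / pmax(n2, 1)

  r <- 2
  nbar <- (n1 + n2) / r
  ntot <- n1 + n2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / ntot
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / ntot

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  informative <- n1 >= 2 & n2 >= 2
  monomorphic <- pbar %in% c(0, 1) & hbar == 0
  denom <- a + b + cc
  defined <- informative & !monomorphic & is.finite(denom) & denom != 0
  theta <- ifelse(defined, a / denom, NA_real_)
  a[!informative] <- NA_real_
  b[!informative] <- NA_real_
  cc[!informative] <- NA_real_
  list(a = a, b = b, c = cc, theta = theta, defined = defined,
       n1 = n1, n2 = n2)
}

#' Windowed Weir-Cockerham FST between two groups
#'
#' Aggregates per-SNP variance components in base-pair windows by the
#' ratio-of-sums convention: window value
#' `sum(a) / sum(a + b + c)` over the defined SNPs in the window. Negative
#' per-SNP estimates are retained, not truncated. Windows containing no
#' defined SNP are omitted.
#'
#' @param gm a `genotype_matrix`
#' @param group_a,group_b disjoint accession groups
#' @param spec a bp-mode [window_spec()]; default 100 kbp windows,
#'   10 kbp step
#' @return a `window_track` of windowed FST values
#' @export
windowed_fst <- function(gm, group_a, group_b,
                         spec = window_spec("bp", 100000, 10000)) {
  if (spec$mode != "bp") stop("windowed_fst uses bp windows")
  per <- wc_fst_per_snp(gm, group_a, group_b)
  per <- per[per$defined, , drop = FALSE]
  out <- list()
  for (chrom in unique(gm$variants$chrom)) {
    p <- per[per$chrom == chrom, , drop = FALSE]
    if (nrow(p) == 0) next
    p <- p[order(p$pos), , drop = FALSE]
    csum_a <- cumsum(p$a)
    csum_abc <- cumsum(p$a + p$b + p$c)
    csum_n <- seq_len(nrow(p))
    starts <- seq(1, max(p$pos), by = spec$step)
    ends <- starts + spec$size - 1
    lo <- findInterval(starts - 1, p$pos) + 1  # first SNP with pos >= start
    hi <- findInterval(ends, p$pos)            # last SNP with pos <= end
    has <- hi >= lo
    sum_a <- ifelse(has, csum_a[pmax(hi, 1)] -
                      ifelse(lo > 1, csum_a[lo - 1], 0), NA_real_)
    sum_abc <- ifelse(has, csum_abc[pmax(hi, 1)] -
                        ifelse(lo > 1, csum_abc[lo - 1], 0), NA_real_)
    n_snps <- ifelse(has, hi - lo + 1, 0L)
    keep <- has & is.finite(sum_abc) & sum_abc != 0
    out[[chrom]] <- data.frame(chrom = chrom,
                               start_bp = starts[keep],
                               end_bp = ends[keep],
                               mid_bp = (starts[keep] + ends[keep]) / 2,
                               n_snps = n_snps[keep],
                               value = sum_a[keep] / sum_abc[keep])
  }
  if (length(out) == 0) {
    return(window_track(data.frame(chrom = character(), start_bp = numeric(),
                                   end_bp = numeric(), mid_bp = numeric(),
                                   n_snps = integer(), value = numeric()),
                        spec, "FST"))
  }
  window_track(do.call(rbind, out), spec, "FST")
}

#' Genome-wide pairwise FST between groups of a partition
#'
#' For every pair of groups the genome-wide ratio-of-sums Weir-Cockerham
#' estimate over all defined SNPs. Groups with fewer than two accessions
#' are excluded with a warning.
#'
#' @param gm a `genotype_matrix`
#' @param partition named vector (names = accession ids) of group labels,
#'   or a factor/vector aligned with the accessions of `gm`
#' @return a symmetric matrix of pairwise FST with a zero diagonal
#' @export
pairwise_group_fst <- function(gm, partition) {
  part <- align_partition(gm, partition)
  sizes <- table(part)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding group(s) with < 2 accessions: ",
            paste(small, collapse = ", "))
  }
  groups <- names(sizes)[sizes >= 2]
  if (length(groups) < 2) stop("need at least two groups of size >= 2")
  m <- matrix(0, length(groups), length(groups),
              dimnames = list(groups, groups))
  for (i in seq_len(length(groups) - 1)) {
    for (j in seq(i + 1, length(groups))) {
      comp <- wc_components(gm$calls[part == groups[i], , drop = FALSE],
                            gm$calls[part == groups[j], , drop = FALSE])
      ok <- comp$defined
      val <- sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok])
      m[i, j] <- m[j, i] <- val
    }
  }
  m
}

# align a partition (named or positional) with a genotype matrix
align_partition <- function(gm, partition) {
  ids <- accession_ids(gm)
  if (!is.null(names(partition))) {
    if (!all(ids %in% names(partition))) {
      stop("partition is missing accession(s): ",
           paste(utils::head(setdiff(ids, names(partition)), 5),
                 collapse = ", "))
    }
    partition <- partition[ids]
  } else if (length(partition) != length(ids)) {
    stop("partition length does not match number of accessions")
  }
  as.character(partition)
}
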