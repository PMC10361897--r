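#' Per-SNP call summaries
#'
#' Counts and frequencies per SNP over non-missing calls, optionally
#' restricted to a subset of accessions. The reference-allele frequency is
#' `(2 * n_hom_ref + n_het) / (2 * n_non_missing)`.
#'
#' @param gm a `genotype_matrix`
#' @param accessions optional accession ids/indices to restrict to
#' @return data.frame with one row per SNP: `n`, `n0`, `n1`, `n2`,
#'   `p_ref`, `p_alt`, `maf`, `het`, `miss`
#' @export
snp_summary <- function(gm, accessions = NULL) {
  calls <- gm$calls
  if (!is.null(accessions)) calls <- calls[accessions, , drop = FALSE]
  n0 <- colSums(calls == 0L, na.rm = TRUE)
  n1 <- colSums(calls == 1L, na.rm = TRUE)
  n2 <- colSums(calls == 2L, na.rm = TRUE)
  n <- n0 + n1 + n2
  p_ref <- ifelse(n > 0, (2 * n0 + n1) / (2 * n), NA_real_)
  p_alt <- 1 - p_ref
  # MAF from allele counts directly, so threshold comparisons at exactly
  # representable fractions (e.g. 5/200 vs 0.025) behave as printed
  data.frame(n = n, n0 = n0, n1 = n1, n2 = n2,
             p_ref = p_ref, p_alt = p_alt,
             maf = ifelse(n > 0,
                          pmin(2 * n0 + n1, 2 * n2 + n1) / (2 * n),
                          NA_real_),
             het = ifelse(n > 0, n1 / n, NA_real_),
             miss = 1 - n / nrow(calls))
}

#' Filter SNPs on heterozygosity, minor allele frequency and missingness
#'
#' Keeps SNPs whose heterozygote fraction (over non-missing calls) is
#' strictly below `max_het`, whose minor allele frequency is strictly above
#' `min_maf`, and whose missing fraction is at most `max_missing`. The
#' defaults reproduce the standard inbred-panel filter (< 2% heterozygosity,
#' MAF > 0.025). SNP order is preserved and the operation is idempotent.
#'
#' @param gm a `genotype_matrix`
#' @param max_het maximum heterozygote fraction (exclusive), in [0, 1]
#' @param min_maf minimum minor allele frequency (exclusive), in [0, 1]
#' @param max_missing maximum missing-call fraction (inclusive), in [0, 1]
#' @return the filtered `genotype_matrix`, with a `"filter_report"`
#'   attribute counting SNPs failing each rule (a SNP may fail several).
#' @export
filter_variants <- function(gm, max_het = 0.02, min_maf = 0.025,
                            max_missing = 1.0) {
  if (n_variants(gm) == 0) stop("empty input: genotype matrix has no SNPs")
  for (th in c(max_het, min_maf, max_missing)) {
    if (!is.finite(th) || th < 0 || th > 1) stop("thresholds must be in [0,1]")
  }
  s <- snp_summary(gm)
  fail_all_missing <- s$n == 0
  fail_het <- !fail_all_missing & s$het >= max_het
  fail_maf <- fail_all_missing | s$maf <= min_maf
  fail_miss <- s$miss > max_missing
  keep <- !(fail_het | fail_maf | fail_miss)
  out <- subset_gm(gm, variants = which(keep))
  attr(out, "filter_report") <- c(n_input = n_variants(gm),
                                  n_kept = sum(keep),
                                  removed_het = sum(fail_het),
                                  removed_maf = sum(fail_maf),
                                  removed_missing = sum(fail_miss))
  out
}

#' Greedy within-window LD pruning
#'
#' Slides a window of `window_snps` SNPs (step `step_snps`) along each
#' chromosome; within a window, for every SNP pair whose squared Pearson
#' correlation of call vectors (pairwise-complete) exceeds `r2_max`, the
#' later-positioned SNP is dropped. Monomorphic SNPs (zero variance) never
#' trigger a drop. The scan is deterministic.
#'
#' @param gm a `genotype_matrix`
#' @param r2_max squared-correlation cutoff (strict `>` triggers a drop)
#' @param window_snps window width in SNPs (>= 2)
#' @param step_snps step in SNPs
#' @return the pruned `genotype_matrix`, with attribute `"n_pruned"`.
#' @export
ld_prune <- function(gm, r2_max = 0.99, window_snps = 50, step_snps = 5) {
  if (window_snps < 2) stop("window_snps must be >= 2")
  if (step_snps < 1) stop("step_snps must be >= 1")
  keep <- rep(TRUE, n_variants(gm))
  for (chrom in unique(gm$variants$chrom)) {
    idx <- which(gm$variants$chrom == chrom)
    starts <- seq(1, length(idx), by = step_snps)
    for (st in starts) {
      win <- idx[st:min(st + window_snps - 1, length(idx))]
      win <- win[keep[win]]
      if (length(win) < 2) next
      cc <- suppressWarnings(
        stats::cor(gm$calls[, win, drop = FALSE],
                   use = "pairwise.complete.obs"))
      r2 <- cc^2
      for (i in seq_len(length(win) - 1)) {
        if (!keep[win[i]]) next
        for (j in seq(i + 1, length(win))) {
          if (!keep[win[j]]) next
          if (is.finite(r2[i, j]) && r2[i, j] > r2_max) keep[win[j]] <- FALSE
        }
      }
    }
  }
  out <- subset_gm(gm, variants = which(keep))
  attr(out, "n_pruned") <- sum(!keep)
  out
}

#' Release-period presets
#'
#' Two interval schemes for grouping accessions by release year:
#' `"decade"` (1830-1959, then 10-year bins up to 2010-2014) and
#' `"twenty"` (1830-1959, 1960-1979, 1980-1999, 2000-2014).
#'
#' @param scheme `"decade"` or `"twenty"`
#' @return data.frame with columns `start`, `end`, `label`
#' @export
period_presets <- function(scheme = c("decade", "twenty")) {
  scheme <- match.arg(scheme)
  if (scheme == "decade") {
    start <- c(1830, 1960, 1970, 1980, 1990, 2000, 2010)
    end <- c(1959, 1969, 1979, 1989, 1999, 2009, 2014)
  } else {
    start <- c(1830, 1960, 1980, 2000)
    end <- c(1959, 1979, 1999, 2014)
  }
  data.frame(start = start, end = end,
             label = paste(start, end, sep = "-"),
             stringsAsFactors = FALSE)
}

#' Assign release periods from years
#'
#' Labels each accession with the release-period interval enclosing its
#' release year (inclusive bounds). Accessions with no year get `NA`;
#' years outside every interval get `"out-of-range"` with a warning.
#'
#' @param meta accession metadata data.frame with a `release_year` column
#' @param breakpoints a period table as returned by [period_presets()]
#'   (columns `start`, `end`, `label`), or a preset name
#' @return `meta` with a `period` column added/overwritten
#' @export
assign_release_periods <- function(meta, breakpoints = period_presets("decade")) {
  if (is.character(breakpoints)) breakpoints <- period_presets(breakpoints)
  if (any(diff(breakpoints$start) <= 0)) {
    stop("breakpoints must be ascending")
  }
  yr <- meta$release_year
  period <- rep(NA_character_, length(yr))
  for (i in seq_len(nrow(breakpoints))) {
    in_i <- !is.na(yr) & yr >= breakpoints$start[i] & yr <= breakpoints$end[i]
    period[in_i] <- breakpoints$label[i]
  }
  out_of_range <- !is.na(yr) & is.na(period)
  if (any(out_of_range)) {
    warning(sum(out_of_range), " release year(s) outside all intervals; ",
            "labelled 'out-of-range'")
    period[out_of_range] <- "out-of-range"
  }
  meta$period <- period
  meta
}

#' Randomly subsample SNPs without replacement
#'
#' @param gm a `genotype_matrix`
#' @param n number of SNPs to retain (0 < n <= number of SNPs)
#' @param seed integer seed; the selection is reproducible
#' @return a position-sorted `genotype_matrix` of `n` SNPs
#' @export
subsample_variants <- function(gm, n, seed = 1L) {
  nv <- n_variants(gm)
  if (n <= 0 || n > nv) stop("n must be in 1..", nv)
  set.seed(seed)
  idx <- sort(sample.int(nv, n))
  subset_gm(gm, variants = idx)
}
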