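#' Window specification for rolling scans
#'
#' @param mode `"snp-count"` (size/step counted in SNPs) or `"bp"`
#'   (size/step in base pairs)
#' @param size window size (> 0)
#' @param step step between window starts (0 < step <= size)
#' @return a `window_spec` list
#' @export
window_spec <- function(mode = c("snp-count", "bp"), size, step) {
  mode <- match.arg(mode)
  if (size <= 0 || step <= 0) stop("size and step must be > 0")
  if (step > size) stop("step must be <= size")
  structure(list(mode = mode, size = size, step = step),
            class = "window_spec")
}

window_track <- function(rows, spec, statistic) {
  rows <- rows[order(rows$chrom, rows$start_bp), , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows, spec = spec, statistic = statistic,
            class = c("window_track", "data.frame"))
}

#' @export
print.window_track <- function(x, ...) {
  cat("window_track of", attr(x, "statistic"), "-", nrow(x), "windows\n")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("...\n")
  invisible(x)
}

#' Polymorphism information content of one locus
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`, where `p_i` are the
#' allele frequencies of the locus (for a biallelic SNP the vector
#' `(p, 1 - p)`). Zero for monomorphic loci, maximal (0.375 for two
#' alleles) at intermediate frequencies.
#'
#' @param allele_freqs numeric vector of allele frequencies summing to 1
#' @return PIC value in [0, 1]
#' @export
snp_pic <- function(allele_freqs) {
  p <- as.numeric(allele_freqs)
  if (any(p < 0)) stop("allele frequencies must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("allele frequencies must sum to 1")
  s2 <- sum(p^2)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4
  1 - s2 - (s2^2 - sum(p^4))
}

# vectorized biallelic PIC from the alt-allele frequency
pic_biallelic <- function(p) {
  q <- 1 - p
  s2 <- p^2 + q^2
  1 - s2 - (s2^2 - (p^4 + q^4))
}

# windows over SNP indices of one chromosome; trailing partials emitted
snp_count_windows <- function(n, size, step) {
  if (n <= size) return(list(seq_len(n)))
  starts <- seq(1, n, by = step)
  starts <- starts[starts <= n]
  wins <- lapply(starts, function(s) seq(s, min(s + size - 1, n)))
  # drop duplicated trailing windows that add no new SNP
  ends <- vapply(wins, max, 0)
  keep <- c(TRUE, diff(ends) > 0 | diff(vapply(wins, min, 0)) > 0)
  wins[keep]
}

rolling_stat <- function(gm, spec, per_snp, statistic) {
  if (spec$mode != "snp-count") stop("rolling scans use snp-count windows")
  vr <- gm$variants
  out <- list()
  for (chrom in unique(vr$chrom)) {
    idx <- which(vr$chrom == chrom)
    if (length(idx) < spec$size) {
      warning("chromosome ", chrom, " has fewer SNPs (", length(idx),
              ") than one window; emitting a single partial window")
    }
    wins <- snp_count_windows(length(idx), spec$size, spec$step)
    rows <- lapply(wins, function(w) {
      snps <- idx[w]
      vals <- per_snp[snps]
      vals <- vals[!is.na(vals)]  # all-missing SNPs drop out of the mean
      data.frame(chrom = chrom,
                 start_bp = vr$pos[snps[1]],
                 end_bp = vr$pos[snps[length(snps)]],
                 mid_bp = (vr$pos[snps[1]] + vr$pos[snps[length(snps)]]) / 2,
                 n_snps = length(snps),
                 value = if (length(vals)) mean(vals) else NA_real_)
    })
    out[[chrom]] <- do.call(rbind, rows)
  }
  window_track(do.call(rbind, out), spec, statistic)
}

#' Rolling-window PIC scan
#'
#' Mean per-SNP PIC in rolling windows of a fixed SNP count. Allele
#' frequencies are computed over non-missing calls (allele counts
#' `2 * n_hom + n_het`); the window span is the position range of its first
#' and last SNP, and a trailing partial window is emitted with its own SNP
#' count.
#'
#' @param gm a `genotype_matrix`
#' @param spec a snp-count [window_spec()]; default 10,000-SNP windows with
#'   a 1,000-SNP step
#' @param accessions optional accession subset over which frequencies are taken
#' @return a `window_track` with one PIC value per window
#' @export
rolling_pic <- function(gm,
                        spec = window_spec("snp-count", 10000, 1000),
                        accessions = NULL) {
  s <- snp_summary(gm, accessions)
  rolling_stat(gm, spec, pic_biallelic(s$p_alt), "PIC")
}

#' Rolling-window reference-allele frequency scan
#'
#' Mean per-SNP reference-allele frequency
#' `(2 n_hom_ref + n_het) / (2 n_non_missing)` in rolling SNP-count windows.
#' SNPs with all calls missing are excluded from the window mean.
#'
#' @inheritParams rolling_pic
#' @return a `window_track` of reference-allele frequencies
#' @export
rolling_ref_freq <- function(gm,
                             spec = window_spec("snp-count", 10000, 1000),
                             accessions = NULL) {
  s <- snp_summary(gm, accessions)
  rolling_stat(gm, spec, s$p_ref, "ref_freq")
}

#' Write a window track as TSV
#'
#' Columns `chrom,start,end,mid,n_snps,value` with 1-based closed
#' coordinates; `bed = TRUE` writes instead a BED-style 0-based half-open
#' `chrom,start,end,value` table.
#'
#' @param track a `window_track`
#' @param path output path
#' @param bed write BED-style coordinates instead
#' @return `path`, invisibly
#' @export
write_track <- function(track, path, bed = FALSE) {
  df <- as.data.frame(track)
  if (bed) {
    out <- data.frame(chrom = df$chrom, start = df$start_bp - 1,
                      end = df$end_bp, value = df$value)
  } else {
    out <- data.frame(chrom = df$chrom, start = df$start_bp,
                      end = df$end_bp, mid = df$mid_bp,
                      n_snps = df$n_snps, value = df$value)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
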