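# Small fixture builders shared across the suite.

# quick genotype matrix from an accessions x SNPs call matrix
make_gm <- function(calls, pos = NULL, chrom = "1H", build = "toy") {
  calls <- as.matrix(calls)
  nv <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(nv) * 10L
  genotype_matrix(calls, data.frame(chrom = chrom, pos = pos,
                                    ref = rep("A", nv), alt = rep("C", nv)),
                  build = build)
}

# seeded random panel of inbred-style calls with given alt-allele freqs
random_gm <- function(n_acc, n_snp, seed, p_alt = NULL, het = 0,
                      missing = 0) {
  set.seed(seed)
  if (is.null(p_alt)) p_alt <- stats::runif(n_snp, 0.05, 0.95)
  calls <- sapply(p_alt, function(p) ifelse(stats::runif(n_acc) < p, 2L, 0L))
  if (het > 0) calls[matrix(stats::runif(length(calls)) < het,
                            nrow(calls))] <- 1L
  if (missing > 0) calls[matrix(stats::runif(length(calls)) < missing,
                                nrow(calls))] <- NA
  make_gm(calls)
}

# a small temporal panel + anchors, shared by the block-recovery tests
small_sweep_sim <- function(seed, ...) {
  cfg <- sim_config(seed = seed, ...)
  sim <- simulate_panel(cfg)
  hap <- sim$truth$haplotype
  anchors <- c(stats::setNames(1L, names(hap)[hap == 1][1]),
               stats::setNames(2L, names(hap)[hap == 2][1]))
  sim$anchors <- anchors
  sim
}

# window spec matched to the simulator's SNP density (~40 SNPs per window,
# the same count per window as a 100 kbp window at full-scale density)
sim_scan_spec <- function() window_spec("bp", 1e6, 2.5e5)

# write a minimal VCF 4.2 text fixture
write_toy_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
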