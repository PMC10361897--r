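# Independent oracles: scalar, loop-based transcriptions of the published
# estimator formulas, kept deliberately separate from the vectorized
# implementations they check.

# Weir-Cockerham (1984) two-population components at one SNP, from raw
# call vectors (alt-allele dosage 0/1/2, NA = missing)
wc_oracle_snp <- function(g1, g2) {
  g1 <- g1[!is.na(g1)]
  g2 <- g2[!is.na(g2)]
  r <- 2
  n <- c(length(g1), length(g2))
  p <- c(sum(g1) / (2 * n[1]), sum(g2) / (2 * n[2]))
  h <- c(sum(g1 == 1) / n[1], sum(g2 == 1) / n[2])
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cval <- hbar / 2
  c(a = a, b = b, c = cval)
}

# brute-force per-SNP PIC via the exported closed form, averaged per window
pic_window_oracle <- function(gm, snp_idx) {
  vals <- vapply(snp_idx, function(j) {
    g <- gm$calls[, j]
    g <- g[!is.na(g)]
    p_alt <- (2 * sum(g == 2) + sum(g == 1)) / (2 * length(g))
    snp_pic(c(p_alt, 1 - p_alt))
  }, 0)
  mean(vals)
}

# exhaustive pairwise r^2 on a call matrix (pairwise-complete)
max_pairwise_r2 <- function(calls) {
  nv <- ncol(calls)
  best <- 0
  for (i in seq_len(nv - 1)) {
    for (j in seq(i + 1, nv)) {
      ok <- !is.na(calls[, i]) & !is.na(calls[, j])
      if (sum(ok) < 3) next
      if (stats::sd(calls[ok, i]) == 0 || stats::sd(calls[ok, j]) == 0) next
      best <- max(best, stats::cor(calls[ok, i], calls[ok, j])^2)
    }
  }
  best
}
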