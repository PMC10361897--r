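#' Two-level analysis of molecular variance (AMOVA)
#'
#' Partitions the total molecular variance of a panel into among-group and
#' within-group components from a matrix of squared distances between
#' accession call vectors. The distance is the squared Euclidean difference
#' of allele counts, averaged over the SNPs where both accessions have
#' calls (pairwise-complete, rescaled by the shared non-missing count).
#' Components follow the standard sums-of-squares decomposition of a
#' distance matrix; negative component estimates are reported as computed
#' but truncated to zero when percentages are formed, so percentages lie in
#' [0, 100] and sum to 100. An optional permutation test shuffles group
#' labels to obtain a p-value for the among-group component.
#'
#' @param gm a `genotype_matrix`
#' @param partition named vector of group labels (see
#'   [pairwise_group_fst()]); single-member groups are allowed (they
#'   contribute no within-group degrees of freedom) but at least one group
#'   must have two members
#' @param n_permutations number of label permutations (0 = no test)
#' @param seed integer seed for the permutations
#' @return an `amova_result` list: `ss` (sums of squares), `df`,
#'   `ms`, `components` (raw sigma2), `percent`, `phi` (among-group
#'   fraction), `n0` (average group size coefficient), `p_value`
#' @export
amova <- function(gm, partition, n_permutations = 0, seed = 1L) {
  part <- align_partition(gm, partition)
  if (length(unique(part)) < 2) stop("need at least two groups")
  if (all(table(part) == 1)) stop("all groups are singletons")
  d2 <- squared_ibs_distance(gm)
  res <- amova_from_d2(d2, part)
  if (n_permutations > 0) {
    set.seed(seed)
    obs <- res$components["among"]
    perm <- replicate(n_permutations, {
      amova_from_d2(d2, sample(part))$components["among"]
    })
    res$p_value <- (sum(perm >= obs) + 1) / (n_permutations + 1)
    res$permuted_among <- unname(perm)
  }
  res
}

# mean squared allele-count difference over shared non-missing SNPs
squared_ibs_distance <- function(gm) {
  x <- gm$calls
  m <- !is.na(x)
  a <- x
  a[!m] <- 0L
  storage.mode(a) <- "double"
  storage.mode(m) <- "double"
  sq <- a^2
  g1 <- sq %*% t(m)          # sum of g_i^2 over SNPs where j is observed
  cross <- a %*% t(a)
  nshared <- m %*% t(m)
  if (any(nshared[upper.tri(nshared)] == 0)) {
    idx <- which(nshared == 0 & upper.tri(nshared), arr.ind = TRUE)[1, ]
    stop("no shared non-missing SNPs between ", rownames(x)[idx[1]],
         " and ", rownames(x)[idx[2]])
  }
  d2 <- (g1 + t(g1) - 2 * cross) / nshared
  diag(d2) <- 0
  d2
}

amova_from_d2 <- function(d2, part) {
  n <- nrow(d2)
  groups <- unique(part)
  g <- length(groups)
  ut <- upper.tri(d2)
  ssd_total <- sum(d2[ut]) / n
  ssd_within <- 0
  sizes <- numeric(g)
  for (k in seq_len(g)) {
    idx <- which(part == groups[k])
    sizes[k] <- length(idx)
    if (length(idx) > 1) {
      dk <- d2[idx, idx, drop = FALSE]
      ssd_within <- ssd_within + sum(dk[upper.tri(dk)]) / length(idx)
    }
  }
  ssd_among <- ssd_total - ssd_within
  df_among <- g - 1
  df_within <- n - g
  ms_among <- ssd_among / df_among
  ms_within <- ssd_within / df_within
  n0 <- (n - sum(sizes^2) / n) / (g - 1)
  sigma_within <- ms_within
  sigma_among <- (ms_among - ms_within) / n0
  comp <- c(among = sigma_among, within = sigma_within)
  trunc <- pmax(comp, 0)
  percent <- if (sum(trunc) > 0) 100 * trunc / sum(trunc) else c(among = 0, within = 100)
  structure(list(ss = c(among = ssd_among, within = ssd_within,
                        total = ssd_total),
                 df = c(among = df_among, within = df_within,
                        total = n - 1),
                 ms = c(among = ms_among, within = ms_within),
                 components = comp,
                 percent = percent,
                 phi = unname(percent["among"]) / 100,
                 n0 = n0,
                 p_value = NA_real_),
            class = "amova_result")
}

#' @export
print.amova_result <- function(x, ...) {
  cat("AMOVA (two-level)\n")
  tab <- data.frame(df = x$df[1:2], SS = x$ss[1:2], MS = x$ms,
                    sigma2 = x$components, percent = x$percent)
  print(round(tab, 4))
  if (!is.na(x$p_value)) cat("permutation p-value:", x$p_value, "\n")
  invisible(x)
}
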