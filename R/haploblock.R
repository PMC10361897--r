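#' Delineate a non-recombining haplotype block from a windowed FST track
#'
#' Windows with value `>= threshold` form runs; runs on the same chromosome
#' separated by at most `max_gap` sub-threshold windows are merged. The
#' merged run with the longest base-pair span (ties: leftmost) and at least
#' `min_windows` contributing (above-threshold) windows is returned; its
#' boundaries are the first contributing window's `start_bp` and the last
#' contributing window's `end_bp`. Secondary qualifying runs are reported
#' in an attribute.
#'
#' @param track a windowed-FST `window_track`
#' @param threshold FST threshold (default 0.7)
#' @param min_windows minimum number of contributing windows (default 5)
#' @param max_gap maximum number of consecutive sub-threshold windows
#'   bridged inside a run (default 2)
#' @param build genome-build tag recorded on the block
#' @return a `haplo_block` list (`chrom`, `start_bp`, `end_bp`,
#'   `threshold`, `window_idx`, `n_windows`) or `NULL` when no run
#'   qualifies. Secondary runs are in `attr(, "secondary")`.
#' @export
delineate_block <- function(track, threshold = 0.7, min_windows = 5,
                            max_gap = 2, build = "unknown") {
  df <- as.data.frame(track)
  runs <- list()
  for (chrom in unique(df$chrom)) {
    w <- df[df$chrom == chrom, , drop = FALSE]
    w <- w[order(w$start_bp), , drop = FALSE]
    hot <- which(w$value >= threshold)
    if (length(hot) == 0) next
    # merge consecutive hot windows separated by <= max_gap cool windows
    grp <- cumsum(c(1, diff(hot) > max_gap + 1))
    for (g in unique(grp)) {
      members <- hot[grp == g]
      if (length(members) < min_windows) next
      runs[[length(runs) + 1]] <- list(
        chrom = chrom,
        start_bp = w$start_bp[members[1]],
        end_bp = w$end_bp[members[length(members)]],
        threshold = threshold,
        window_idx = members,
        n_windows = length(members),
        build = build)
    }
  }
  if (length(runs) == 0) return(NULL)
  spans <- vapply(runs, function(r) r$end_bp - r$start_bp, 0)
  best <- which.max(spans)  # ties resolve to the leftmost (first) run
  block <- structure(runs[[best]], class = "haplo_block")
  attr(block, "secondary") <- runs[-best]
  block
}

#' @export
print.haplo_block <- function(x, ...) {
  cat(sprintf("haplo_block %s:%.0f-%.0f (%.2f Mbp, %d windows >= %.2f)\n",
              x$chrom, x$start_bp, x$end_bp,
              (x$end_bp - x$start_bp) / 1e6, x$n_windows, x$threshold))
  invisible(x)
}

#' Extract the SNPs of a haplotype block (plus flanks)
#'
#' @param gm a `genotype_matrix`
#' @param block a `haplo_block` (or any list with `chrom`, `start_bp`,
#'   `end_bp`)
#' @param flank_bp flank added on each side (default 10,000)
#' @return the `genotype_matrix` restricted to
#'   `[start_bp - flank_bp, end_bp + flank_bp]` on the block chromosome
#' @export
extract_block_snps <- function(gm, block, flank_bp = 10000) {
  vr <- gm$variants
  keep <- vr$chrom == block$chrom &
    vr$pos >= block$start_bp - flank_bp &
    vr$pos <= block$end_bp + flank_bp
  if (!any(keep)) stop("no SNPs in block region ", block$chrom, ":",
                       block$start_bp, "-", block$end_bp)
  subset_gm(gm, variants = which(keep))
}

#' Assign block haplotypes by anchored clustering
#'
#' Orders the accessions by PCoA of the identity-by-state distance over
#' the block SNPs, k-means-clusters the leading coordinates, and names
#' each cluster after the haplotype of the anchor accessions it contains.
#' A cluster containing anchors of two different declared haplotypes is an
#' error (increase `k`, as when a coarse clustering merges distinct
#' haplotypes); anchor-free clusters receive fresh labels above the anchor
#' range. Accessions whose distance to their cluster centroid exceeds
#' `max_z` within-cluster standard deviations are labelled unassigned
#' (`NA`) rather than forced.
#'
#' @param block_gm a `genotype_matrix` restricted to the block
#' @param k number of clusters (>= number of distinct anchor labels)
#' @param anchors named integer vector: names = accession ids, values =
#'   declared haplotype labels (positive integers)
#' @param seed integer seed for k-means
#' @param n_axes number of leading PCoA axes clustered (default 10)
#' @param max_z unassignability z-score threshold (default `Inf` = off)
#' @return a `haplotype_assignment` data.frame with columns `accession`,
#'   `haplotype`, `cluster`, `dist_to_centroid`, `is_anchor`; attributes
#'   `k`, `seed`, `anchors`
#' @export
assign_haplotypes <- function(block_gm, k, anchors, seed = 1L,
                              n_axes = 10, max_z = Inf) {
  anchors <- validate_anchors(anchors)
  ids <- accession_ids(block_gm)
  if (!all(names(anchors) %in% ids)) {
    stop("anchor accession(s) not in matrix: ",
         paste(setdiff(names(anchors), ids), collapse = ", "))
  }
  if (k < length(unique(anchors))) {
    stop("k must be >= number of distinct anchor labels")
  }
  ord <- pcoa(ibs_distance(block_gm))
  coords <- ord$coordinates[, seq_len(min(n_axes, ncol(ord$coordinates))),
                            drop = FALSE]
  k_eff <- min(k, nrow(unique(round(coords, 12))))
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k_eff, nstart = 50, iter.max = 200)
  cl <- km$cluster

  # clusters inherit their anchors' label; mixed anchors are an error
  label_of <- rep(NA_integer_, k_eff)
  for (j in seq_len(k_eff)) {
    in_j <- anchors[names(anchors) %in% ids[cl == j]]
    if (length(unique(in_j)) > 1) {
      stop("cluster ", j, " contains anchors of haplotypes ",
           paste(sort(unique(in_j)), collapse = " and "),
           "; increase k until anchor haplotypes separate")
    }
    if (length(in_j)) label_of[j] <- in_j[1]
  }
  fresh <- if (length(anchors)) max(anchors) else 0L
  for (j in which(is.na(label_of))) {
    fresh <- fresh + 1L
    label_of[j] <- fresh
  }

  d2c <- sqrt(rowSums((coords - km$centers[cl, , drop = FALSE])^2))
  z <- rep(0, length(d2c))
  for (j in seq_len(k_eff)) {
    in_j <- cl == j
    s <- stats::sd(d2c[in_j])
    if (sum(in_j) > 2 && is.finite(s) && s > 0) {
      z[in_j] <- (d2c[in_j] - mean(d2c[in_j])) / s
    }
  }
  hap <- label_of[cl]
  hap[z > max_z] <- NA_integer_

  out <- data.frame(accession = ids, haplotype = hap, cluster = cl,
                    dist_to_centroid = d2c,
                    is_anchor = ids %in% names(anchors),
                    stringsAsFactors = FALSE)
  structure(out, k = k_eff, seed = seed, anchors = anchors,
            class = c("haplotype_assignment", "data.frame"))
}

validate_anchors <- function(anchors) {
  if (is.data.frame(anchors)) {
    anchors <- stats::setNames(as.integer(anchors$haplotype),
                               anchors$accession)
  }
  if (length(anchors) < 1 || is.null(names(anchors))) {
    stop("anchors must be a named vector (accession -> haplotype label)")
  }
  anchors <- stats::setNames(as.integer(anchors), names(anchors))
  if (any(anchors < 1)) stop("haplotype labels must be positive integers")
  anchors
}

#' Haplotype frequency trajectory over release periods
#'
#' Counts and frequencies of each haplotype per release period, over the
#' accessions that have both a period and an assigned haplotype.
#' Frequencies within each non-empty period sum to 1; periods with no
#' assigned accession are emitted with `n = 0` and `NA` frequencies.
#'
#' @param assignment a `haplotype_assignment`
#' @param meta accession metadata with `id` and `release_year`
#' @param breakpoints period table or preset name (see
#'   [assign_release_periods()])
#' @return data.frame with columns `period`, `haplotype`, `n`,
#'   `n_period`, `frequency`
#' @export
haplotype_trajectory <- function(assignment, meta,
                                 breakpoints = period_presets("decade")) {
  if (is.character(breakpoints)) breakpoints <- period_presets(breakpoints)
  meta <- assign_release_periods(meta, breakpoints)
  hap <- assignment$haplotype[match(meta$id, assignment$accession)]
  ok <- !is.na(hap) & !is.na(meta$period) & meta$period != "out-of-range"
  haps <- sort(unique(hap[ok]))
  rows <- list()
  for (p in breakpoints$label) {
    in_p <- ok & meta$period == p
    np <- sum(in_p)
    for (h in haps) {
      rows[[length(rows) + 1]] <- data.frame(
        period = p, haplotype = h,
        n = sum(hap[in_p] == h), n_period = np,
        frequency = if (np > 0) sum(hap[in_p] == h) / np else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Project an external collection onto the panel's haplotypes
#'
#' Matches SNPs between the panel block matrix and an external genotype
#' matrix by (chrom, pos, ref, alt), applies the region filters (per-SNP
#' missingness and minor allele count on the combined matrix; external
#' accessions exceeding `max_missing` missing calls over the shared SNPs
#' are excluded), then clusters the panel anchor accessions together with
#' the external accessions and labels external accessions through the
#' anchor-bearing clusters.
#'
#' @param panel_block_gm panel `genotype_matrix` restricted to the block
#' @param external_gm external-collection `genotype_matrix`
#' @param anchors named haplotype anchors from the panel
#' @param k number of clusters for the combined analysis
#' @param max_missing missing-data threshold (default 0.20)
#' @param min_mac minimum minor allele count per SNP (default 1)
#' @param seed integer seed
#' @return a `haplotype_assignment` restricted to the external accessions;
#'   attributes `shared_snps`, `dropped_mismatch`, `excluded_accessions`
#' @export
project_accessions <- function(panel_block_gm, external_gm, anchors, k,
                               max_missing = 0.20, min_mac = 1, seed = 1L) {
  anchors <- validate_anchors(anchors)
  if (!identical(panel_block_gm$build, external_gm$build)) {
    stop("genome builds differ (", panel_block_gm$build, " vs ",
         external_gm$build, "); supply coordinates on a common build ",
         "via a region mapping before projecting")
  }
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = "_")
  poskey <- function(v) paste(v$chrom, v$pos, sep = "_")
  pk <- key(panel_block_gm$variants); ek <- key(external_gm$variants)
  shared <- intersect(pk, ek)
  dropped_mismatch <- length(intersect(poskey(panel_block_gm$variants),
                                       poskey(external_gm$variants))) -
    length(shared)
  if (length(shared) < 100) {
    stop("only ", length(shared),
         " shared SNPs between panel and collection (< 100): ",
         "insufficient resolution for projection")
  }
  panel <- subset_gm(panel_block_gm, accessions = names(anchors),
                     variants = match(shared, pk))
  ext <- subset_gm(external_gm, variants = match(shared, ek))

  miss_frac <- rowMeans(is.na(ext$calls))
  excluded <- accession_ids(ext)[miss_frac > max_missing]
  if (length(excluded) == nrow(ext$calls)) {
    stop("all external accessions exceed the missing-data threshold")
  }
  ext <- subset_gm(ext, accessions = which(miss_frac <= max_missing))

  combined <- genotype_matrix(rbind(panel$calls, ext$calls),
                              panel$variants, build = panel$build)
  s <- snp_summary(combined)
  mac <- pmin(2 * s$n0 + s$n1, 2 * s$n2 + s$n1)
  keep <- mac >= min_mac & s$miss <= max_missing
  if (sum(keep) < 100) {
    stop("fewer than 100 shared SNPs remain after region filters")
  }
  combined <- subset_gm(combined, variants = which(keep))

  asg <- assign_haplotypes(combined, k = k, anchors = anchors, seed = seed)
  out <- asg[!(asg$accession %in% names(anchors)), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, k = attr(asg, "k"), seed = seed, anchors = anchors,
            shared_snps = sum(keep), dropped_mismatch = dropped_mismatch,
            excluded_accessions = excluded,
            class = c("haplotype_assignment", "data.frame"))
}

#' Geographic frequency of a target haplotype
#'
#' Per country and passport category value: the number of accessions, the
#' number carrying the target haplotype and its frequency. Country/category
#' cells with fewer than `min_n` accessions are excluded (listed, not
#' zero-filled).
#'
#' @param assignment a `haplotype_assignment` (panel or projected)
#' @param passport data.frame with `accession`, `country` and the category
#'   column
#' @param target_label haplotype label of interest
#' @param category name of the passport column to stratify by
#'   (e.g. `"cultivation_status"`, `"row_type"`, `"growth_habit"`)
#' @param min_n minimum accessions per (country, category value) row
#'   (default 15)
#' @return data.frame `country`, `category_value`, `n`, `n_target`,
#'   `frequency`; excluded rows in `attr(, "excluded")`
#' @export
geographic_frequency <- function(assignment, passport, target_label,
                                 category, min_n = 15) {
  if (!category %in% names(passport)) {
    stop("unknown passport category: ", category)
  }
  hap <- assignment$haplotype[match(passport$accession,
                                    assignment$accession)]
  ok <- !is.na(hap) & !is.na(passport$country)
  tab <- data.frame(country = passport$country[ok],
                    category_value = passport[[category]][ok],
                    target = hap[ok] == target_label)
  agg <- stats::aggregate(target ~ country + category_value, data = tab,
                          FUN = function(v) c(n = length(v),
                                              n_target = sum(v)))
  out <- data.frame(country = agg$country,
                    category_value = agg$category_value,
                    n = agg$target[, "n"],
                    n_target = agg$target[, "n_target"])
  out$frequency <- out$n_target / out$n
  small <- out$n < min_n
  excluded <- out[small, c("country", "category_value", "n")]
  out <- out[!small, , drop = FALSE]
  out <- out[order(out$country, out$category_value), , drop = FALSE]
  rownames(out) <- rownames(excluded) <- NULL
  structure(out, excluded = excluded, min_n = min_n,
            target_label = target_label)
}

#' Graphical-genotype export of a block region
#'
#' Recodes a (possibly subsampled) block region as
#' `ref-hom` / `het` / `alt-hom` / `missing`, rows grouped contiguously by
#' haplotype label and columns position-sorted, for external plotting.
#'
#' @param gm a `genotype_matrix`
#' @param block a `haplo_block`
#' @param flank_bp flank in bp (default 10,000)
#' @param n_snps optional number of randomly kept SNPs (seeded)
#' @param seed integer seed for the SNP subsample
#' @param order_by named vector of haplotype labels per accession
#'   (e.g. from a `haplotype_assignment`)
#' @param path optional TSV output path
#' @return a character data.frame (accessions x SNPs) with a `haplotype`
#'   first column, invisibly if written to `path`
#' @export
graphical_genotypes <- function(gm, block, flank_bp = 10000, n_snps = NULL,
                                seed = 1L, order_by = NULL, path = NULL) {
  sub <- extract_block_snps(gm, block, flank_bp)
  if (!is.null(n_snps)) {
    if (n_snps > n_variants(sub)) stop("n_snps exceeds SNPs available")
    sub <- subsample_variants(sub, n_snps, seed)
  }
  codes <- c(`0` = "ref-hom", `1` = "het", `2` = "alt-hom")
  mat <- matrix(codes[as.character(sub$calls)], nrow = nrow(sub$calls),
                dimnames = dimnames(sub$calls))
  mat[is.na(sub$calls)] <- "missing"
  hap <- if (is.null(order_by)) rep(NA_integer_, nrow(mat)) else
    order_by[rownames(mat)]
  ord <- order(hap, rownames(mat))
  out <- data.frame(accession = rownames(mat)[ord], haplotype = hap[ord],
                    mat[ord, , drop = FALSE], check.names = FALSE,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
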