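#' End-to-end block recovery from a temporal panel
#'
#' Convenience driver chaining the sweep-detection stages: windowed
#' Weir-Cockerham FST between the earliest and latest release-period
#' groups, thresholded-run block delineation, anchored haplotype
#' assignment over the block SNPs, and the haplotype frequency trajectory
#' over release periods.
#'
#' @param gm a `genotype_matrix`
#' @param meta accession metadata with `release_year`
#' @param anchors named haplotype anchors (accession -> label)
#' @param breakpoints release-period table or preset name
#' @param spec windowed-FST [window_spec()] (default 100 kbp / 10 kbp)
#' @param threshold,min_windows,max_gap block delineation parameters
#' @param flank_bp flank around the detected block (default 10,000)
#' @param k number of clusters for haplotype assignment
#' @param seed integer seed
#' @return list with `track`, `block`, `assignment`, `trajectory`
#' @export
recover_block <- function(gm, meta, anchors,
                          breakpoints = period_presets("decade"),
                          spec = window_spec("bp", 100000, 10000),
                          threshold = 0.7, min_windows = 5, max_gap = 2,
                          flank_bp = 10000, k = 2, seed = 1L) {
  if (is.character(breakpoints)) breakpoints <- period_presets(breakpoints)
  meta <- assign_release_periods(meta, breakpoints)
  present <- breakpoints$label[breakpoints$label %in% meta$period]
  early <- meta$id[!is.na(meta$period) & meta$period == present[1]]
  late <- meta$id[!is.na(meta$period) &
                    meta$period == present[length(present)]]
  track <- windowed_fst(gm, early, late, spec)
  block <- delineate_block(track, threshold, min_windows, max_gap,
                           build = gm$build)
  if (is.null(block)) {
    return(list(track = track, block = NULL, assignment = NULL,
                trajectory = NULL))
  }
  block_gm <- extract_block_snps(gm, block, flank_bp)
  assignment <- assign_haplotypes(block_gm, k = k, anchors = anchors,
                                  seed = seed)
  trajectory <- haplotype_trajectory(assignment, meta, breakpoints)
  list(track = track, block = block, assignment = assignment,
       trajectory = trajectory)
}

#' Simultaneous binomial envelope of the generating logistic sweep
#'
#' For each release period, the count of target-haplotype carriers in a
#' simulated panel is (approximately) binomial with the period's mean
#' logistic probability. This returns a simultaneous `level` envelope for
#' the whole trajectory: per-period binomial quantiles at Bonferroni-
#' adjusted tails, so the entire observed trajectory falls inside with
#' probability at least `level`.
#'
#' @param truth the `truth` element of [simulate_panel()]
#' @param breakpoints release-period table or preset name
#' @param level simultaneous coverage level (default 0.95)
#' @return data.frame `period`, `n`, `p_mean`, `lower`, `upper` (counts)
#' @export
trajectory_envelope <- function(truth, breakpoints = period_presets("decade"),
                                level = 0.95) {
  if (is.character(breakpoints)) breakpoints <- period_presets(breakpoints)
  years <- truth$years
  p <- truth$p_target
  rows <- list()
  occupied <- vapply(seq_len(nrow(breakpoints)), function(i) {
    sum(years >= breakpoints$start[i] & years <= breakpoints$end[i]) > 0
  }, TRUE)
  alpha <- (1 - level) / max(1, sum(occupied))
  for (i in seq_len(nrow(breakpoints))) {
    in_p <- years >= breakpoints$start[i] & years <= breakpoints$end[i]
    n <- sum(in_p)
    pm <- if (n > 0) mean(p[in_p]) else NA_real_
    rows[[i]] <- data.frame(
      period = breakpoints$label[i], n = n, p_mean = pm,
      lower = if (n > 0) stats::qbinom(alpha / 2, n, pm) else NA_integer_,
      upper = if (n > 0) stats::qbinom(1 - alpha / 2, n, pm) else NA_integer_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
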