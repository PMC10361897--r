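#' Configuration for the synthetic temporal panel
#'
#' Encodes the study conditions the generator emulates: a panel of inbred
#' accessions released over ~190 years, genotyped at independent background
#' SNPs plus a pericentromeric block of non-recombining haplotypes whose
#' target haplotype frequency follows a logistic sweep
#' `P(target | year) = 1 / (1 + exp(-rate * (year - midpoint)))`. Sizes are
#' scaled roughly 100x down from a full breeding-panel dataset so that the
#' complete validation suite runs in minutes.
#'
#' @param seed integer master seed (all generator randomness derives from it)
#' @param n_accessions panel size (default 200)
#' @param year_range release-year span (default 1830-2014)
#' @param periods release-period table (default the decade presets);
#'   accessions are spread evenly over periods, uniformly within each
#' @param chrom,chrom_length_bp single simulated chromosome (default
#'   `"5H"`, 500 Mbp)
#' @param n_background_snps independent background SNPs outside the block
#'   (default 20,000)
#' @param block_start_bp,block_end_bp block coordinates (default
#'   50-150 Mbp)
#' @param n_block_snps SNPs inside the block (default 2,000)
#' @param n_haplotypes number of block haplotypes H >= 2 (default 2);
#'   haplotypes 3+ are minority haplotypes drawn at `minority_freq` each
#' @param divergence fraction of block SNPs fixed-different between
#'   haplotype pairs (default 0.5)
#' @param minority_freq per-accession probability of each minority
#'   haplotype (default 0.03 when H > 2)
#' @param sweep_midpoint,sweep_rate logistic sweep parameters (default
#'   1975 and 0.15 per year)
#' @param freq_beta Beta(a, b) law of the background reference-allele
#'   frequency (default uniform, `c(1, 1)`)
#' @param drift_rate optional per-year logit drift of background
#'   frequencies creating a temporal ordination gradient (default 0)
#' @param het_rate residual-heterozygosity rate per call (default 0.005)
#' @param missing_rate missing-call rate (default 0.02)
#' @param external external-collection spec: data.frame `country`, `n`,
#'   `target_freq` plus `snp_keep_frac` attribute; see
#'   [simulate_external_collection()]
#' @param expression expression spec: list `n_genes`, `n_up`, `n_down`,
#'   `effect` (log2 units), `sigma`, `n_tissues`, `baseline_mean`,
#'   `baseline_sd`
#' @return a validated `sim_config` list
#' @export
sim_config <- function(seed = 1L,
                       n_accessions = 200,
                       year_range = c(1830, 2014),
                       periods = period_presets("decade"),
                       chrom = "5H",
                       chrom_length_bp = 5e8,
                       n_background_snps = 20000,
                       block_start_bp = 5e7,
                       block_end_bp = 1.5e8,
                       n_block_snps = 2000,
                       n_haplotypes = 2,
                       divergence = 0.5,
                       minority_freq = if (n_haplotypes > 2) 0.03 else 0,
                       sweep_midpoint = 1975,
                       sweep_rate = 0.15,
                       freq_beta = c(1, 1),
                       drift_rate = 0,
                       het_rate = 0.005,
                       missing_rate = 0.02,
                       external = default_external_spec(),
                       expression = default_expression_spec()) {
  cfg <- as.list(environment())
  if (cfg$n_haplotypes < 2) stop("need at least 2 block haplotypes")
  for (p in c(cfg$divergence, cfg$het_rate, cfg$missing_rate,
              cfg$minority_freq)) {
    if (p < 0 || p > 1) stop("rates and divergence must lie in [0, 1]")
  }
  if (cfg$block_start_bp >= cfg$block_end_bp ||
      cfg$block_start_bp < 1 || cfg$block_end_bp > cfg$chrom_length_bp) {
    stop("block must lie inside the chromosome")
  }
  if (!is.null(cfg$external) &&
      any(cfg$external$target_freq < 0 | cfg$external$target_freq > 1)) {
    stop("external per-country target frequencies must lie in [0, 1]")
  }
  ex <- cfg$expression
  if (ex$n_up + ex$n_down > ex$n_genes) {
    stop("n_up + n_down exceeds the number of simulated genes")
  }
  if (ex$sigma <= 0) stop("expression noise sigma must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

#' @rdname sim_config
#' @export
default_external_spec <- function() {
  # per-country target-haplotype frequencies spanning a north-south style
  # gradient, with the highest frequencies in the putative source region
  data.frame(country = c("MAR", "TUN", "DZA", "ESP", "DEU", "SWE"),
             n = c(60, 60, 60, 60, 60, 60),
             target_freq = c(0.85, 0.65, 0.55, 0.45, 0.15, 0.05),
             stringsAsFactors = FALSE)
}

#' @rdname sim_config
#' @export
default_expression_spec <- function() {
  list(n_genes = 850, n_up = 46, n_down = 2, effect = 4, sigma = 0.5,
       n_tissues = 6, baseline_mean = 3, baseline_sd = 1.5)
}

# deterministic base layer shared by panel and external collection:
# variant records, background allele frequencies, block haplotype vectors
sim_base <- function(config) {
  set.seed(config$seed)
  in_block_range <- function(pos) {
    pos >= config$block_start_bp & pos <= config$block_end_bp
  }
  bg_pos <- sort(sample.int(config$chrom_length_bp, config$n_background_snps * 2))
  bg_pos <- bg_pos[!in_block_range(bg_pos)][seq_len(config$n_background_snps)]
  bl_span <- config$block_end_bp - config$block_start_bp + 1
  bl_pos <- sort(config$block_start_bp - 1 +
                   sample.int(bl_span, config$n_block_snps))
  pos <- c(bg_pos, bl_pos)
  is_block <- c(rep(FALSE, length(bg_pos)), rep(TRUE, length(bl_pos)))
  ord <- order(pos)
  pos <- pos[ord]; is_block <- is_block[ord]
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1), "")
  variants <- data.frame(chrom = config$chrom, pos = pos, ref = ref,
                         alt = alt, stringsAsFactors = FALSE)

  p_ref_bg <- stats::rbeta(sum(!is_block), config$freq_beta[1],
                           config$freq_beta[2])
  # haplotype vectors over block SNPs, coded as alt-allele counts {0, 2}
  nb <- sum(is_block)
  p_ref_bl <- stats::rbeta(nb, config$freq_beta[1], config$freq_beta[2])
  hap <- matrix(0L, config$n_haplotypes, nb)
  hap[1, ] <- ifelse(stats::runif(nb) < p_ref_bl, 0L, 2L)
  for (h in seq(2, config$n_haplotypes)) {
    flip <- sample.int(nb, round(config$divergence * nb))
    hap[h, ] <- hap[1, ]
    hap[h, flip] <- 2L - hap[h, flip]
  }
  list(variants = variants, is_block = is_block,
       p_ref_bg = p_ref_bg, hap = hap)
}

#' Simulate a temporal breeding panel with a sweeping haplotype block
#'
#' Background SNP calls are drawn independently per accession from per-SNP
#' reference-allele frequencies (optionally drifting with release year);
#' block SNP calls are copied verbatim from the accession's assigned
#' haplotype vector, so the block is perfectly non-recombining. The target
#' haplotype (label 2) is assigned with the logistic sweep probability;
#' residual heterozygous calls and missing calls are injected at the
#' configured rates. Fully reproducible from `config$seed`.
#'
#' @param config a [sim_config()]
#' @return a list with `genotypes` (a `genotype_matrix`), `meta`
#'   (accession metadata with release years), and `truth` (per-accession
#'   true haplotype, true block boundaries, block SNP positions and the
#'   generating logistic curve)
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  base <- sim_base(config)
  n <- config$n_accessions
  ids <- sprintf("ACC%03d", seq_len(n))

  # accessions spread evenly over the release periods, uniform year within
  per <- config$periods
  n_per <- rep(floor(n / nrow(per)), nrow(per))
  extra <- n - sum(n_per)
  if (extra > 0) n_per[seq_len(extra)] <- n_per[seq_len(extra)] + 1
  years <- unlist(lapply(seq_len(nrow(per)), function(i) {
    span <- seq(per$start[i], per$end[i])
    span[sample.int(length(span), n_per[i], replace = TRUE)]
  }))
  years <- sort(years)

  # logistic sweep of the target haplotype (label 2)
  p_target <- stats::plogis(config$sweep_rate * (years - config$sweep_midpoint))
  hap_id <- ifelse(stats::runif(n) < p_target, 2L, 1L)
  if (config$n_haplotypes > 2 && config$minority_freq > 0) {
    for (h in seq(3, config$n_haplotypes)) {
      hap_id[stats::runif(n) < config$minority_freq] <- h
    }
  }

  nv <- nrow(base$variants)
  calls <- matrix(0L, n, nv)
  bg_idx <- which(!base$is_block)
  bl_idx <- which(base$is_block)
  p_alt_bg <- 1 - base$p_ref_bg
  if (config$drift_rate != 0) {
    mid_year <- mean(config$year_range)
    for (i in seq_len(n)) {
      p_i <- stats::plogis(stats::qlogis(pmin(pmax(p_alt_bg, 1e-6), 1 - 1e-6)) +
                             config$drift_rate * (years[i] - mid_year))
      calls[i, bg_idx] <- ifelse(stats::runif(length(bg_idx)) < p_i, 2L, 0L)
    }
  } else {
    u <- matrix(stats::runif(n * length(bg_idx)), n)
    calls[, bg_idx] <- ifelse(sweep(u, 2, p_alt_bg, `<`), 2L, 0L)
  }
  calls[, bl_idx] <- base$hap[hap_id, , drop = FALSE]

  if (config$het_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < config$het_rate,
                 nrow(calls))] <- 1L
  }
  if (config$missing_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < config$missing_rate,
                 nrow(calls))] <- NA
  }
  rownames(calls) <- ids
  gm <- genotype_matrix(calls, base$variants, build = "synthetic")

  meta <- empty_meta(ids)
  meta$release_year <- years
  meta$country <- sample(c("DEU", "GBR", "FRA", "DNK", "SWE", "NLD"),
                         n, replace = TRUE)
  meta$row_type <- "two-rowed"
  meta$growth_habit <- "spring"
  meta <- assign_release_periods(meta, per)

  truth <- list(haplotype = stats::setNames(hap_id, ids),
                years = stats::setNames(years, ids),
                block = list(chrom = config$chrom,
                             start_bp = config$block_start_bp,
                             end_bp = config$block_end_bp),
                block_snp_pos = base$variants$pos[bl_idx],
                logistic = list(midpoint = config$sweep_midpoint,
                                rate = config$sweep_rate),
                p_target = stats::setNames(p_target, ids))
  list(genotypes = gm, meta = meta, truth = truth)
}

#' Simulate an external germplasm collection sharing the panel haplotypes
#'
#' Draws gene-bank style accessions per country with configured target-
#' haplotype frequencies, re-using the panel's block haplotype vectors
#' (regenerated deterministically from the same seed). The SNP set is
#' thinned to `snp_keep_frac` of the panel SNPs to exercise shared-SNP
#' matching. Passport data carry country, cultivation status, row type and
#' growth habit.
#'
#' @param config a [sim_config()] with an `external` spec
#' @param snp_keep_frac fraction of panel SNPs retained (default 0.5)
#' @return list with `genotypes`, `passport`, `truth` (true haplotype per
#'   external accession)
#' @export
simulate_external_collection <- function(config, snp_keep_frac = 0.5) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$external
  if (is.null(ex)) stop("config has no external-collection spec")
  base <- sim_base(config)
  set.seed(config$seed + 1000003L)

  n <- sum(ex$n)
  ids <- sprintf("EXT%04d", seq_len(n))
  country <- rep(ex$country, ex$n)
  p2 <- rep(ex$target_freq, ex$n)
  hap_id <- ifelse(stats::runif(n) < p2, 2L, 1L)

  nv <- nrow(base$variants)
  bg_idx <- which(!base$is_block)
  bl_idx <- which(base$is_block)
  calls <- matrix(0L, n, nv)
  u <- matrix(stats::runif(n * length(bg_idx)), n)
  calls[, bg_idx] <- ifelse(sweep(u, 2, 1 - base$p_ref_bg, `<`), 2L, 0L)
  calls[, bl_idx] <- base$hap[hap_id, , drop = FALSE]
  if (config$het_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < config$het_rate,
                 nrow(calls))] <- 1L
  }
  if (config$missing_rate > 0) {
    calls[matrix(stats::runif(length(calls)) < config$missing_rate,
                 nrow(calls))] <- NA
  }
  rownames(calls) <- ids
  keep <- sort(sample.int(nv, round(snp_keep_frac * nv)))
  gm <- genotype_matrix(calls[, keep, drop = FALSE],
                        base$variants[keep, , drop = FALSE],
                        build = "synthetic")
  passport <- data.frame(
    accession = ids, country = country,
    cultivation_status = sample(c("landrace", "cultivar"), n, replace = TRUE),
    row_type = sample(c("two-rowed", "six-rowed"), n, replace = TRUE),
    growth_habit = sample(c("spring", "winter"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  truth <- list(haplotype = stats::setNames(hap_id, ids),
                target_freq = stats::setNames(ex$target_freq, ex$country))
  list(genotypes = gm, passport = passport, truth = truth)
}

#' Simulate haplotype-coupled gene expression
#'
#' Baseline log2 cpm per gene is Normal(`baseline_mean`, `baseline_sd`),
#' i.i.d. noise Normal(0, `sigma`) over accessions and tissues; the first
#' `n_up` genes add `+effect` and the next `n_down` genes `-effect` in
#' every tissue for carriers of the target haplotype (label 2). Carriers
#' of minority haplotypes get a variable partial effect, mirroring block
#' variants that follow neither main expression pattern. cpm values are
#' `2^log2cpm - 1` floored at 0.
#'
#' @param truth the `truth` element of [simulate_panel()]
#' @param config a [sim_config()] (its `expression` spec is used)
#' @return list with `expression` (an `expression_matrix`) and
#'   `gene_truth` (per-gene dependence status)
#' @export
simulate_expression <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  set.seed(config$seed + 2000003L)
  ids <- names(truth$haplotype)
  n_acc <- length(ids)
  gene_ids <- sprintf("GENE%04d", seq_len(ex$n_genes))
  genes <- data.frame(
    id = gene_ids, chrom = truth$block$chrom,
    pos = sort(truth$block$start_bp - 1 +
                 sample.int(truth$block$end_bp - truth$block$start_bp + 1,
                            ex$n_genes)),
    stringsAsFactors = FALSE)
  status <- rep("null", ex$n_genes)
  status[seq_len(ex$n_up)] <- "up"
  if (ex$n_down > 0) status[ex$n_up + seq_len(ex$n_down)] <- "down"

  mu <- stats::rnorm(ex$n_genes, ex$baseline_mean, ex$baseline_sd)
  carrier <- truth$haplotype == 2L
  minority <- truth$haplotype > 2L
  tissues <- c("seedling_crown", "seedling_root", "peduncle",
               "inflorescence", "spikelet", "developing_grain")[
                 seq_len(ex$n_tissues)]
  arr <- array(NA_real_, c(ex$n_genes, n_acc, ex$n_tissues),
               dimnames = list(gene_ids, ids, tissues))
  effect_sign <- ifelse(status == "up", 1, ifelse(status == "down", -1, 0))
  minority_scale <- stats::runif(n_acc)  # per-accession partial effect
  for (t in seq_len(ex$n_tissues)) {
    lg <- matrix(mu, ex$n_genes, n_acc) +
      outer(effect_sign * ex$effect, as.numeric(carrier)) +
      outer(effect_sign * ex$effect, as.numeric(minority) * minority_scale) +
      matrix(stats::rnorm(ex$n_genes * n_acc, 0, ex$sigma), ex$n_genes)
    arr[, , t] <- pmax(2^lg - 1, 0)
  }
  list(expression = expression_matrix(arr, genes, tissues,
                                      build = "synthetic"),
       gene_truth = data.frame(gene = gene_ids, status = status,
                               stringsAsFactors = FALSE))
}
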