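#' Identity-by-state distance between accessions
#'
#' `d(i, j) = sum |g_i - g_j| / (2 * n_shared)`, the proportion of allele
#' differences over the SNPs where both accessions have calls. Bounded in
#' [0, 1]; 0 for identical genotypes, 1 for complementary homozygotes.
#'
#' @param gm a `genotype_matrix`
#' @return a symmetric numeric matrix of distances with a zero diagonal
#' @export
ibs_distance <- function(gm) {
  if (n_accessions(gm) < 2) stop("need at least two accessions")
  x <- gm$calls
  m <- !is.na(x)
  i0 <- (x == 0L) & m; i1 <- (x == 1L) & m; i2 <- (x == 2L) & m
  storage.mode(i0) <- storage.mode(i1) <- storage.mode(i2) <- "double"
  storage.mode(m) <- "double"
  nshared <- m %*% t(m)
  if (any(nshared[upper.tri(nshared)] == 0)) {
    idx <- which(nshared == 0 & upper.tri(nshared), arr.ind = TRUE)[1, ]
    stop("no shared non-missing SNPs between ", rownames(x)[idx[1]],
         " and ", rownames(x)[idx[2]])
  }
  one_off <- i0 %*% t(i1) + i1 %*% t(i0) + i1 %*% t(i2) + i2 %*% t(i1)
  two_off <- i0 %*% t(i2) + i2 %*% t(i0)
  d <- (one_off + 2 * two_off) / (2 * nshared)
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Principal coordinate analysis (classical scaling)
#'
#' Double-centers the squared distance matrix and eigendecomposes it.
#' Coordinates are returned for axes with positive eigenvalues; negative
#' eigenvalues are reported but their axes dropped. Percent variance per
#' axis is computed over the positive eigenvalues and sums to 100.
#'
#' @param d a symmetric distance matrix (or `dist` object)
#' @return an `ordination` list: `coordinates` (accessions x axes),
#'   `eigenvalues` (all, non-increasing), `percent` (per kept axis)
#' @export
pcoa <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix must be symmetric")
  n <- nrow(d)
  cs <- suppressWarnings(
    stats::cmdscale(stats::as.dist(d), k = n - 1, eig = TRUE))
  eig <- cs$eig
  tol <- max(abs(eig)) * 1e-9
  pos <- which(eig > tol)
  if (length(pos) == 0) {
    coords <- matrix(0, n, 1, dimnames = list(rownames(d), "Axis1"))
    percent <- 100
  } else {
    coords <- cs$points[, pos, drop = FALSE]
    colnames(coords) <- paste0("Axis", seq_along(pos))
    rownames(coords) <- rownames(d)
    percent <- 100 * eig[pos] / sum(eig[pos])
  }
  structure(list(coordinates = coords, eigenvalues = eig,
                 percent = percent),
            class = "ordination")
}

#' @export
print.ordination <- function(x, ...) {
  cat("ordination:", nrow(x$coordinates), "points,",
      ncol(x$coordinates), "positive axes\n")
  k <- min(5, length(x$percent))
  cat("percent variance:",
      paste(sprintf("%.1f", x$percent[1:k]), collapse = ", "),
      if (length(x$percent) > k) "..." else "", "\n")
  invisible(x)
}

# PC scores of the centered call matrix; missing calls are replaced by the
# SNP mean before centering (they carry no information about structure).
pc_scores <- function(gm, n_pcs = NULL, var_target = NULL) {
  x <- gm$calls
  storage.mode(x) <- "double"
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  x <- sweep(x, 2, mu)
  pr <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  varexp <- pr$sdev^2 / sum(pr$sdev^2)
  if (is.null(n_pcs)) {
    if (is.null(var_target)) var_target <- 0.9
    n_pcs <- which(cumsum(varexp) >= var_target)[1]
    if (is.na(n_pcs)) n_pcs <- length(varexp)
  }
  n_pcs <- min(n_pcs, ncol(pr$x))
  list(scores = pr$x[, seq_len(n_pcs), drop = FALSE],
       n_pcs = n_pcs, varexp = varexp)
}

#' K-means clustering over principal components with BIC model selection
#'
#' Projects the panel onto its leading principal components (enough to
#' capture `var_target` of the variance unless `n_pcs` is given), runs
#' best-of-`n_starts` k-means for every `k` in `k_range` and scores each
#' solution with `BIC(k) = n * ln(WSS_k / n) + k * ln(n)`. The returned
#' model is the argmin-BIC `k`; the full BIC curve is kept so the elbow
#' heuristic or a user override can pick a different `k`.
#'
#' @param gm a `genotype_matrix`
#' @param n_pcs number of PCs to retain (default: smallest number reaching
#'   `var_target`)
#' @param var_target cumulative variance target used when `n_pcs` is `NULL`
#' @param k_range candidate numbers of clusters
#' @param n_starts random restarts per `k`
#' @param seed integer seed; results are deterministic given the seed
#' @return a `cluster_model` list: `n_pcs`, `k`, `memberships` (named),
#'   `centroids`, `bic_curve`, `wss`, `seed`
#' @export
find_clusters <- function(gm, n_pcs = NULL, var_target = 0.9,
                          k_range = 1:10, n_starts = 100, seed = 1L) {
  pcs <- pc_scores(gm, n_pcs, var_target)
  x <- pcs$scores
  n <- nrow(x)
  k_range <- sort(unique(k_range))
  if (any(k_range > n)) {
    warning("skipping k > number of accessions")
    k_range <- k_range[k_range <= n]
  }
  set.seed(seed)
  total_ss <- sum(sweep(x, 2, colMeans(x))^2)
  bic <- rep(NA_real_, length(k_range))
  wss <- rep(NA_real_, length(k_range))
  fits <- vector("list", length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    if (k == 1) {
      wss[i] <- total_ss
      fits[[i]] <- list(cluster = rep(1L, n),
                        centers = matrix(colMeans(x), 1))
    } else {
      fit <- tryCatch(
        stats::kmeans(x, centers = k, nstart = n_starts, iter.max = 200),
        error = function(e) NULL)  # e.g. fewer distinct points than centers
      if (is.null(fit)) { bic[i] <- Inf; next }
      wss[i] <- fit$tot.withinss
      fits[[i]] <- fit
    }
    bic[i] <- if (wss[i] <= 0) -Inf else n * log(wss[i] / n) + k * log(n)
  }
  best <- which.min(bic)  # ties resolve toward the smallest k
  memb <- fits[[best]]$cluster
  names(memb) <- accession_ids(gm)
  structure(list(n_pcs = pcs$n_pcs, k = k_range[best],
                 memberships = memb,
                 centroids = fits[[best]]$centers,
                 bic_curve = stats::setNames(bic, k_range),
                 wss = stats::setNames(wss, k_range),
                 varexp = pcs$varexp, seed = seed),
            class = "cluster_model")
}

#' Elbow heuristic on a BIC curve
#'
#' Returns the `k` maximizing the discrete second difference
#' `BIC(k-1) - 2 BIC(k) + BIC(k+1)`; ties break toward the smallest `k`.
#' Advisory only: the pipeline accepts a user override of `k`.
#'
#' @param bic_curve named numeric vector of BIC over consecutive `k`
#'   (at least 3 points)
#' @return the chosen `k` (integer)
#' @export
choose_k_elbow <- function(bic_curve) {
  ks <- as.integer(names(bic_curve))
  if (is.null(names(bic_curve))) ks <- seq_along(bic_curve)
  if (length(bic_curve) < 3) stop("need at least 3 BIC points")
  if (any(diff(ks) != 1)) stop("BIC curve must cover consecutive k")
  v <- as.numeric(bic_curve)
  inner <- 2:(length(v) - 1)
  d2 <- v[inner - 1] - 2 * v[inner] + v[inner + 1]
  ks[inner[which.max(d2)]]
}

#' Discriminant analysis of principal components (DAPC)
#'
#' Reduces the centered call matrix to `n_pcs` principal components, then
#' fits a linear discriminant analysis on the predefined groups. Returns
#' per-accession discriminant coordinates, group centroids and the
#' leave-in reassignment accuracy (fraction of accessions whose predicted
#' group equals their actual group).
#'
#' @param gm a `genotype_matrix`
#' @param partition named vector of group labels; at least 2 groups of
#'   size >= 2
#' @param n_pcs number of PCs retained (must be < number of accessions)
#' @param n_da number of discriminant axes (default
#'   `min(groups - 1, n_pcs)`)
#' @return a `dapc_model` list: `n_pcs`, `n_da`, `coordinates`,
#'   `centroids`, `accuracy`, `groups`, `predicted`
#' @export
dapc <- function(gm, partition, n_pcs, n_da = NULL) {
  part <- align_partition(gm, partition)
  sizes <- table(part)
  if (length(sizes) < 2) stop("need at least two groups")
  if (any(sizes < 2)) stop("every group must have >= 2 members")
  if (n_pcs >= n_accessions(gm)) {
    stop("n_pcs must be smaller than the number of accessions (overfit guard)")
  }
  pcs <- pc_scores(gm, n_pcs)
  max_da <- min(length(sizes) - 1, pcs$n_pcs)
  if (is.null(n_da)) n_da <- max_da
  n_da <- min(n_da, max_da)
  fit <- suppressWarnings(MASS::lda(pcs$scores, grouping = factor(part)))
  pred <- stats::predict(fit)
  coords <- pred$x[, seq_len(n_da), drop = FALSE]
  rownames(coords) <- accession_ids(gm)
  cent <- apply(coords, 2, function(col) tapply(col, part, mean))
  cent <- matrix(cent, nrow = length(sizes),
                 dimnames = list(names(tapply(coords[, 1], part, mean)),
                                 colnames(coords)))
  structure(list(n_pcs = pcs$n_pcs, n_da = n_da,
                 coordinates = coords, centroids = cent,
                 accuracy = mean(as.character(pred$class) == part),
                 groups = stats::setNames(part, accession_ids(gm)),
                 predicted = stats::setNames(as.character(pred$class),
                                             accession_ids(gm))),
            class = "dapc_model")
}

#' Cross-validated choice of the number of PCs for DAPC
#'
#' Repeatedly holds out a stratified fraction of accessions, fits the
#' discriminant analysis on the remainder for each candidate number of
#' PCs, and scores the held-out assignment success. Returns the candidate
#' with the highest mean success; ties break toward fewer PCs.
#'
#' @param gm a `genotype_matrix`
#' @param partition named vector of group labels
#' @param candidate_n_pcs integer vector of candidates
#' @param reps number of repetitions (default 100)
#' @param holdout_frac held-out fraction per group (default 0.1; at least
#'   one member per group is always held out)
#' @param seed integer seed
#' @return list: `n_pcs` (chosen), `success` (mean per candidate)
#' @export
xval_n_pcs <- function(gm, partition, candidate_n_pcs, reps = 100,
                       holdout_frac = 0.1, seed = 1L) {
  part <- align_partition(gm, partition)
  candidate_n_pcs <- sort(unique(candidate_n_pcs))
  if (length(candidate_n_pcs) == 1) {
    return(list(n_pcs = candidate_n_pcs,
                success = stats::setNames(NA_real_, candidate_n_pcs)))
  }
  pcs <- pc_scores(gm, max(candidate_n_pcs))
  scores <- pcs$scores
  grp <- factor(part)
  set.seed(seed)
  succ <- matrix(NA_real_, reps, length(candidate_n_pcs))
  for (r in seq_len(reps)) {
    hold <- unlist(lapply(levels(grp), function(g) {
      idx <- which(grp == g)
      sample(idx, max(1, round(length(idx) * holdout_frac)))
    }))
    train <- setdiff(seq_len(nrow(scores)), hold)
    for (ci in seq_along(candidate_n_pcs)) {
      np <- min(candidate_n_pcs[ci], length(train) - 1)
      fit <- tryCatch(
        suppressWarnings(MASS::lda(scores[train, seq_len(np), drop = FALSE],
                                   grouping = grp[train])),
        error = function(e) NULL)
      if (is.null(fit)) next
      pr <- stats::predict(fit, scores[hold, seq_len(np), drop = FALSE])
      succ[r, ci] <- mean(as.character(pr$class) == as.character(grp[hold]))
    }
  }
  mean_succ <- colMeans(succ, na.rm = TRUE)
  best <- which.max(mean_succ)  # ties -> fewer PCs (first index)
  list(n_pcs = candidate_n_pcs[best],
       success = stats::setNames(mean_succ, candidate_n_pcs))
}
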