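#' Construct an expression matrix (genes x accessions x tissues)
#'
#' Counts-per-million (cpm) values for a set of genes with genomic
#' coordinates, measured on the panel accessions in one or more tissues.
#' Values must be non-negative.
#'
#' @param cpm a 3-d array genes x accessions x tissues (dimnames used when
#'   present), or a genes x accessions matrix for a single tissue
#' @param genes data.frame with columns `id`, `chrom`, `pos`
#' @param tissues character vector of tissue labels
#' @param build genome-build tag for the gene coordinates
#' @param logged whether values are already log2(cpm + pseudocount)
#' @return an `expression_matrix` list: `cpm`, `genes`, `tissues`,
#'   `build`, `logged`
#' @export
expression_matrix <- function(cpm, genes, tissues = NULL,
                              build = "unknown", logged = FALSE) {
  if (length(dim(cpm)) == 2) cpm <- array(cpm, dim = c(dim(cpm), 1),
                                          dimnames = c(dimnames(cpm),
                                                       list(tissues)))
  if (length(dim(cpm)) != 3) stop("cpm must be genes x accessions x tissues")
  if (!logged && any(cpm < 0, na.rm = TRUE)) {
    stop("cpm values must be non-negative")
  }
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!all(c("id", "chrom", "pos") %in% names(genes))) {
    stop("genes needs columns id, chrom, pos")
  }
  if (nrow(genes) != dim(cpm)[1]) stop("gene table / cpm dimension mismatch")
  if (is.null(tissues)) {
    tissues <- dimnames(cpm)[[3]]
    if (is.null(tissues)) tissues <- paste0("tissue", seq_len(dim(cpm)[3]))
  }
  if (length(tissues) != dim(cpm)[3]) stop("tissue labels / cpm mismatch")
  dimnames(cpm)[[1]] <- genes$id
  dimnames(cpm)[[3]] <- tissues
  structure(list(cpm = cpm, genes = genes, tissues = tissues,
                 build = build, logged = logged),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", dim(x$cpm)[1], "genes x", dim(x$cpm)[2],
      "accessions x", dim(x$cpm)[3], "tissues",
      if (x$logged) "(log2 scale)" else "(cpm scale)", "\n")
  invisible(x)
}

#' Log-transform cpm values
#'
#' `log2(cpm + pseudocount)`; monotone and order-preserving. The default
#' pseudocount of 1 maps cpm 0 to 0.
#'
#' @param expr an `expression_matrix` on the cpm scale
#' @param pseudocount positive offset (default 1)
#' @return the `expression_matrix` on the log2 scale (`logged = TRUE`)
#' @export
log_cpm <- function(expr, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (expr$logged) return(expr)
  if (any(expr$cpm < 0, na.rm = TRUE)) stop("negative cpm values")
  expr$cpm <- log2(expr$cpm + pseudocount)
  expr$logged <- TRUE
  attr(expr, "pseudocount") <- pseudocount
  expr
}

as_log2 <- function(expr, pseudocount = 1) {
  if (expr$logged) expr else log_cpm(expr, pseudocount)
}

#' Filter genes to the expressed subset
#'
#' Keeps a gene iff in at least one tissue, strictly more than `min_frac`
#' of the accessions express it at strictly more than `min_cpm` cpm.
#' Idempotent and invariant to gene order.
#'
#' @param expr an `expression_matrix` on the cpm scale
#' @param min_cpm expression threshold (exclusive, default 1)
#' @param min_frac accession-fraction threshold (exclusive, default 0.30)
#' @return the filtered `expression_matrix`; kept ids in
#'   `attr(, "kept_genes")`
#' @export
filter_expressed <- function(expr, min_cpm = 1, min_frac = 0.30) {
  if (expr$logged) stop("filter_expressed expects cpm-scale values")
  if (dim(expr$cpm)[3] < 1) stop("no tissues in expression matrix")
  frac <- apply(expr$cpm > min_cpm, c(1, 3), mean)  # gene x tissue
  keep <- apply(frac > min_frac, 1, any)
  out <- expression_matrix(expr$cpm[keep, , , drop = FALSE],
                           expr$genes[keep, , drop = FALSE],
                           expr$tissues, expr$build, expr$logged)
  attr(out, "kept_genes") <- expr$genes$id[keep]
  out
}

#' PCoA of expression profiles in one tissue
#'
#' Euclidean distance on log2 cpm of one tissue slice, ordinated by
#' classical scaling. `mode = "accessions"` ordinates the cultivars on
#' their expression of all genes; `mode = "genes"` ordinates the genes on
#' their expression across cultivars.
#'
#' @param expr an `expression_matrix` (log-transformed internally if
#'   needed)
#' @param tissue tissue label or index
#' @param mode `"accessions"` or `"genes"`
#' @return an `ordination`
#' @export
pcoa_expression <- function(expr, tissue = 1,
                            mode = c("accessions", "genes")) {
  mode <- match.arg(mode)
  expr <- as_log2(expr)
  slice <- expr$cpm[, , tissue]            # genes x accessions
  if (mode == "accessions") slice <- t(slice)
  pcoa(as.matrix(stats::dist(slice)))
}

#' K-means clustering of genes on their expression profiles
#'
#' Genes are observations; their profiles are the log2 cpm values across
#' accessions, for one tissue or concatenated over all tissues.
#'
#' @param expr an `expression_matrix`
#' @param k number of gene clusters (default 4)
#' @param seed integer seed
#' @param tissue tissue label/index, or `NULL` to concatenate all tissues
#' @return named integer vector of cluster memberships (1..k) per gene
#' @export
cluster_genes <- function(expr, k = 4, seed = 1L, tissue = NULL) {
  expr <- as_log2(expr)
  if (is.null(tissue)) {
    x <- do.call(cbind, lapply(seq_len(dim(expr$cpm)[3]),
                               function(t) expr$cpm[, , t]))
  } else {
    x <- expr$cpm[, , tissue]
  }
  if (k > nrow(x)) stop("k exceeds the number of genes")
  set.seed(seed)
  km <- stats::kmeans(x, centers = k, nstart = 25, iter.max = 100)
  stats::setNames(km$cluster, expr$genes$id)
}

#' Call haplotype-dependent genes by standardized mean difference
#'
#' For each gene and tissue, the standardized mean difference (SMD) of
#' log2 cpm between carriers of the target haplotype and carriers of the
#' other haplotype of interest (difference of group means over the pooled
#' standard deviation). A gene is called `up-in-target` (resp.
#' `down-in-target`) iff its SMD is `>= smd_threshold` (resp.
#' `<= -smd_threshold`) with the same sign in every tissue; otherwise
#' `none`. Accessions carrying any other (minority) haplotype, or
#' unassigned, are excluded. Zero pooled variance with equal means gives
#' SMD 0.
#'
#' @param expr an `expression_matrix`
#' @param assignment a `haplotype_assignment`
#' @param target_label target haplotype label (e.g. the sweeping one)
#' @param other_label comparison haplotype label; default: the most
#'   frequent non-target label
#' @param smd_threshold |SMD| threshold (default 2.0)
#' @param gene_clusters optional named cluster vector from
#'   [cluster_genes()] cross-referenced in the report
#' @return a `haplo_expression_report` data.frame: `gene`, `direction`,
#'   `min_abs_smd`, `consistent`, `cluster`; per-tissue SMDs in
#'   `attr(, "smd")`
#' @export
haplotype_dependent_genes <- function(expr, assignment, target_label,
                                      other_label = NULL,
                                      smd_threshold = 2.0,
                                      gene_clusters = NULL) {
  expr <- as_log2(expr)
  acc <- dimnames(expr$cpm)[[2]]
  hap <- assignment$haplotype[match(acc, assignment$accession)]
  if (is.null(other_label)) {
    rest <- hap[!is.na(hap) & hap != target_label]
    if (length(rest) == 0) stop("no non-target accessions to compare with")
    other_label <- as.integer(names(sort(table(rest), decreasing = TRUE))[1])
  }
  in_t <- !is.na(hap) & hap == target_label
  in_o <- !is.na(hap) & hap == other_label
  if (sum(in_t) < 3 || sum(in_o) < 3) {
    stop("each haplotype group needs >= 3 accessions (target: ", sum(in_t),
         ", other: ", sum(in_o), ")")
  }
  n1 <- sum(in_t); n2 <- sum(in_o)
  n_t <- dim(expr$cpm)[3]
  smd <- matrix(NA_real_, dim(expr$cpm)[1], n_t,
                dimnames = list(expr$genes$id, expr$tissues))
  for (t in seq_len(n_t)) {
    sl <- expr$cpm[, , t]
    xt <- sl[, in_t, drop = FALSE]
    xo <- sl[, in_o, drop = FALSE]
    m1 <- rowMeans(xt); m2 <- rowMeans(xo)
    v1 <- apply(xt, 1, stats::var); v2 <- apply(xo, 1, stats::var)
    sp <- sqrt(((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2))
    s <- (m1 - m2) / sp
    s[sp == 0 & m1 == m2] <- 0
    s[sp == 0 & m1 != m2] <- sign(m1 - m2)[sp == 0 & m1 != m2] * Inf
    smd[, t] <- s
  }
  consistent <- apply(smd, 1, function(v) all(v > 0) || all(v < 0))
  up <- consistent & apply(smd >= smd_threshold, 1, all)
  down <- consistent & apply(smd <= -smd_threshold, 1, all)
  direction <- rep("none", nrow(smd))
  direction[up] <- "up-in-target"
  direction[down] <- "down-in-target"
  out <- data.frame(gene = expr$genes$id,
                    direction = direction,
                    min_abs_smd = apply(abs(smd), 1, min),
                    consistent = consistent,
                    cluster = if (is.null(gene_clusters)) NA_integer_ else
                      unname(gene_clusters[expr$genes$id]),
                    stringsAsFactors = FALSE)
  structure(out, smd = smd, target_label = target_label,
            other_label = other_label, smd_threshold = smd_threshold,
            class = c("haplo_expression_report", "data.frame"))
}

#' Read a long-format expression TSV
#'
#' Columns `gene,chrom,pos,accession,tissue,cpm`; assembled into an
#' `expression_matrix`.
#'
#' @param path TSV path
#' @param build genome-build tag
#' @return an `expression_matrix`
#' @export
read_expression_long <- function(path, build = "unknown") {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene", "chrom", "pos", "accession", "tissue", "cpm")
  if (!all(req %in% names(tab))) {
    stop("expression TSV needs columns ", paste(req, collapse = ","))
  }
  genes <- unique(tab[, c("gene", "chrom", "pos")])
  names(genes)[1] <- "id"
  accs <- unique(tab$accession)
  tissues <- unique(tab$tissue)
  arr <- array(NA_real_, c(nrow(genes), length(accs), length(tissues)),
               dimnames = list(genes$id, accs, tissues))
  arr[cbind(match(tab$gene, genes$id), match(tab$accession, accs),
            match(tab$tissue, tissues))] <- tab$cpm
  expression_matrix(arr, genes, tissues, build = build)
}

#' Write an expression matrix as a long-format TSV
#'
#' @param expr an `expression_matrix`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_expression_long <- function(expr, path) {
  dn <- dimnames(expr$cpm)
  long <- expand.grid(gene = dn[[1]], accession = dn[[2]], tissue = dn[[3]],
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$cpm <- as.vector(expr$cpm)
  gi <- match(long$gene, expr$genes$id)
  long$chrom <- expr$genes$chrom[gi]
  long$pos <- expr$genes$pos[gi]
  long <- long[, c("gene", "chrom", "pos", "accession", "tissue", "cpm")]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
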