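#' Construct a genotype matrix for a panel of inbred accessions
#'
#' The central container of the package: biallelic SNP calls for a set of
#' accessions, coded as the count of the alternative allele
#' (0 = homozygous reference, 1 = heterozygous, 2 = homozygous alternative,
#' `NA` = missing). Variants are kept sorted by (chromosome, position) and
#' must be unique per (chromosome, position); positions are 1-based.
#'
#' @param calls integer matrix, accessions x variants, values in
#'   \{0, 1, 2, NA\}. Row names are taken as accession ids if `accessions`
#'   is not supplied.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (one row per column of `calls`). `ref` and `alt` must differ per row.
#' @param build genome-build tag, a free string (e.g. `"Barke"`).
#' @param accessions optional character vector of accession ids.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `calls`, `variants`, `build`.
#' @export
genotype_matrix <- function(calls, variants, build = "unknown",
                            accessions = NULL) {
  calls <- as.matrix(calls)
  if (!is.null(accessions)) rownames(calls) <- accessions
  if (is.null(rownames(calls))) {
    rownames(calls) <- sprintf("ACC%03d", seq_len(nrow(calls)))
  }
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(variants))) {
    stop("`variants` must have columns chrom, pos, ref, alt")
  }
  if (nrow(variants) != ncol(calls)) {
    stop("dimension mismatch: ", ncol(calls), " call columns but ",
         nrow(variants), " variant records")
  }
  if (any(variants$pos < 1)) stop("positions must be >= 1 (1-based)")
  if (any(variants$ref == variants$alt)) {
    stop("ref and alt alleles must differ at every variant")
  }
  bad <- !(calls %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("calls must be 0, 1, 2 or NA")
  storage.mode(calls) <- "integer"

  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  calls <- calls[, ord, drop = FALSE]
  if (anyDuplicated(variants[, c("chrom", "pos")])) {
    stop("duplicate (chrom, pos) variant records")
  }
  rownames(variants) <- NULL
  colnames(calls) <- paste(variants$chrom, variants$pos, sep = ":")
  structure(list(calls = calls, variants = variants,
                 build = as.character(build)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$calls), "accessions x",
      ncol(x$calls), "SNPs, build", x$build, "\n")
  cat("chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of accessions / variants in a genotype matrix
#' @param gm a `genotype_matrix`
#' @return integer count
#' @export
n_accessions <- function(gm) nrow(gm$calls)

#' @rdname n_accessions
#' @export
n_variants <- function(gm) ncol(gm$calls)

#' Accession ids of a genotype matrix
#' @param gm a `genotype_matrix`
#' @return character vector
#' @export
accession_ids <- function(gm) rownames(gm$calls)

#' Subset a genotype matrix by accessions and/or variants
#'
#' @param gm a `genotype_matrix`
#' @param accessions accession ids or indices (optional)
#' @param variants variant indices (optional)
#' @return a `genotype_matrix`
#' @export
subset_gm <- function(gm, accessions = NULL, variants = NULL) {
  calls <- gm$calls
  if (!is.null(accessions)) {
    if (is.character(accessions)) {
      missing_ids <- setdiff(accessions, rownames(calls))
      if (length(missing_ids)) {
        stop("unknown accession id(s): ",
             paste(utils::head(missing_ids, 5), collapse = ", "))
      }
    }
    calls <- calls[accessions, , drop = FALSE]
  }
  vr <- gm$variants
  if (!is.null(variants)) {
    calls <- calls[, variants, drop = FALSE]
    vr <- vr[variants, , drop = FALSE]
  }
  genotype_matrix(calls, vr, build = gm$build)
}

#' Read a VCF file into a genotype matrix
#'
#' Retains biallelic SNP records only; multi-allelic records and indels are
#' skipped and counted. Genotypes are coded by the number of alternative
#' alleles; missing genotypes (`./.`) become `NA`. Samples are assumed to be
#' inbred lines but heterozygous calls are permitted.
#'
#' @param path path to a VCF v4.x file (plain or gzipped)
#' @param build genome-build tag recorded on the result
#' @return a `genotype_matrix`; the number of skipped records is attached as
#'   attribute `"skipped"`.
#' @export
read_vcf <- function(path, build = "unknown") {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("failed to parse VCF ", path, ": ",
                                         conditionMessage(e)))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (nrow(fix) == 0) stop("empty input: no variant records in ", path)
  nt <- c("A", "C", "G", "T")
  keep <- fix$REF %in% nt & fix$ALT %in% nt
  n_skipped <- sum(!keep)
  if (!any(keep)) stop("empty input: no biallelic SNP records retained")
  if (n_skipped > 0) {
    message("read_vcf: skipped ", n_skipped,
            " non-biallelic-SNP record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- function(g) {
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- t(matrix(code(as.vector(gt)), nrow = nrow(gt)))
  rownames(calls) <- colnames(gt)
  variants <- data.frame(chrom = fix$CHROM[keep],
                         pos = as.integer(fix$POS[keep]),
                         ref = fix$REF[keep], alt = fix$ALT[keep],
                         stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, variants, build = build)
  attr(gm, "skipped") <- n_skipped
  gm
}

#' Read a delimited genotype matrix and companion metadata
#'
#' The genotype file is a TSV whose first four columns are
#' `chrom`, `pos`, `ref`, `alt` followed by one column per accession, with
#' cell values 0/1/2 or NA. The metadata file is a CSV keyed by accession
#' id with columns `id,name,country,release_year,row_type,growth_habit,
#' anchor_haplotype`; accessions absent from it get null fields.
#'
#' @param path path to the genotype TSV
#' @param meta_path optional path to the metadata CSV
#' @param build genome-build tag
#' @return a list with elements `genotypes` (a `genotype_matrix`) and
#'   `meta` (an accession metadata data.frame)
#' @export
read_matrix <- function(path, meta_path = NULL, build = "unknown") {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 5) stop("genotype table needs chrom,pos,ref,alt + samples")
  variants <- tab[, 1:4]
  names(variants) <- c("chrom", "pos", "ref", "alt")
  ids <- colnames(tab)[-(1:4)]
  if (anyDuplicated(ids)) {
    stop("duplicated accession id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  calls <- as.matrix(tab[, -(1:4), drop = FALSE])
  bad <- which(matrix(!(calls %in% c(0, 1, 2, NA)), nrow(calls)),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("invalid genotype value '%s' at row %d (SNP %s:%s), column '%s'",
                 calls[bad[1, 1], bad[1, 2]], bad[1, 1],
                 variants$chrom[bad[1, 1]], variants$pos[bad[1, 1]],
                 ids[bad[1, 2]]))
  }
  gm <- genotype_matrix(t(calls), variants, build = build, accessions = ids)
  meta <- empty_meta(ids)
  if (!is.null(meta_path)) {
    given <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    if (anyDuplicated(given$id)) stop("duplicated id in metadata")
    idx <- match(ids, given$id)
    for (col in setdiff(names(meta), "id")) {
      if (col %in% names(given)) meta[[col]] <- given[[col]][idx]
    }
  }
  list(genotypes = gm, meta = meta)
}

#' Write a genotype matrix as a delimited file
#'
#' Inverse of [read_matrix()]: calls, positions and ordering round-trip
#' bit-exactly.
#'
#' @param gm a `genotype_matrix`
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_matrix <- function(gm, path) {
  tab <- cbind(gm$variants, as.data.frame(t(gm$calls)))
  colnames(tab) <- c("chrom", "pos", "ref", "alt", rownames(gm$calls))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Metadata skeleton for a set of accessions
#'
#' All-null accession metadata in the package's column layout
#' (`id,name,country,release_year,row_type,growth_habit,anchor_haplotype`).
#'
#' @param ids character vector of accession ids
#' @return a data.frame with one row per accession
#' @export
empty_meta <- function(ids) {
  data.frame(id = ids, name = ids,
             country = rep(NA_character_, length(ids)),
             release_year = rep(NA_integer_, length(ids)),
             row_type = rep("unknown", length(ids)),
             growth_habit = rep("unknown", length(ids)),
             anchor_haplotype = rep(NA_integer_, length(ids)),
             stringsAsFactors = FALSE)
}
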