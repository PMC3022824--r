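#' Analysis-ready genotype matrix
#'
#' The central container of the package: a samples-by-SNPs integer matrix of
#' genotype categories coded `0` (homozygote of the minor allele), `1`
#' (heterozygote), `2` (homozygote of the major allele), with `NA` as the
#' missing sentinel, plus per-sample and per-SNP metadata.
#'
#' @param codes integer matrix, samples in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param sample_ids character vector, one id per row.
#' @param snp_ids character vector of unique rs identifiers, one per column.
#' @param chromosomes optional per-SNP chromosome labels (default `"1"`).
#' @param alleles optional data frame with columns `minor` and `major`
#'   (one row per SNP) recording the allele symbols behind the coding, when
#'   known.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(codes, sample_ids, snp_ids,
                            chromosomes = NULL, alleles = NULL) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) != length(sample_ids))
    stop("number of rows of `codes` must equal length(sample_ids)")
  if (ncol(codes) != length(snp_ids))
    stop("number of columns of `codes` must equal length(snp_ids)")
  if (anyDuplicated(snp_ids))
    stop("snp_ids must be unique")
  bad <- codes[!is.na(codes)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("non-missing genotype codes must be in {0, 1, 2}")
  if (is.null(chromosomes)) chromosomes <- rep("1", length(snp_ids))
  if (length(chromosomes) != length(snp_ids))
    stop("chromosomes must have one entry per SNP")
  if (!is.null(alleles)) {
    alleles <- as.data.frame(alleles)
    if (nrow(alleles) != length(snp_ids) ||
        !all(c("minor", "major") %in% names(alleles)))
      stop("alleles must be a data frame with columns minor, major and one row per SNP")
  }
  dimnames(codes) <- list(sample_ids, snp_ids)
  structure(
    list(codes = codes,
         sample_ids = as.character(sample_ids),
         snp_ids = as.character(snp_ids),
         chromosomes = as.character(chromosomes),
         alleles = alleles),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs (%d missing calls)\n",
              nrow(x$codes), ncol(x$codes), sum(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

#' Restrict a genotype matrix to a subset of SNPs and/or samples
#'
#' @param G a [genotype_matrix()].
#' @param snps SNP selector: rs ids or column indices (default all).
#' @param samples sample selector: ids or row indices (default all).
#' @return A `genotype_matrix` with the selected rows/columns.
#' @export
subset_genotypes <- function(G, snps = NULL, samples = NULL) {
  stopifnot(inherits(G, "genotype_matrix"))
  j <- if (is.null(snps)) seq_along(G$snp_ids) else resolve_idx(snps, G$snp_ids, "SNP")
  i <- if (is.null(samples)) seq_along(G$sample_ids) else resolve_idx(samples, G$sample_ids, "sample")
  genotype_matrix(G$codes[i, j, drop = FALSE],
                  G$sample_ids[i], G$snp_ids[j],
                  G$chromosomes[j],
                  if (!is.null(G$alleles)) G$alleles[j, , drop = FALSE])
}

resolve_idx <- function(sel, ids, what) {
  if (is.character(sel)) {
    idx <- match(sel, ids)
    if (anyNA(idx)) stop(sprintf("unknown %s id(s): %s", what,
                                 paste(sel[is.na(idx)], collapse = ", ")))
    idx
  } else {
    sel <- as.integer(sel)
    if (any(sel < 1L) || any(sel > length(ids)))
      stop(sprintf("%s index out of range", what))
    sel
  }
}

#' Phenotype vector constructor
#'
#' Binary case-control labels, `1` = case, `0` = control, aligned to the
#' samples of a genotype matrix.
#'
#' @param labels vector coercible to integer with values in `{0, 1}`.
#' @return An integer vector of class `phenotype`.
#' @export
phenotype <- function(labels) {
  y <- as.integer(labels)
  if (anyNA(y) || !all(y %in% c(0L, 1L)))
    stop("phenotype labels must be 0 (control) or 1 (case) with no missing values")
  structure(y, class = "phenotype")
}
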