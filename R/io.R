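#' Read a PLINK text ped/map cohort
#'
#' Parses the PLINK text dialect used throughout the package: the `.ped` file
#' carries six leading columns (FID, IID, PAT, MAT, SEX, PHENO with 2 = case,
#' 1 = control) followed by two allele columns per SNP (`0 0` = missing call);
#' the `.map` file carries chromosome, rs id, genetic distance and bp
#' position. Alleles are returned verbatim; genotype coding happens later in
#' [encode_genotypes()].
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @return A list with `alleles` (character matrix, samples x SNPs, entries
#'   `"A/G"` etc., `NA` for missing calls), `sample_ids`, `labels`
#'   (1 = case, 0 = control), and `snps` (data frame: chromosome, snp_id,
#'   position).
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_fields <- strsplit(trimws(map_lines[nzchar(trimws(map_lines))]), "[ \t]+")
  if (any(lengths(map_fields) != 4L))
    stop("malformed .map file: expected 4 whitespace-separated columns")
  map <- do.call(rbind, map_fields)
  snps <- data.frame(chromosome = map[, 1], snp_id = map[, 2],
                     position = as.integer(map[, 4]),
                     stringsAsFactors = FALSE)
  m <- nrow(snps)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expect_len <- 6L + 2L * m
  if (any(lengths(fields) != expect_len))
    stop(sprintf("ragged .ped rows or SNP count mismatch with .map: expected %d fields", expect_len))
  ped <- do.call(rbind, fields)

  pheno <- ped[, 6]
  if (!all(pheno %in% c("1", "2")))
    stop("unsupported ped phenotype code(s): only 2=case / 1=control are accepted (unlabeled samples unsupported)")
  labels <- as.integer(pheno == "2")
  sample_ids <- ped[, 2]

  a1 <- ped[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- ped[, 6L + 2L * seq_len(m), drop = FALSE]
  miss <- a1 == "0" | a2 == "0"
  if (any(xor(a1 == "0", a2 == "0")))
    stop("half-missing genotype call (one allele '0') in .ped")
  alleles <- matrix(paste(a1, a2, sep = "/"), nrow = nrow(ped))
  alleles[miss] <- NA_character_
  dimnames(alleles) <- list(sample_ids, snps$snp_id)

  list(alleles = alleles, sample_ids = sample_ids, labels = labels, snps = snps)
}

#' Derive the minor/major allele mapping from a reference cohort
#'
#' The minor allele of each SNP is determined from allele frequencies in the
#' reference (training) cohort only, and the frozen mapping is then applied to
#' any other cohort, so that genotype coding never leaks test information.
#' Ties at frequency 0.5 resolve to the alphabetically first allele;
#' monomorphic SNPs record the observed allele as major and a placeholder
#' minor symbol (no 0/1 codes can then arise).
#'
#' @param alleles character matrix of `"A/G"`-style calls (from
#'   [read_ped_map()]), `NA` for missing.
#' @return Data frame with columns `minor`, `major`, one row per SNP.
#' @export
allele_mapping <- function(alleles) {
  m <- ncol(alleles)
  minor <- major <- character(m)
  for (j in seq_len(m)) {
    calls <- alleles[, j]
    calls <- calls[!is.na(calls)]
    if (!length(calls))
      stop(sprintf("SNP %s has no observed genotypes in the reference cohort",
                   colnames(alleles)[j]))
    obs <- unlist(strsplit(calls, "/", fixed = TRUE), use.names = FALSE)
    tab <- sort(table(obs))
    syms <- names(tab)
    if (length(syms) > 2L)
      stop(sprintf("SNP %s has more than two alleles: %s",
                   colnames(alleles)[j], paste(sort(syms), collapse = ", ")))
    if (length(syms) == 1L) {
      major[j] <- syms
      # monomorphic: minor allele unobserved; record a placeholder symbol
      minor[j] <- setdiff(c("A", "C", "G", "T"), syms)[1]
    } else {
      if (tab[[1]] == tab[[2]]) {        # exact 0.5/0.5 tie
        minor[j] <- min(syms); major[j] <- max(syms)
      } else {
        minor[j] <- syms[1]; major[j] <- syms[2]
      }
    }
  }
  data.frame(minor = minor, major = major, stringsAsFactors = FALSE)
}

#' Encode allele-pair calls into 0/1/2 genotype categories
#'
#' Applies the coding used throughout the analysis: `0` = homozygote of the
#' minor allele, `1` = heterozygote, `2` = homozygote of the major allele.
#' The minor allele comes from `mapping` (derive it once from the training
#' cohort with [allele_mapping()] and reuse it for the test cohort).
#'
#' @param parsed result of [read_ped_map()] (or any list with the same
#'   `alleles`, `sample_ids`, `snps` fields).
#' @param mapping data frame from [allele_mapping()]; default derives it from
#'   `parsed` itself (training cohort use).
#' @return A [genotype_matrix()].
#' @export
encode_genotypes <- function(parsed, mapping = allele_mapping(parsed$alleles)) {
  alleles <- parsed$alleles
  m <- ncol(alleles)
  if (nrow(mapping) != m) stop("mapping has wrong number of SNPs")
  codes <- matrix(NA_integer_, nrow(alleles), m)
  for (j in seq_len(m)) {
    calls <- alleles[, j]
    ok <- !is.na(calls)
    if (!any(ok)) next
    parts <- strsplit(calls[ok], "/", fixed = TRUE)
    a1 <- vapply(parts, `[`, "", 1L)
    a2 <- vapply(parts, `[`, "", 2L)
    known <- c(mapping$minor[j], mapping$major[j])
    alien <- setdiff(unique(c(a1, a2)), known)
    if (length(alien))
      stop(sprintf("SNP %s: allele %s absent from the training mapping",
                   parsed$snps$snp_id[j], paste(alien, collapse = ", ")))
    codes[ok, j] <- (a1 == mapping$major[j]) + (a2 == mapping$major[j])
  }
  genotype_matrix(codes, parsed$sample_ids, parsed$snps$snp_id,
                  parsed$snps$chromosome, mapping)
}

#' Impute missing genotype calls with the per-SNP majority category
#'
#' Every missing call is replaced by the most frequent non-missing category
#' of that SNP computed on the reference (training) matrix; ties between
#' categories resolve to the lowest code. With `reference = G` the matrix
#' imputes against itself (training-cohort use); passing the training matrix
#' as `reference` freezes the majority categories for a test cohort.
#'
#' @param G a [genotype_matrix()] to impute.
#' @param reference the matrix on which majority categories are computed
#'   (default `G`). Must cover the same SNPs in the same order.
#' @return `G` with no missing codes.
#' @export
impute_missing <- function(G, reference = G) {
  stopifnot(inherits(G, "genotype_matrix"), inherits(reference, "genotype_matrix"))
  if (!identical(reference$snp_ids, G$snp_ids))
    stop("reference must cover the same SNPs in the same order")
  codes <- G$codes
  need <- which(colSums(is.na(codes)) > 0L)
  for (j in need) {
    counts <- tabulate(reference$codes[, j] + 1L, nbins = 3L)
    if (sum(counts) == 0L)
      stop(sprintf("SNP %s is entirely missing in the reference matrix; cannot impute",
                   G$snp_ids[j]))
    maj <- which.max(counts) - 1L   # which.max takes the first max: lowest code on ties
    codes[is.na(codes[, j]), j] <- maj
  }
  out <- G
  out$codes <- codes
  out
}

#' Read a TSV genotype cohort
#'
#' The TSV dialect: a header row `sample_id<TAB>label<TAB><rs ids...>`, then
#' one row per sample with the label coded 1 = case / 0 = control and
#' genotype categories in `{0, 1, 2, NA}`.
#'
#' @param path file path.
#' @return A list with `G` (a [genotype_matrix()]) and `labels`.
#' @export
read_tsv_matrix <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = "character", check.names = FALSE,
                           na.strings = "NA")
  if (ncol(tab) < 3L || names(tab)[1] != "sample_id" || names(tab)[2] != "label")
    stop("TSV genotype file must start with columns sample_id, label")
  snp_ids <- names(tab)[-(1:2)]
  lab_raw <- tab[[2]]
  if (!all(lab_raw %in% c("0", "1")))
    stop("TSV labels must be 1 (case) or 0 (control)")
  code_chr <- as.matrix(tab[, -(1:2), drop = FALSE])
  bad <- code_chr[!is.na(code_chr)]
  if (length(bad) && !all(bad %in% c("0", "1", "2")))
    stop(sprintf("invalid genotype code(s) in TSV: %s",
                 paste(unique(setdiff(bad, c("0", "1", "2"))), collapse = ", ")))
  codes <- matrix(as.integer(code_chr), nrow = nrow(tab))
  list(G = genotype_matrix(codes, tab[[1]], snp_ids),
       labels = as.integer(lab_raw))
}

#' Write a cohort to disk
#'
#' Writes either the TSV dialect (`<prefix>.tsv`) or PLINK text
#' (`<prefix>.ped` + `<prefix>.map`). In ped output, code 0 becomes two
#' minor alleles, 1 a minor/major pair, 2 two major alleles, and missing
#' calls become `0 0`; phenotypes are written 2 = case / 1 = control. Both
#' formats round-trip bit-exactly through [read_tsv_matrix()] /
#' [read_ped_map()] + [encode_genotypes()].
#'
#' @param G a [genotype_matrix()]; for `format = "ped_map"` it must carry
#'   allele symbols.
#' @param labels per-sample 1/0 labels.
#' @param path_prefix output path without extension.
#' @param format `"tsv"` or `"ped_map"`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(G, labels, path_prefix, format = c("tsv", "ped_map")) {
  format <- match.arg(format)
  stopifnot(inherits(G, "genotype_matrix"), length(labels) == nrow(G$codes))
  if (format == "tsv") {
    path <- paste0(path_prefix, ".tsv")
    tab <- cbind(sample_id = G$sample_ids, label = as.integer(labels),
                 as.data.frame(G$codes, check.names = FALSE))
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, na = "NA")
    return(invisible(path))
  }
  if (is.null(G$alleles))
    stop("ped output needs allele symbols (G$alleles); tsv output does not")
  m <- ncol(G$codes); n <- nrow(G$codes)
  minor <- G$alleles$minor; major <- G$alleles$major
  geno <- matrix("", n, m)
  for (j in seq_len(m)) {
    g <- G$codes[, j]
    gj <- c(paste(minor[j], minor[j]), paste(minor[j], major[j]),
            paste(major[j], major[j]))[g + 1L]
    gj[is.na(g)] <- "0 0"
    geno[, j] <- gj
  }
  ped <- cbind("FAM", G$sample_ids, "0", "0", "0",
               ifelse(as.integer(labels) == 1L, "2", "1"),
               geno)
  ped_path <- paste0(path_prefix, ".ped")
  map_path <- paste0(path_prefix, ".map")
  writeLines(apply(ped, 1L, paste, collapse = " "), ped_path)
  map <- cbind(G$chromosomes, G$snp_ids, "0", seq_len(m))
  writeLines(apply(map, 1L, paste, collapse = "\t"), map_path)
  invisible(c(ped_path, map_path))
}
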