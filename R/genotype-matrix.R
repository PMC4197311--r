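#' Construct a genotype matrix
#'
#' The central container of the package: a diploid dosage matrix (samples in
#' rows, SNPs in columns) together with per-SNP metadata. Each non-missing
#' entry counts copies of `allele_a` in a genotype, so values are 0, 1 or 2;
#' missing genotypes are `NA` (never dosage 0).
#'
#' @param dosage numeric/integer matrix, samples x SNPs, entries in
#'   `{0, 1, 2, NA}`. Row names are sample ids, column names SNP ids.
#' @param snps data.frame with columns `snp_id`, `chrom`, `pos`, `allele_a`,
#'   `allele_b`. `pos` is the 1-based base-pair position on the assembly the
#'   map refers to; `allele_b` may be `NA` for SNPs observed monomorphic.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosage` and `snps`.
#' @examples
#' dos <- rbind(s1 = c(2, 1), s2 = c(0, NA))
#' colnames(dos) <- c("rs1", "rs2")
#' snps <- data.frame(snp_id = c("rs1", "rs2"), chrom = "1",
#'                    pos = c(100L, 200L), allele_a = "A", allele_b = "G")
#' g <- genotype_matrix(dos, snps)
#' @export
genotype_matrix <- function(dosage, snps) {
  if (!is.matrix(dosage)) stop("`dosage` must be a matrix")
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  req <- c("snp_id", "chrom", "pos", "allele_a", "allele_b")
  miss <- setdiff(req, names(snps))
  if (length(miss) > 0)
    stop("`snps` is missing column(s): ", paste(miss, collapse = ", "))
  if (ncol(dosage) != nrow(snps))
    stop("dosage has ", ncol(dosage), " columns but `snps` describes ",
         nrow(snps), " SNPs")
  if (is.null(rownames(dosage)))
    stop("dosage must carry sample ids as row names")
  if (anyDuplicated(rownames(dosage)))
    stop("sample ids must be unique")
  if (anyDuplicated(snps$snp_id))
    stop("snp ids must be unique within a panel: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  if (any(snps$pos < 1, na.rm = TRUE)) stop("SNP positions must be >= 1")
  bad_allele <- !is.na(snps$allele_b) & snps$allele_a == snps$allele_b
  if (any(bad_allele))
    stop("allele_a must differ from allele_b: ",
         paste(snps$snp_id[bad_allele], collapse = ", "))
  vals <- dosage[!is.na(dosage)]
  if (length(vals) > 0 && !all(vals %in% c(0, 1, 2)))
    stop("non-missing dosages must be 0, 1 or 2")
  colnames(dosage) <- snps$snp_id
  rownames(snps) <- NULL
  structure(list(dosage = dosage, snps = snps), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing genotypes: %.2f%%\n", 100 * miss))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$snps$chrom), collapse = ", ")))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample ids of a genotype matrix
#' @param g a `genotype_matrix`
#' @return character vector of sample ids
#' @export
sample_ids <- function(g) rownames(g$dosage)

#' Number of SNPs in a genotype matrix
#' @param g a `genotype_matrix`
#' @return integer SNP count
#' @export
n_snps <- function(g) ncol(g$dosage)

#' Per-SNP call rate
#'
#' Fraction of samples with a non-missing genotype at each SNP.
#'
#' @param g a `genotype_matrix`
#' @return named numeric vector in `[0, 1]`
#' @export
snp_call_rate <- function(g) {
  colMeans(!is.na(g$dosage))
}

#' Per-SNP minor allele frequency
#'
#' Computed over all non-missing chromosomes across all samples in the panel.
#' SNPs with no non-missing calls get `NA`.
#'
#' @param g a `genotype_matrix`
#' @return named numeric vector in `[0, 0.5]`
#' @export
snp_maf <- function(g) {
  n <- 2 * colSums(!is.na(g$dosage))
  a <- colSums(g$dosage, na.rm = TRUE)
  p <- ifelse(n > 0, a / n, NA_real_)
  pmin(p, 1 - p)
}

#' Restrict a genotype matrix to a subset of samples
#' @param g a `genotype_matrix`
#' @param keep character vector of sample ids (order preserved as given)
#' @return a `genotype_matrix`
#' @export
subset_samples <- function(g, keep) {
  missing_ids <- setdiff(keep, sample_ids(g))
  if (length(missing_ids) > 0)
    stop("unknown sample id(s): ", paste(missing_ids, collapse = ", "))
  genotype_matrix(g$dosage[keep, , drop = FALSE], g$snps)
}

subset_snp_idx <- function(g, idx) {
  genotype_matrix(g$dosage[, idx, drop = FALSE],
                  g$snps[idx, , drop = FALSE])
}

#' Sort SNPs by genomic position
#'
#' Orders SNPs by chromosome label then base-pair position, as required by
#' [ld_prune()].
#'
#' @param g a `genotype_matrix`
#' @return a `genotype_matrix` with SNP columns reordered
#' @export
sort_snps <- function(g) {
  subset_snp_idx(g, order(g$snps$chrom, g$snps$pos))
}
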