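#' Read a PLINK text PED/MAP panel
#'
#' Parses space- or tab-delimited PED/MAP files into a [genotype_matrix()].
#' Each PED row holds six leading columns (family, individual, paternal,
#' maternal, sex, phenotype) followed by two allele columns per SNP; the
#' individual id (column 2) is used as the sample id. A `"0 0"` allele pair is
#' a missing genotype. For each SNP, `allele_a` is the lexicographically
#' smaller of the observed alleles, applied uniformly across the panel (the
#' F_ST and LSBL statistics are invariant to this orientation, and it makes
#' write-then-read an identity on dosage). Dosage counts copies of
#' `allele_a`.
#'
#' @param ped_path path to the PED file
#' @param map_path path to the MAP file (columns: chromosome, SNP id,
#'   genetic position, base-pair position)
#' @return a `genotype_matrix`
#' @seealso [write_ped_map()] for the inverse operation
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  nf <- lengths(map_fields)
  if (any(nf < 4))
    stop("MAP parse error at line ", which(nf < 4)[1],
         ": expected 4 columns, found ", nf[which(nf < 4)[1]])
  map <- do.call(rbind, lapply(map_fields, `[`, 1:4))
  snp_id <- map[, 2]
  if (anyDuplicated(snp_id))
    stop("duplicate snp_id in MAP: ",
         paste(unique(snp_id[duplicated(snp_id)]), collapse = ", "))
  n_snp <- length(snp_id)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6 + 2 * n_snp
  nf <- lengths(ped_fields)
  if (any(nf != expected))
    stop("PED parse error at line ", which(nf != expected)[1],
         ": expected ", expected, " columns, found ",
         nf[which(nf != expected)[1]])
  samples <- vapply(ped_fields, `[`, character(1), 2)
  if (anyDuplicated(samples))
    stop("duplicate sample ids in PED: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  n_samp <- length(samples)

  alle <- matrix(unlist(lapply(ped_fields, `[`, -(1:6))),
                 nrow = n_samp, byrow = TRUE)
  a1 <- alle[, seq(1, 2 * n_snp, by = 2), drop = FALSE]
  a2 <- alle[, seq(2, 2 * n_snp, by = 2), drop = FALSE]
  is_miss <- a1 == "0" | a2 == "0"

  allele_a <- character(n_snp)
  allele_b <- rep(NA_character_, n_snp)
  dosage <- matrix(NA_real_, n_samp, n_snp)
  for (j in seq_len(n_snp)) {
    obs1 <- a1[, j][!is_miss[, j]]
    obs2 <- a2[, j][!is_miss[, j]]
    if (length(obs1) == 0) {
      # SNP with no calls at all: alleles unknowable, keep placeholders
      allele_a[j] <- "0"
      next
    }
    distinct <- sort(unique(c(obs1, obs2)))
    if (length(distinct) > 2)
      stop("non-biallelic SNP ", snp_id[j], ": alleles ",
           paste(distinct, collapse = ", "))
    allele_a[j] <- distinct[1]
    if (length(distinct) == 2) allele_b[j] <- distinct[2]
    d <- (a1[, j] == allele_a[j]) + (a2[, j] == allele_a[j])
    d[is_miss[, j]] <- NA_real_
    dosage[, j] <- d
  }
  rownames(dosage) <- samples

  snps <- data.frame(snp_id = snp_id,
                     chrom = map[, 1],
                     pos = as.integer(map[, 4]),
                     allele_a = allele_a,
                     allele_b = allele_b,
                     stringsAsFactors = FALSE)
  genotype_matrix(dosage, snps)
}

#' Write a genotype matrix as PLINK text PED/MAP
#'
#' Round-trips with [read_ped_map()]: reading the written files reproduces
#' sample ids, SNP metadata and dosage. Missing genotypes are written as
#' `"0 0"`.
#'
#' @param g a `genotype_matrix`
#' @param out_prefix output path prefix; `<prefix>.ped` and `<prefix>.map`
#'   are created
#' @return invisibly, the two file paths
#' @export
write_ped_map <- function(g, out_prefix) {
  map <- sprintf("%s\t%s\t0\t%d", g$snps$chrom, g$snps$snp_id, g$snps$pos)
  aa <- g$snps$allele_a
  ab <- g$snps$allele_b
  need_b <- apply(g$dosage, 2, function(d) any(!is.na(d) & d < 2))
  if (any(need_b & is.na(ab)))
    stop("cannot write SNP(s) with unknown second allele: ",
         paste(g$snps$snp_id[need_b & is.na(ab)], collapse = ", "))
  ab[is.na(ab)] <- "0"  # never emitted: such SNPs have dosage 2 or NA only

  n_samp <- nrow(g$dosage)
  n_snp <- ncol(g$dosage)
  geno <- matrix("0 0", n_samp, n_snp)
  for (j in seq_len(n_snp)) {
    d <- g$dosage[, j]
    gj <- geno[, j]
    gj[!is.na(d) & d == 2] <- paste(aa[j], aa[j])
    gj[!is.na(d) & d == 1] <- paste(aa[j], ab[j])
    gj[!is.na(d) & d == 0] <- paste(ab[j], ab[j])
    geno[, j] <- gj
  }
  ids <- rownames(g$dosage)
  lead <- sprintf("%s %s 0 0 0 -9", ids, ids)
  ped <- paste(lead, apply(geno, 1, paste, collapse = " "))

  ped_path <- paste0(out_prefix, ".ped")
  map_path <- paste0(out_prefix, ".map")
  writeLines(ped, ped_path)
  writeLines(map, map_path)
  invisible(c(ped = ped_path, map = map_path))
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
    stop("`", name, "` must be a single fraction in [0, 1]")
}

#' Filter SNPs on call rate and minor allele frequency
#'
#' Retains SNPs whose call rate strictly exceeds `min_call_rate` and whose
#' panel-wide MAF strictly exceeds `min_maf` (the array-QC dialect of
#' "call rate > 95% and MAF > 0.05"). Samples and SNP order are unchanged.
#'
#' @param g a `genotype_matrix`
#' @param min_call_rate minimum call-rate fraction (exclusive), default 0.95
#' @param min_maf minimum MAF (exclusive), default 0.05
#' @return a `genotype_matrix` with the surviving SNPs (possibly 0 of them)
#' @export
filter_snps <- function(g, min_call_rate = 0.95, min_maf = 0.05) {
  check_fraction(min_call_rate, "min_call_rate")
  check_fraction(min_maf, "min_maf")
  cr <- snp_call_rate(g)
  maf <- snp_maf(g)
  keep <- cr > min_call_rate & !is.na(maf) & maf > min_maf
  subset_snp_idx(g, which(keep))
}

#' Subset SNPs on a MAF floor
#'
#' Companion to [filter_snps()] for analyses that use an inclusive MAF bound
#' (the "MAF >= 0.2" dialect used for diversity panels).
#'
#' @param g a `genotype_matrix`
#' @param min_maf MAF threshold
#' @param inclusive if `TRUE` (default) keep SNPs with MAF `>= min_maf`,
#'   otherwise strictly `>`
#' @return a `genotype_matrix`
#' @export
subset_by_maf <- function(g, min_maf, inclusive = TRUE) {
  check_fraction(min_maf, "min_maf")
  maf <- snp_maf(g)
  keep <- if (inclusive) !is.na(maf) & maf >= min_maf
          else !is.na(maf) & maf > min_maf
  subset_snp_idx(g, which(keep))
}

#' Merge two genotype panels with disjoint SNP sets
#'
#' Combines, over the samples present in both panels, the SNPs of `g1`
#' followed by the SNPs of `g2` (e.g. merging a fine-mapping panel into an
#' array panel). Sample order follows `g1`.
#'
#' @param g1,g2 `genotype_matrix` objects with disjoint SNP id sets
#' @return a `genotype_matrix` over the shared samples with
#'   `n_snps(g1) + n_snps(g2)` SNPs
#' @export
merge_panels <- function(g1, g2) {
  dup <- intersect(g1$snps$snp_id, g2$snps$snp_id)
  if (length(dup) > 0)
    stop("merge conflict: snp_id present in both panels: ",
         paste(dup, collapse = ", "))
  shared <- intersect(sample_ids(g1), sample_ids(g2))
  shared <- sample_ids(g1)[sample_ids(g1) %in% shared]
  if (length(shared) == 0)
    stop("panels share no samples")
  dosage <- cbind(g1$dosage[shared, , drop = FALSE],
                  g2$dosage[shared, , drop = FALSE])
  genotype_matrix(dosage, rbind(g1$snps, g2$snps))
}

#' Read a sample-to-population assignment table
#'
#' Two-column TSV: sample id, population label. A header line reading
#' `sample_id<TAB>population` is skipped if present.
#'
#' @param path path to the TSV
#' @return named character vector mapping sample id to population label
#' @export
read_population_file <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) != 2)
    stop("population file must have exactly 2 tab-separated columns")
  if (nrow(tab) > 0 && identical(unname(unlist(tab[1, ])),
                                 c("sample_id", "population")))
    tab <- tab[-1, , drop = FALSE]
  assignment <- stats::setNames(tab[[2]], tab[[1]])
  validate_assignment(assignment)
  assignment
}

#' Write a sample-to-population assignment table
#' @param assignment named character vector (names are sample ids)
#' @param path output TSV path
#' @return invisibly, `path`
#' @export
write_population_file <- function(assignment, path) {
  validate_assignment(assignment)
  utils::write.table(
    data.frame(sample_id = names(assignment), population = assignment),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_assignment <- function(assignment) {
  if (is.null(names(assignment)) || any(!nzchar(names(assignment))))
    stop("assignment must be named by sample id")
  if (anyDuplicated(names(assignment)))
    stop("each sample must have exactly one population label")
  if (any(is.na(assignment) | !nzchar(assignment)))
    stop("population labels must be non-empty")
  invisible(assignment)
}
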