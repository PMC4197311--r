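#' Define a three-group contrast for a selection scan
#'
#' A scan contrasts a focal group (e.g. one highland population) against two
#' contrast groups (e.g. the remaining highland populations and a pool of
#' lowland breeds). The three sample sets must be pairwise disjoint and each
#' must contain at least one diploid sample.
#'
#' @param focal,contrast1,contrast2 character vectors of sample ids
#' @param labels length-3 character vector naming the groups
#' @return an object of class `group_spec`
#' @export
group_spec <- function(focal, contrast1, contrast2,
                       labels = c("focal", "contrast1", "contrast2")) {
  groups <- list(focal = unique(focal), contrast1 = unique(contrast1),
                 contrast2 = unique(contrast2))
  if (any(lengths(groups) == 0))
    stop("each group needs at least one sample")
  overlap <- c(intersect(groups$focal, groups$contrast1),
               intersect(groups$focal, groups$contrast2),
               intersect(groups$contrast1, groups$contrast2))
  if (length(overlap) > 0)
    stop("groups must be pairwise disjoint; shared sample(s): ",
         paste(unique(overlap), collapse = ", "))
  if (length(labels) != 3) stop("`labels` must have length 3")
  structure(c(groups, list(labels = as.character(labels))),
            class = "group_spec")
}

#' @export
print.group_spec <- function(x, ...) {
  cat(sprintf("group_spec: %s (%d) vs %s (%d) vs %s (%d)\n",
              x$labels[1], length(x$focal),
              x$labels[2], length(x$contrast1),
              x$labels[3], length(x$contrast2)))
  invisible(x)
}

pops_to_samples <- function(assignment, pops, what) {
  unknown <- setdiff(pops, unique(assignment))
  if (length(unknown) > 0)
    stop("unknown population label(s) in ", what, ": ",
         paste(unknown, collapse = ", "))
  names(assignment)[assignment %in% pops]
}

#' Build a population-shared scan contrast
#'
#' Focal group = all samples of the highland populations; the two contrast
#' groups are unions of lowland breed labels (e.g. the two lowland breed
#' groups split by a population tree).
#'
#' @param assignment named character vector (sample id -> population)
#' @param highland_pops character vector of focal population labels
#' @param lowland_group1,lowland_group2 character vectors of contrast
#'   population labels
#' @return a `group_spec`
#' @export
build_shared_spec <- function(assignment, highland_pops,
                              lowland_group1, lowland_group2) {
  validate_assignment(assignment)
  all_labels <- c(highland_pops, lowland_group1, lowland_group2)
  if (anyDuplicated(all_labels))
    stop("population label(s) reused across groups: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  group_spec(
    focal = pops_to_samples(assignment, highland_pops, "highland_pops"),
    contrast1 = pops_to_samples(assignment, lowland_group1, "lowland_group1"),
    contrast2 = pops_to_samples(assignment, lowland_group2, "lowland_group2"),
    labels = c(paste(highland_pops, collapse = "+"),
               paste(lowland_group1, collapse = "+"),
               paste(lowland_group2, collapse = "+")))
}

#' Build a population-specific scan contrast
#'
#' Focal group = one highland population; contrast 1 = the remaining
#' highland populations; contrast 2 = the lowland breeds.
#'
#' @param assignment named character vector (sample id -> population)
#' @param focal_pop a single population label
#' @param other_highland character vector of the remaining highland labels
#'   (must be non-empty: the scan is a three-group model)
#' @param lowland character vector of lowland population labels
#' @return a `group_spec`
#' @export
build_specific_spec <- function(assignment, focal_pop, other_highland,
                                lowland) {
  if (length(focal_pop) != 1) stop("`focal_pop` must be a single label")
  if (length(other_highland) == 0)
    stop("`other_highland` must be non-empty: the scan needs three groups")
  validate_assignment(assignment)
  all_labels <- c(focal_pop, other_highland, lowland)
  if (anyDuplicated(all_labels))
    stop("population label(s) reused across groups: ",
         paste(unique(all_labels[duplicated(all_labels)]), collapse = ", "))
  group_spec(
    focal = pops_to_samples(assignment, focal_pop, "focal_pop"),
    contrast1 = pops_to_samples(assignment, other_highland, "other_highland"),
    contrast2 = pops_to_samples(assignment, lowland, "lowland"),
    labels = c(focal_pop,
               paste(other_highland, collapse = "+"),
               paste(lowland, collapse = "+")))
}

#' Pairwise F_ST for the three groups of a scan
#'
#' Computes, at every SNP, the clipped Reich-Hudson F_ST for the three
#' two-way comparisons of a [group_spec()]: focal vs contrast 1 (`d_f1`),
#' focal vs contrast 2 (`d_f2`) and contrast 1 vs contrast 2 (`d_12`).
#' SNPs for which any pair is undefined (fewer than 2 genotyped chromosomes
#' in a group) are flagged `valid = FALSE` and carry `NA` distances.
#'
#' @param g a `genotype_matrix`
#' @param spec a `group_spec`
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `d_f1`, `d_f2`,
#'   `d_12`, `valid`
#' @export
three_group_fst <- function(g, spec) {
  if (!inherits(spec, "group_spec")) stop("`spec` must be a group_spec")
  cf <- allele_counts(g, spec$focal)
  c1 <- allele_counts(g, spec$contrast1)
  c2 <- allele_counts(g, spec$contrast2)
  d_f1 <- reich_fst(cf$a, cf$n, c1$a, c1$n)$clipped
  d_f2 <- reich_fst(cf$a, cf$n, c2$a, c2$n)$clipped
  d_12 <- reich_fst(c1$a, c1$n, c2$a, c2$n)$clipped
  data.frame(snp_id = g$snps$snp_id,
             chrom = g$snps$chrom,
             pos = g$snps$pos,
             d_f1 = d_f1, d_f2 = d_f2, d_12 = d_12,
             valid = !(is.na(d_f1) | is.na(d_f2) | is.na(d_12)),
             row.names = NULL)
}

#' Locus-specific branch length
#'
#' Decomposes three pairwise F_ST values into the branch length private to
#' the focal group: `LSBL = (d_f1 + d_f2 - d_12) / 2`. Negative values are
#' retained (only F_ST itself is clipped); they can never enter the upper
#' outlier tail. Inputs must be clipped F_ST values in `[0, 1]`.
#'
#' @param d_f1 F_ST between focal and contrast 1 (vectorized)
#' @param d_f2 F_ST between focal and contrast 2
#' @param d_12 F_ST between the two contrast groups
#' @return numeric vector of LSBL values in `[-0.5, 1]`
#' @examples
#' lsbl(0.3, 0.2, 0.1)  # 0.2
#' lsbl(1, 1, 0)        # 1: a fixed difference private to the focal group
#' @export
lsbl <- function(d_f1, d_f2, d_12) {
  for (v in list(d_f1, d_f2, d_12)) {
    if (any(is.na(v)) || any(v < 0 | v > 1))
      stop("LSBL inputs must be clipped F_ST values in [0, 1]")
  }
  (d_f1 + d_f2 - d_12) / 2
}

#' Call empirical outliers in the upper LSBL tail
#'
#' Sorts the valid records by descending LSBL (ties broken by ascending
#' (chrom, pos) for determinism) and returns the top
#' `floor(top_fraction * N_valid)` records. The cutoff is the LSBL value of
#' the last included record.
#'
#' @param records data.frame with columns `snp_id`, `chrom`, `pos`, `lsbl`
#'   (one row per valid SNP)
#' @param top_fraction fraction of the empirical distribution to call
#'   (default 0.005, i.e. the top 0.5 percent)
#' @return an object of class `outlier_set`: list with `top_fraction`,
#'   `n_valid`, `cutoff` and `outliers` (the selected records, with a `rank`
#'   column, in descending LSBL order)
#' @export
empirical_outliers <- function(records, top_fraction = 0.005) {
  if (!is.data.frame(records) ||
      !all(c("snp_id", "chrom", "pos", "lsbl") %in% names(records)))
    stop("`records` needs columns snp_id, chrom, pos, lsbl")
  records <- records[!is.na(records$lsbl), , drop = FALSE]
  if (nrow(records) == 0) stop("no valid LSBL record")
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1)
    stop("`top_fraction` must be in (0, 1)")
  ord <- order(-records$lsbl, records$chrom, records$pos)
  records <- records[ord, , drop = FALSE]
  k <- floor(top_fraction * nrow(records))
  out <- records[seq_len(k), , drop = FALSE]
  if (k > 0) out$rank <- seq_len(k)
  rownames(out) <- NULL
  structure(list(top_fraction = top_fraction,
                 n_valid = nrow(records),
                 cutoff = if (k > 0) out$lsbl[k] else NA_real_,
                 outliers = out),
            class = "outlier_set")
}

#' @export
print.outlier_set <- function(x, ...) {
  cat(sprintf(
    "outlier_set: %d outliers (top %.3g%% of %d valid SNPs), cutoff %.4g\n",
    nrow(x$outliers), 100 * x$top_fraction, x$n_valid, x$cutoff))
  invisible(x)
}

#' Run a full LSBL selection scan
#'
#' Convenience wrapper: three-group pairwise F_ST at every SNP, LSBL for the
#' valid SNPs, and empirical outlier calling in the upper tail.
#'
#' @param g a `genotype_matrix` (already filtered as desired)
#' @param spec a `group_spec`
#' @param top_fraction outlier fraction (default 0.005)
#' @return an object of class `lsbl_scan`: list with `records` (per-SNP
#'   data.frame with `d_f1`, `d_f2`, `d_12`, `lsbl`, `valid`, `is_outlier`,
#'   `rank`), `outliers` (an `outlier_set`), `cutoff`, `n_valid`, `labels`
#' @export
lsbl_scan <- function(g, spec, top_fraction = 0.005) {
  rec <- three_group_fst(g, spec)
  rec$lsbl <- NA_real_
  v <- rec$valid
  rec$lsbl[v] <- lsbl(rec$d_f1[v], rec$d_f2[v], rec$d_12[v])
  out <- empirical_outliers(rec[v, c("snp_id", "chrom", "pos", "lsbl")],
                            top_fraction)
  rec$is_outlier <- rec$snp_id %in% out$outliers$snp_id
  rec$rank <- NA_integer_
  if (nrow(out$outliers) > 0)
    rec$rank[match(out$outliers$snp_id, rec$snp_id)] <- out$outliers$rank
  structure(list(records = rec, outliers = out,
                 cutoff = out$cutoff, n_valid = out$n_valid,
                 top_fraction = top_fraction, labels = spec$labels),
            class = "lsbl_scan")
}

#' @export
print.lsbl_scan <- function(x, ...) {
  cat(sprintf("lsbl_scan: focal %s vs %s / %s\n",
              x$labels[1], x$labels[2], x$labels[3]))
  cat(sprintf("  %d valid SNPs, %d outliers at top %.3g%%, cutoff %.4g\n",
              x$n_valid, nrow(x$outliers$outliers),
              100 * x$top_fraction, x$cutoff))
  invisible(x)
}

#' Per-population allele-A frequencies at selected SNPs
#'
#' The frequency table behind allele-frequency heat maps of top outlier
#' loci: `a / n` per population per SNP, `NA` where a population has no
#' genotyped chromosomes.
#'
#' @param g a `genotype_matrix`
#' @param assignment named character vector (sample id -> population)
#' @param snp_ids SNP ids to report
#' @return numeric matrix, populations x SNPs
#' @export
frequency_table <- function(g, assignment, snp_ids) {
  validate_assignment(assignment)
  unknown <- setdiff(snp_ids, g$snps$snp_id)
  if (length(unknown) > 0)
    stop("unknown snp_id(s): ", paste(unknown, collapse = ", "))
  assignment <- assignment[names(assignment) %in% sample_ids(g)]
  pops <- unique(assignment)
  idx <- match(snp_ids, g$snps$snp_id)
  freq <- matrix(NA_real_, length(pops), length(snp_ids),
                 dimnames = list(pops, snp_ids))
  for (p in pops) {
    ac <- allele_counts(g, names(assignment)[assignment == p])
    freq[p, ] <- ifelse(ac$n[idx] > 0, ac$a[idx] / ac$n[idx], NA_real_)
  }
  freq
}
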