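#' Genotypic (composite) LD r-squared between two SNPs
#'
#' Squared Pearson correlation of the two dosage vectors over samples with
#' non-missing calls at both SNPs. This is the composite r-squared
#' appropriate for unphased array genotypes. `NA` when fewer than 2 complete
#' samples remain or either SNP has zero variance on the complete subset
#' (callers treat such pairs as prune-ineligible).
#'
#' @param g a `genotype_matrix`
#' @param snp_i,snp_j SNP ids or column indices
#' @return a single r-squared value in `[0, 1]`, or `NA`
#' @export
ld_r2 <- function(g, snp_i, snp_j) {
  idx <- function(s) {
    if (is.character(s)) {
      i <- match(s, g$snps$snp_id)
      if (is.na(i)) stop("unknown snp_id: ", s)
      i
    } else as.integer(s)
  }
  x <- g$dosage[, idx(snp_i)]
  y <- g$dosage[, idx(snp_j)]
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}

# r^2 matrix for a window of dosage columns, pairwise-complete
window_r2 <- function(dos) {
  suppressWarnings(r <- stats::cor(dos, use = "pairwise.complete.obs"))
  r^2
}

#' Prune SNPs to a low-LD subset
#'
#' Sliding-window LD pruning over SNPs sorted by (chromosome, position).
#' Within each window of `window_snps` retained SNPs (advancing by
#' `step_snps`), while any retained pair has `r^2 >= r2_max`, the SNP of the
#' pair with the lower panel-wide MAF is removed (ties: the later map
#' position is removed). Passes repeat until no removal occurs, so the
#' retained set is a fixpoint and the operation is idempotent. Pairs with
#' undefined r-squared (monomorphic on the shared samples) are never pruned.
#'
#' @param g a `genotype_matrix` with SNPs sorted by (chrom, pos); see
#'   [sort_snps()]
#' @param r2_max r-squared threshold; retained intra-window pairs end below
#'   it (default 0.3)
#' @param window_snps window size in SNPs (default 50)
#' @param step_snps step size in SNPs (default 5)
#' @return a `genotype_matrix` containing the retained SNPs
#' @export
ld_prune <- function(g, r2_max = 0.3, window_snps = 50, step_snps = 5) {
  if (window_snps < 2 || step_snps < 1)
    stop("window_snps must be >= 2 and step_snps >= 1")
  o <- order(g$snps$chrom, g$snps$pos)
  if (!identical(o, seq_len(n_snps(g))))
    stop("SNPs must be sorted by (chrom, pos); call sort_snps() first")
  maf <- snp_maf(g)
  pos <- g$snps$pos
  keep <- rep(TRUE, n_snps(g))

  for (ch in unique(g$snps$chrom)) {
    ch_idx <- which(g$snps$chrom == ch)
    repeat {
      removed <- FALSE
      active <- ch_idx[keep[ch_idx]]
      if (length(active) < 2) break
      starts <- seq(1, length(active), by = step_snps)
      for (s in starts) {
        w <- active[s:min(s + window_snps - 1, length(active))]
        w <- w[keep[w]]  # may have been pruned by an earlier window
        if (length(w) < 2) next
        repeat {
          r2 <- window_r2(g$dosage[, w, drop = FALSE])
          r2[!is.finite(r2)] <- 0
          diag(r2) <- 0
          viol <- which(r2 >= r2_max, arr.ind = TRUE)
          viol <- viol[viol[, 1] < viol[, 2], , drop = FALSE]
          if (nrow(viol) == 0) break
          viol <- viol[order(viol[, 1], viol[, 2]), , drop = FALSE]
          i <- w[viol[1, 1]]; j <- w[viol[1, 2]]
          drop_snp <- if (is.na(maf[i]) || is.na(maf[j])) j
            else if (maf[i] < maf[j]) i
            else if (maf[j] < maf[i]) j
            else if (pos[i] > pos[j]) i else j
          keep[drop_snp] <- FALSE
          removed <- TRUE
          w <- w[w != drop_snp]
          if (length(w) < 2) break
        }
      }
      if (!removed) break
    }
  }
  subset_snp_idx(g, which(keep))
}
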