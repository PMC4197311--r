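#' Per-SNP allele counts within a group of samples
#'
#' For each SNP, `a` is the number of copies of `allele_a` among the
#' successfully genotyped chromosomes of the group and `n` the number of such
#' chromosomes (2 per non-missing diploid genotype). These `(a, n)` pairs are
#' the sole input to the F_ST estimator and the diversity statistics.
#'
#' @param g a `genotype_matrix`
#' @param members character vector of sample ids forming the group
#' @return data.frame with columns `snp_id`, `a`, `n`
#' @export
allele_counts <- function(g, members) {
  if (length(members) == 0) stop("empty member set")
  unknown <- setdiff(members, sample_ids(g))
  if (length(unknown) > 0)
    stop("unknown sample id(s): ", paste(unknown, collapse = ", "))
  sub <- g$dosage[members, , drop = FALSE]
  data.frame(snp_id = g$snps$snp_id,
             a = colSums(sub, na.rm = TRUE),
             n = 2 * colSums(!is.na(sub)),
             row.names = NULL)
}

check_counts <- function(a, n) {
  if (any(is.na(a) | is.na(n))) stop("allele counts must not be NA")
  if (any(a < 0 | n < 0 | a > n)) stop("allele counts require 0 <= a <= n")
}

#' Reich-Hudson unbiased F_ST from allele counts
#'
#' The unbiased two-population F_ST estimator computed from allele counts
#' `(a_i, n_i)`, where `n_i` is counted in chromosomes:
#' \deqn{h_i = a_i (n_i - a_i) / (n_i (n_i - 1))}
#' \deqn{N = (a_1/n_1 - a_2/n_2)^2 - h_1/n_1 - h_2/n_2, \quad D = N + h_1 + h_2}
#' \deqn{F_{ST} = N / D.}
#' The raw estimate may be negative; because F_ST is defined on `[0, 1]`,
#' negative values are clipped to 0 in the `clipped` column. When `D = 0`
#' (both groups fixed for the same allele) the estimate is 0 by convention.
#' Pairs with fewer than 2 chromosomes in either group are undefined and
#' returned as `NA` (callers treat such SNPs as missing for that pair).
#'
#' @param a1,n1 allele-A count and chromosome count in group 1 (vectorized)
#' @param a2,n2 allele-A count and chromosome count in group 2
#' @return data.frame with columns `raw` and `clipped`
#' @examples
#' reich_fst(20, 20, 0, 20)   # fixed difference: clipped = 1
#' reich_fst(10, 20, 10, 20)  # identical frequencies: clipped = 0
#' @export
reich_fst <- function(a1, n1, a2, n2) {
  check_counts(a1, n1)
  check_counts(a2, n2)
  k <- max(length(a1), length(a2))
  a1 <- rep_len(a1, k); n1 <- rep_len(n1, k)
  a2 <- rep_len(a2, k); n2 <- rep_len(n2, k)
  defined <- n1 >= 2 & n2 >= 2
  raw <- rep(NA_real_, k)
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  num <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
  den <- num + h1 + h2
  raw[defined] <- ifelse(den[defined] == 0, 0,
                         num[defined] / den[defined])
  data.frame(raw = raw, clipped = pmax(raw, 0))
}

#' Genome-wide F_ST as a ratio of sums
#'
#' Aggregates the per-SNP numerators and denominators of [reich_fst()] into a
#' single genome-wide estimate, `sum(N) / sum(D)`, the recommended way to
#' average the Hudson-type estimator across loci (less biased than averaging
#' per-SNP ratios). SNPs undefined in either group are skipped.
#'
#' @inheritParams reich_fst
#' @return a single numeric F_ST estimate
#' @export
reich_fst_genomewide <- function(a1, n1, a2, n2) {
  check_counts(a1, n1)
  check_counts(a2, n2)
  keep <- n1 >= 2 & n2 >= 2
  a1 <- a1[keep]; n1 <- n1[keep]; a2 <- a2[keep]; n2 <- n2[keep]
  if (length(a1) == 0) stop("no SNP defined in both groups")
  h1 <- a1 * (n1 - a1) / (n1 * (n1 - 1))
  h2 <- a2 * (n2 - a2) / (n2 * (n2 - 1))
  num <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
  den <- num + h1 + h2
  sum(num) / sum(den)
}

#' Unbiased expected heterozygosity
#'
#' `H_E = 2 p (1 - p) n / (n - 1)` with `p = a / n`, the small-sample
#' unbiased gene diversity at a biallelic SNP. `NA` where `n < 2`.
#'
#' @param a allele-A counts (vectorized)
#' @param n chromosome counts
#' @return numeric vector of H_E values
#' @export
expected_heterozygosity <- function(a, n) {
  check_counts(a, n)
  p <- ifelse(n > 0, a / n, NA_real_)
  he <- 2 * p * (1 - p) * n / (n - 1)
  he[n < 2] <- NA_real_
  he
}

#' Proportion of polymorphic markers
#'
#' Fraction of SNPs segregating within a population (`0 < a < n`), among SNPs
#' with at least 2 genotyped chromosomes.
#'
#' @param a allele-A counts per SNP
#' @param n chromosome counts per SNP
#' @return a single fraction in `[0, 1]`
#' @export
proportion_polymorphic <- function(a, n) {
  check_counts(a, n)
  ok <- n >= 2
  if (!any(ok)) stop("no SNP with >= 2 genotyped chromosomes")
  mean(a[ok] > 0 & a[ok] < n[ok])
}

#' Rarefaction allelic richness
#'
#' Expected number of distinct alleles observed in a standardized subsample
#' of `g` chromosomes drawn without replacement from the `n` genotyped
#' chromosomes:
#' \deqn{A_R(g) = \sum_j \left[1 - \binom{n - a_j}{g} / \binom{n}{g}\right]}
#' over the two allele counts `a_j \in \{a, n - a\}` (a binomial coefficient
#' with `m < g` is 0). Values lie in `[1, 2]` for a biallelic SNP; SNPs with
#' `n < g` are undefined (`NA`) and should be excluded from population means.
#'
#' @param a allele-A counts per SNP (vectorized)
#' @param n chromosome counts per SNP
#' @param g standardized subsample size in chromosomes (single positive
#'   integer)
#' @return numeric vector of A_R values
#' @export
allelic_richness <- function(a, n, g) {
  check_counts(a, n)
  if (!is.numeric(g) || length(g) != 1 || g < 1 || g != round(g))
    stop("`g` must be a single positive integer (chromosomes)")
  k <- max(length(a), length(n))
  a <- rep_len(a, k); n <- rep_len(n, k)
  term <- function(cnt) {
    # P(allele with cnt copies appears in the subsample)
    m <- n - cnt
    ratio <- ifelse(m < g, 0, exp(lchoose(m, g) - lchoose(n, g)))
    ifelse(cnt == 0, 0, 1 - ratio)
  }
  ar <- term(a) + term(n - a)
  ar[n < g] <- NA_real_
  ar
}

#' Per-population diversity summary
#'
#' Mean expected heterozygosity, proportion of polymorphic markers and mean
#' rarefaction allelic richness for each population in the assignment.
#' A_R is averaged over SNPs with at least `g` genotyped chromosomes in the
#' population; H_E over SNPs with at least 2.
#'
#' @param g a `genotype_matrix`
#' @param assignment named character vector (sample id -> population)
#' @param g_size standardization size for allelic richness, in chromosomes
#' @return data.frame with one row per population: `population`, `n_samples`,
#'   `h_e`, `p_n`, `a_r`, `g`
#' @export
diversity_summary <- function(g, assignment, g_size) {
  validate_assignment(assignment)
  assignment <- assignment[names(assignment) %in% sample_ids(g)]
  if (length(assignment) == 0)
    stop("no assigned sample is present in the genotype matrix")
  pops <- unique(assignment)
  rows <- lapply(pops, function(p) {
    members <- names(assignment)[assignment == p]
    ac <- allele_counts(g, members)
    he <- expected_heterozygosity(ac$a, ac$n)
    ar <- allelic_richness(ac$a, ac$n, g_size)
    data.frame(population = p,
               n_samples = length(members),
               h_e = mean(he, na.rm = TRUE),
               p_n = proportion_polymorphic(ac$a, ac$n),
               a_r = mean(ar, na.rm = TRUE),
               g = g_size)
  })
  do.call(rbind, rows)
}
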