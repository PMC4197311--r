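# Independent oracle implementations used to cross-check the package.
# Deliberately written as plain scalar transcriptions, sharing no code with
# the functions they verify.

# Reich-Hudson unbiased Fst, one SNP at a time
oracle_reich <- function(a1, n1, a2, n2) {
  h1 <- (a1 * (n1 - a1)) / (n1 * (n1 - 1))
  h2 <- (a2 * (n2 - a2)) / (n2 * (n2 - 1))
  nn <- (a1 / n1 - a2 / n2)^2 - h1 / n1 - h2 / n2
  dd <- nn + h1 + h2
  raw <- if (dd == 0) 0 else nn / dd
  c(raw = raw, clipped = max(raw, 0))
}

# expected distinct alleles in a subsample of g chromosomes, by exhaustive
# enumeration of all subsets of the n chromosomes
oracle_richness_enum <- function(a, n, g) {
  chroms <- c(rep("A", a), rep("B", n - a))
  subs <- utils::combn(n, g)
  mean(apply(subs, 2, function(ix) length(unique(chroms[ix]))))
}

# hypergeometric upper tail by exhaustive enumeration of candidate draws
oracle_enrich_enum <- function(universe, term, n_cand, k_obs) {
  subs <- utils::combn(length(universe), n_cand)
  hits <- apply(subs, 2, function(ix)
    length(intersect(universe[ix], term)) >= k_obs)
  mean(hits)
}

# quick genotype_matrix around a dosage matrix
make_gm <- function(dosage, chrom = NULL, pos = NULL) {
  m <- ncol(dosage)
  if (is.null(rownames(dosage)))
    rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  if (is.null(chrom)) chrom <- rep("1", m)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  genotype_matrix(dosage, data.frame(
    snp_id = sprintf("rs%03d", seq_len(m)),
    chrom = chrom, pos = pos, allele_a = "A", allele_b = "C",
    stringsAsFactors = FALSE))
}

extdata <- function(name) {
  path <- system.file("extdata", name, package = "lsblscan")
  if (!nzchar(path)) path <- file.path("..", "..", "inst", "extdata", name)
  path
}
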