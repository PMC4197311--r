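#' Allele-sharing distance between samples
#'
#' For each pair of samples, over the `M` SNPs non-missing in both, the
#' distance is `1 - (IBS2 + 0.5 * IBS1) / M`, where IBS2/IBS1 count SNPs at
#' which the two genotypes share both or one allele. In dosage terms this is
#' `mean(|x - y|) / 2`. Identical samples are at distance 0, opposite
#' homozygotes at every SNP at distance 1.
#'
#' @param g a `genotype_matrix` with at least 2 samples and 1 SNP
#' @return a symmetric numeric matrix with sample ids as dimnames
#' @export
allele_sharing_dist <- function(g) {
  dos <- g$dosage
  if (nrow(dos) < 2) stop("need at least 2 samples")
  if (ncol(dos) < 1) stop("need at least 1 SNP")
  ids <- rownames(dos)
  n <- nrow(dos)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    xi <- dos[i, ]
    for (j in (i + 1):n) {
      diff <- abs(xi - dos[j, ])
      m <- sum(!is.na(diff))
      if (m == 0)
        stop("samples ", ids[i], " and ", ids[j],
             " share no non-missing SNP")
      d[i, j] <- d[j, i] <- sum(diff, na.rm = TRUE) / (2 * m)
    }
  }
  d
}

#' Write a labeled square distance matrix as TSV
#' @param d symmetric matrix with dimnames
#' @param path output path
#' @return invisibly, `path`
#' @export
write_distance_matrix <- function(d, path) {
  utils::write.table(cbind(id = rownames(d), as.data.frame(d)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labeled square distance matrix from TSV
#' @param path path written by [write_distance_matrix()]
#' @return symmetric numeric matrix with dimnames
#' @export
read_distance_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  labels <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1, drop = FALSE])
  dimnames(d) <- list(labels, labels)
  storage.mode(d) <- "double"
  d
}
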