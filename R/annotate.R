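#' Candidate regions around outlier SNPs
#'
#' Each outlier SNP nominates a candidate region of `flank` bp upstream and
#' downstream of its position (default 50 kb each side), clamped at the
#' chromosome start. Coordinates are reported 1-based closed.
#'
#' @param outliers an `outlier_set`, an `lsbl_scan`, or a data.frame with
#'   columns `snp_id`, `chrom`, `pos`
#' @param flank flanking distance in bp on each side (default 50000)
#' @return data.frame with columns `snp_id`, `chrom`, `pos`, `window_start`,
#'   `window_end`
#' @export
candidate_regions <- function(outliers, flank = 50000) {
  if (inherits(outliers, "lsbl_scan")) outliers <- outliers$outliers
  if (inherits(outliers, "outlier_set")) outliers <- outliers$outliers
  if (!is.data.frame(outliers) ||
      !all(c("snp_id", "chrom", "pos") %in% names(outliers)))
    stop("`outliers` needs columns snp_id, chrom, pos")
  if (!is.numeric(flank) || length(flank) != 1 || flank < 0)
    stop("`flank` must be a single non-negative number of bp")
  data.frame(snp_id = outliers$snp_id,
             chrom = outliers$chrom,
             pos = outliers$pos,
             window_start = pmax(1, outliers$pos - flank),
             window_end = outliers$pos + flank,
             row.names = NULL)
}

#' Read gene models from BED or GFF3
#'
#' BED input takes the `name` column as the gene id. GFF3 input keeps
#' features of type `gene` when present (all features otherwise) and takes
#' the gene id from the first available of `gene_id_field`, `gene_id`, `ID`,
#' `Name`. Coordinates are returned 1-based closed (BED's 0-based half-open
#' start is converted on import).
#'
#' @param path path to a `.bed`, `.gff`, `.gff3` or `.gtf` file
#' @param gene_id_field optional attribute key holding the gene id (GFF3/GTF
#'   only)
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`
#' @export
read_gene_models <- function(path, gene_id_field = NULL) {
  gr <- rtracklayer::import(path)
  mc <- S4Vectors::mcols(gr)
  if ("type" %in% names(mc) && any(mc$type == "gene"))
    gr <- gr[mc$type == "gene"]
  mc <- S4Vectors::mcols(gr)
  keys <- c(gene_id_field, "gene_id", "ID", "Name", "name")
  key <- keys[keys %in% names(mc)][1]
  if (is.na(key) || is.null(key))
    stop("no gene id field found (looked for: ",
         paste(keys, collapse = ", "), ")")
  data.frame(gene_id = as.character(mc[[key]]),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             row.names = NULL)
}

#' Map candidate regions to overlapping genes
#'
#' A gene is hit by a region iff their intervals intersect by at least 1 bp
#' (genes need not be fully contained). The candidate gene set of a scan is
#' the deduplicated union of hit gene ids. Chromosome labels present in the
#' regions but absent from the gene annotation trigger a warning (zero hits
#' on those chromosomes).
#'
#' @param regions data.frame from [candidate_regions()]
#' @param genes data.frame from [read_gene_models()] (or with the same
#'   columns; `start`/`end` 1-based closed, `start <= end`)
#' @return data.frame with columns `snp_id`, `gene_id`, `overlap_bp`
#' @export
map_regions_to_genes <- function(regions, genes) {
  if (any(genes$start > genes$end)) stop("gene intervals need start <= end")
  missing_chrom <- setdiff(unique(regions$chrom), unique(genes$chrom))
  if (length(missing_chrom) > 0)
    warning("no gene annotation on chromosome(s): ",
            paste(missing_chrom, collapse = ", "))
  gr_reg <- GenomicRanges::GRanges(
    regions$chrom,
    IRanges::IRanges(regions$window_start, regions$window_end))
  gr_gene <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start, genes$end))
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_reg, gr_gene, minoverlap = 1))
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  ov <- pmin(regions$window_end[q], genes$end[s]) -
        pmax(regions$window_start[q], genes$start[s]) + 1
  data.frame(snp_id = regions$snp_id[q],
             gene_id = genes$gene_id[s],
             overlap_bp = as.integer(ov),
             row.names = NULL)
}

#' Read gene sets from a GMT file
#'
#' @param path path to a tab-delimited GMT file (term, description, member
#'   genes)
#' @return named list of character vectors of gene ids
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' Hypergeometric gene-set enrichment with Bonferroni correction
#'
#' For each gene set, tests over-representation of the candidate genes by
#' the hypergeometric upper tail `P(X >= k)` with universe size `N`, term
#' size `K` (after intersecting the set with the universe), candidate count
#' `n` and overlap `k`. Terms with no universe gene are dropped before
#' correction; terms with `k = 0` report `p_raw = 1` and are retained so the
#' multiple-testing count is transparent. Bonferroni:
#' `p_corrected = min(1, p_raw * n_terms_tested)`.
#'
#' @param candidates character vector of candidate gene ids (must be a
#'   subset of `universe`)
#' @param universe character vector of all gene ids eligible for candidacy
#' @param gene_sets named list of character vectors (e.g. from [read_gmt()])
#' @return data.frame sorted by ascending `p_corrected`, with columns
#'   `term_id`, `k`, `K`, `n`, `N`, `p_raw`, `p_corrected`
#' @export
gene_set_enrichment <- function(candidates, universe, gene_sets) {
  universe <- unique(universe)
  candidates <- unique(candidates)
  if (length(universe) == 0) stop("empty universe")
  if (length(candidates) == 0) stop("empty candidate set")
  stray <- setdiff(candidates, universe)
  if (length(stray) > 0)
    stop("candidate gene(s) not in universe: ",
         paste(stray, collapse = ", "))
  if (length(gene_sets) == 0 || is.null(names(gene_sets)))
    stop("`gene_sets` must be a non-empty named list")
  N <- length(universe)
  n <- length(candidates)
  K <- vapply(gene_sets, function(s) length(intersect(s, universe)),
              integer(1))
  keep <- K >= 1
  if (!any(keep)) stop("no gene set intersects the universe")
  gene_sets <- gene_sets[keep]
  K <- K[keep]
  k <- vapply(gene_sets, function(s) length(intersect(s, candidates)),
              integer(1))
  p_raw <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  m <- length(gene_sets)
  res <- data.frame(term_id = names(gene_sets),
                    k = k, K = K, n = n, N = N,
                    p_raw = p_raw,
                    p_corrected = pmin(1, p_raw * m),
                    row.names = NULL)
  res[order(res$p_corrected, res$p_raw, res$term_id), , drop = FALSE]
}
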