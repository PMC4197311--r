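# Thin orchestration layer: each run_* function wires file-based inputs
# through the package operations and writes TSV outputs plus a key-value
# metadata sidecar recording every parameter and stage count.

out_path <- function(out_dir, name, force) {
  path <- file.path(out_dir, name)
  if (file.exists(path) && !force)
    stop("output exists (use force = TRUE to overwrite): ", path)
  path
}

write_metadata <- function(meta, path) {
  writeLines(paste(names(meta), vapply(meta, paste, character(1),
                                       collapse = ","), sep = "\t"), path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate a panel and write it to disk
#'
#' Writes `panel.ped`/`panel.map`, `populations.tsv`, `truth.tsv` and
#' `simulate.meta.tsv` into `out_dir`.
#'
#' @param cfg a [sim_config()]
#' @param out_dir output directory (created if needed)
#' @param force overwrite existing outputs (default `FALSE`)
#' @return invisibly, the simulated panel (as from [simulate_panel()])
#' @export
run_simulate <- function(cfg, out_dir, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- simulate_panel(cfg)
  prefix <- sub("\\.ped$", "", out_path(out_dir, "panel.ped", force))
  write_ped_map(panel$genotypes, prefix)
  write_population_file(panel$assignment,
                        out_path(out_dir, "populations.tsv", force))
  write_tsv(panel$truth, out_path(out_dir, "truth.tsv", force))
  write_metadata(list(
    stage = "simulate", seed = cfg$seed, n_snps = cfg$n_snps,
    populations = paste0(cfg$populations$label, ":",
                         cfg$populations$n_individuals, ":",
                         cfg$populations$drift),
    missing_rate = cfg$missing_rate,
    n_selected = if (is.null(cfg$selected)) 0 else sum(cfg$selected$n_loci)),
    out_path(out_dir, "simulate.meta.tsv", force))
  invisible(panel)
}

#' Run an LSBL selection scan from files
#'
#' Reads a PED/MAP panel and a population file, applies the call-rate/MAF
#' filter, builds the three-group contrast, scans, and writes
#' `scan.tsv` (snp_id, chrom, pos, d_f1, d_f2, d_12, lsbl, is_outlier,
#' rank) plus `scan.meta.tsv` with filter-stage counts, cutoff and N_valid.
#'
#' @param ped,map,populations input file paths
#' @param focal_pops,contrast1_pops,contrast2_pops population label sets
#'   defining the three groups
#' @param out_dir output directory
#' @param top_fraction outlier fraction (default 0.005)
#' @param min_call_rate,min_maf strict filter thresholds (defaults 0.95,
#'   0.05)
#' @param force overwrite existing outputs
#' @return invisibly, the `lsbl_scan` object
#' @export
run_scan <- function(ped, map, populations, focal_pops, contrast1_pops,
                     contrast2_pops, out_dir, top_fraction = 0.005,
                     min_call_rate = 0.95, min_maf = 0.05, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_ped_map(ped, map)
  n_input <- n_snps(g)
  gf <- filter_snps(g, min_call_rate = min_call_rate, min_maf = min_maf)
  assign <- read_population_file(populations)
  spec <- build_shared_spec(assign, focal_pops, contrast1_pops,
                            contrast2_pops)
  scan <- lsbl_scan(gf, spec, top_fraction = top_fraction)
  write_tsv(scan$records[, c("snp_id", "chrom", "pos", "d_f1", "d_f2",
                             "d_12", "lsbl", "is_outlier", "rank")],
            out_path(out_dir, "scan.tsv", force))
  write_metadata(list(
    stage = "scan", ped = ped, map = map,
    focal = paste(focal_pops, collapse = "+"),
    contrast1 = paste(contrast1_pops, collapse = "+"),
    contrast2 = paste(contrast2_pops, collapse = "+"),
    min_call_rate = min_call_rate, min_maf = min_maf,
    top_fraction = top_fraction,
    n_snps_input = n_input, n_snps_filtered = n_snps(gf),
    n_valid = scan$n_valid,
    n_outliers = nrow(scan$outliers$outliers),
    cutoff = scan$cutoff),
    out_path(out_dir, "scan.meta.tsv", force))
  invisible(scan)
}

#' Per-population diversity statistics from files
#'
#' Reads a panel, restricts it to SNPs with MAF at or above `min_maf`
#' (inclusive), and writes `diversity.tsv` with H_E, P_N and A_R per
#' population.
#'
#' @param ped,map,populations input file paths
#' @param g_size rarefaction size in chromosomes for allelic richness
#' @param out_dir output directory
#' @param min_maf inclusive MAF floor (default 0.2)
#' @param force overwrite existing outputs
#' @return invisibly, the diversity data.frame
#' @export
run_diversity <- function(ped, map, populations, g_size, out_dir,
                          min_maf = 0.2, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_ped_map(ped, map)
  gs <- subset_by_maf(g, min_maf, inclusive = TRUE)
  assign <- read_population_file(populations)
  div <- diversity_summary(gs, assign, g_size)
  write_tsv(div, out_path(out_dir, "diversity.tsv", force))
  write_metadata(list(stage = "diversity", min_maf = min_maf,
                      g_size = g_size, n_snps_input = n_snps(g),
                      n_snps_used = n_snps(gs)),
                 out_path(out_dir, "diversity.meta.tsv", force))
  invisible(div)
}

#' Allele-sharing NJ tree from files
#'
#' Reads a panel, computes the pairwise allele-sharing distance between
#' individuals, builds the neighbor-joining tree and writes
#' `distances.tsv` and `tree.nwk`.
#'
#' @param ped,map input file paths
#' @param out_dir output directory
#' @param force overwrite existing outputs
#' @return invisibly, the [ape::phylo] tree
#' @export
run_tree <- function(ped, map, out_dir, force = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- read_ped_map(ped, map)
  d <- allele_sharing_dist(g)
  tree <- neighbor_joining(d)
  write_distance_matrix(d, out_path(out_dir, "distances.tsv", force))
  write_newick(tree, out_path(out_dir, "tree.nwk", force))
  write_metadata(list(stage = "tree", n_samples = nrow(d),
                      n_snps = n_snps(g)),
                 out_path(out_dir, "tree.meta.tsv", force))
  invisible(tree)
}
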