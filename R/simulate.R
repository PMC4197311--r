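#' Configure a synthetic genotype panel
#'
#' Defines a Balding-Nichols simulation: each SNP has an ancestral allele-A
#' frequency drawn uniformly from `ancestral_maf_range`, and each population
#' draws its own frequency from `Beta(p(1-F)/F, (1-p)(1-F)/F)` around the
#' ancestral `p`, where `F` is the population's drift parameter (`F = 0`
#' means no drift: the population keeps `p` exactly). Genotypes are then
#' binomial (Hardy-Weinberg within populations) with independent missingness.
#'
#' Selection is modeled post hoc on the focal population's drifted
#' frequency, in one of three modes per [selection_spec()]: a signed
#' frequency shift `delta` (the drifted frequency plus `delta`, clamped to
#' `[0, 1]`); an absolute target frequency; or `"fix_minor"`, a completed
#' sweep fixing the allele that is minor in the drifted focal population
#' (realized shift always at least 0.5, which makes it the default for
#' power studies).
#'
#' The defaults emulate an array-scale selection-scan design: one focal
#' population of 30 diploids with drift `F = 0.1` against two contrast pools
#' of 100 diploids each with effective drift `F = 0.03` (a pool of many
#' breeds drifts less than any single breed), ascertained ancestral
#' frequencies in (0.05, 0.95), and 2\% missing genotypes.
#'
#' @param n_snps number of independent SNPs
#' @param populations data.frame with columns `label`, `n_individuals`,
#'   `drift` (per-population Balding-Nichols F in `[0, 1)`)
#' @param selected `NULL` for an all-neutral panel, or a data.frame from
#'   [selection_spec()]
#' @param ancestral_maf_range length-2 numeric, uniform range for the
#'   ancestral allele-A frequency
#' @param missing_rate per-call missingness probability in `[0, 1)`
#' @param seed integer seed (below 2^31 - 1); all simulation randomness
#'   derives from it
#' @param n_chrom number of chromosome labels SNPs are spread across
#' @param spacing_bp base-pair spacing between consecutive SNPs on a
#'   chromosome
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_snps = 10000,
                       populations = data.frame(
                         label = c("Highland", "Lowland1", "Lowland2"),
                         n_individuals = c(30, 100, 100),
                         drift = c(0.10, 0.03, 0.03)),
                       selected = NULL,
                       ancestral_maf_range = c(0.05, 0.95),
                       missing_rate = 0.02,
                       seed = 1,
                       n_chrom = 18,
                       spacing_bp = 5000) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  if (!all(c("label", "n_individuals", "drift") %in% names(populations)))
    stop("`populations` needs columns label, n_individuals, drift")
  if (anyDuplicated(populations$label))
    stop("population labels must be unique")
  if (any(populations$n_individuals < 1))
    stop("each population needs at least 1 individual")
  if (any(populations$drift < 0 | populations$drift >= 1))
    stop("drift must be in [0, 1)")
  if (length(ancestral_maf_range) != 2 ||
      ancestral_maf_range[1] > ancestral_maf_range[2] ||
      any(ancestral_maf_range < 0 | ancestral_maf_range > 1))
    stop("`ancestral_maf_range` must be an increasing pair in [0, 1]")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("`missing_rate` must be in [0, 1)")
  if (!is.numeric(seed) || length(seed) != 1 || seed != round(seed) ||
      seed < 0 || seed > 2^31 - 2)
    stop("`seed` must be an integer in [0, 2^31 - 2]")
  if (!is.null(selected)) {
    selected <- as.data.frame(selected, stringsAsFactors = FALSE)
    if (!all(c("population", "n_loci", "mode", "value") %in% names(selected)))
      stop("`selected` needs columns population, n_loci, mode, value; ",
           "use selection_spec()")
    unknown <- setdiff(selected$population, populations$label)
    if (length(unknown) > 0)
      stop("selected population(s) not simulated: ",
           paste(unknown, collapse = ", "))
    if (sum(selected$n_loci) > n_snps)
      stop("more selected loci than SNPs")
  }
  structure(list(n_snps = as.integer(n_snps), populations = populations,
                 selected = selected,
                 ancestral_maf_range = ancestral_maf_range,
                 missing_rate = missing_rate, seed = as.integer(seed),
                 n_chrom = as.integer(n_chrom),
                 spacing_bp = as.integer(spacing_bp)),
            class = "sim_config")
}

#' Describe planted selected loci
#'
#' @param population label of the population carrying the selected alleles
#' @param n_loci number of selected loci
#' @param mode `"shift"` (add `value` to the drifted frequency, clamped to
#'   `[0, 1]`), `"target"` (set the frequency to `value`), or `"fix_minor"`
#'   (sweep the drifted minor allele to fixation)
#' @param value signed shift in `[-1, 1]` or target frequency in `[0, 1]`;
#'   ignored for `"fix_minor"`
#' @return data.frame usable as the `selected` argument of [sim_config()]
#' @export
selection_spec <- function(population, n_loci,
                           mode = c("fix_minor", "shift", "target"),
                           value = NA_real_) {
  mode <- match.arg(mode)
  if (mode == "shift" &&
      (!is.numeric(value) || is.na(value) || value < -1 || value > 1))
    stop("`value` must be a signed shift in [-1, 1] for mode shift")
  if (mode == "target" &&
      (!is.numeric(value) || is.na(value) || value < 0 || value > 1))
    stop("`value` must be a frequency in [0, 1] for mode target")
  data.frame(population = population, n_loci = as.integer(n_loci),
             mode = mode, value = value, stringsAsFactors = FALSE)
}

snp_map_for <- function(cfg) {
  i <- seq_len(cfg$n_snps)
  per_chrom <- ceiling(cfg$n_snps / cfg$n_chrom)
  chrom <- as.character((i - 1) %/% per_chrom + 1)
  within <- (i - 1) %% per_chrom + 1
  data.frame(snp_id = sprintf(paste0("snp%0", nchar(cfg$n_snps), "d"), i),
             chrom = chrom,
             pos = within * cfg$spacing_bp,
             stringsAsFactors = FALSE)
}

#' Simulate per-population allele frequencies and the ground truth table
#'
#' Draws ancestral and per-population drifted frequencies under the
#' Balding-Nichols model of [sim_config()] and applies the configured
#' selection to the focal loci. Deterministic given `cfg$seed`.
#'
#' @param cfg a `sim_config`
#' @return a `sim_truth` data.frame: one row per SNP with `snp_id`, `chrom`,
#'   `pos`, `ancestral_p`, `selected_in` (population label or `NA`),
#'   `shift` (realized focal frequency change, `NA` for neutral loci) and
#'   one `freq_<label>` column per population
#' @export
simulate_frequencies <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config")
  set.seed(cfg$seed)
  m <- cfg$n_snps
  p <- stats::runif(m, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
  truth <- snp_map_for(cfg)
  truth$ancestral_p <- p
  truth$selected_in <- NA_character_
  truth$shift <- NA_real_
  for (k in seq_len(nrow(cfg$populations))) {
    Fd <- cfg$populations$drift[k]
    pk <- if (Fd == 0) p else
      stats::rbeta(m, p * (1 - Fd) / Fd, (1 - p) * (1 - Fd) / Fd)
    truth[[paste0("freq_", cfg$populations$label[k])]] <- pk
  }
  if (!is.null(cfg$selected)) {
    pool <- sample(m, sum(cfg$selected$n_loci))
    offset <- 0
    for (k in seq_len(nrow(cfg$selected))) {
      row <- cfg$selected[k, ]
      loci <- pool[offset + seq_len(row$n_loci)]
      offset <- offset + row$n_loci
      col <- paste0("freq_", row$population)
      p_old <- truth[[col]][loci]
      p_new <- switch(row$mode,
        shift = pmin(pmax(p_old + row$value, 0), 1),
        target = rep(row$value, length(loci)),
        fix_minor = ifelse(p_old < 0.5, 1, 0))
      truth[[col]][loci] <- p_new
      truth$selected_in[loci] <- row$population
      truth$shift[loci] <- p_new - p_old
    }
  }
  class(truth) <- c("sim_truth", "data.frame")
  truth
}

#' Simulate genotypes from a frequency truth table
#'
#' Each individual's dosage at each SNP is `Binomial(2, p_pop)`
#' (Hardy-Weinberg within populations); each call is then independently set
#' missing with probability `missing_rate`. Uses the RNG stream seeded with
#' `cfg$seed + 1`, so frequencies and genotypes are separately reproducible.
#'
#' @param truth a `sim_truth` from [simulate_frequencies()]
#' @param cfg the `sim_config` that produced `truth`
#' @return list with `genotypes` (a `genotype_matrix`; alleles are "A"
#'   = the counted allele and "B") and `assignment` (named character vector,
#'   sample id -> population)
#' @export
simulate_genotypes <- function(truth, cfg) {
  if (!inherits(cfg, "sim_config")) stop("`cfg` must be a sim_config")
  set.seed(cfg$seed + 1)
  m <- cfg$n_snps
  blocks <- list()
  ids <- character(0)
  pops <- character(0)
  for (k in seq_len(nrow(cfg$populations))) {
    lab <- cfg$populations$label[k]
    nk <- cfg$populations$n_individuals[k]
    pk <- truth[[paste0("freq_", lab)]]
    dos <- matrix(stats::rbinom(nk * m, 2, rep(pk, each = nk)), nrow = nk)
    if (cfg$missing_rate > 0) {
      miss <- matrix(stats::runif(nk * m) < cfg$missing_rate, nrow = nk)
      dos[miss] <- NA_real_
    }
    rownames(dos) <- sprintf("%s_%02d", lab, seq_len(nk))
    blocks[[k]] <- dos
    ids <- c(ids, rownames(dos))
    pops <- c(pops, rep(lab, nk))
  }
  dosage <- do.call(rbind, blocks)
  snps <- data.frame(truth[, c("snp_id", "chrom", "pos")],
                     allele_a = "A", allele_b = "B",
                     stringsAsFactors = FALSE)
  list(genotypes = genotype_matrix(dosage, snps),
       assignment = stats::setNames(pops, ids))
}

#' Simulate a complete panel
#'
#' Runs [simulate_frequencies()] then [simulate_genotypes()].
#'
#' @param cfg a `sim_config`
#' @return list with `truth`, `genotypes`, `assignment`
#' @export
simulate_panel <- function(cfg) {
  truth <- simulate_frequencies(cfg)
  geno <- simulate_genotypes(truth, cfg)
  list(truth = truth, genotypes = geno$genotypes,
       assignment = geno$assignment)
}
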