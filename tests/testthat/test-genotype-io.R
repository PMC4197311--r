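test_that("PED/MAP parsing matches hand-transcribed dosages", {
  g <- read_ped_map(extdata("toy.ped"), extdata("toy.map"))
  # rs1: first genotype A/A -> allele_a = A, C seen later; rs2: G first,
  # s2 missing ("0 0"), s3 heterozygous G/T
  expect_equal(sample_ids(g), c("s1", "s2", "s3"))
  expect_equal(g$snps$snp_id, c("rs1", "rs2"))
  expect_equal(g$snps$allele_a, c("A", "G"))
  expect_equal(g$snps$allele_b, c("C", "T"))
  expect_equal(unname(g$dosage[, "rs1"]), c(2, 1, 0))
  expect_equal(unname(g$dosage[, "rs2"]), c(2, NA, 1))
  expect_equal(g$snps$pos, c(100L, 500L))
})

test_that("single-sample homozygote and heterozygote-first tie rule", {
  ped <- withr::local_tempfile(lines = "1 s1 0 0 1 -9 A A")
  map <- withr::local_tempfile(lines = "1 rs1 0 100")
  g <- read_ped_map(ped, map)
  expect_equal(unname(g$dosage[1, 1]), 2)

  # heterozygous first informative genotype: lexicographically smaller
  # allele becomes allele_a even when written second
  ped2 <- withr::local_tempfile(lines = c("1 s1 0 0 1 -9 G A",
                                          "1 s2 0 0 1 -9 G G"))
  g2 <- read_ped_map(ped2, map)
  expect_equal(g2$snps$allele_a, "A")
  expect_equal(unname(g2$dosage[, 1]), c(1, 0))
})

test_that("malformed PED/MAP input is rejected with a useful message", {
  map <- withr::local_tempfile(lines = "1 rs1 0 100")
  short <- withr::local_tempfile(lines = c("1 s1 0 0 1 -9 A A",
                                           "1 s2 0 0 1 -9 A"))
  expect_error(read_ped_map(short, map), "line 2")
  tri <- withr::local_tempfile(lines = c("1 s1 0 0 1 -9 A C",
                                         "1 s2 0 0 1 -9 T T"))
  expect_error(read_ped_map(tri, map), "non-biallelic.*rs1")
})

test_that("call-rate/MAF filter matches an independent per-SNP recount", {
  set.seed(42)
  n_samp <- 40
  n_snp <- 1000
  dos <- matrix(rbinom(n_samp * n_snp, 2, 0.3), n_samp, n_snp)
  dos[matrix(runif(n_samp * n_snp) < 0.06, n_samp, n_snp)] <- NA
  g <- make_gm(dos)
  gf <- filter_snps(g, 0.95, 0.05)

  keep <- logical(n_snp)
  for (j in seq_len(n_snp)) {           # naive recount, one SNP at a time
    d <- dos[, j]
    cr <- sum(!is.na(d)) / n_samp
    nn <- 2 * sum(!is.na(d))
    p <- sum(d, na.rm = TRUE) / nn
    keep[j] <- cr > 0.95 && min(p, 1 - p) > 0.05
  }
  expect_equal(gf$snps$snp_id, g$snps$snp_id[keep])
  # idempotence
  expect_identical(filter_snps(gf, 0.95, 0.05)$dosage, gf$dosage)
})

test_that("filter thresholds are strict; MAF subsetting honors inclusivity", {
  # 100 samples: call rate exactly 0.95 and MAF exactly 0.05 / 0.2
  dos <- cbind(c(rep(NA, 5), rep(0, 95)),              # call rate = 0.95
               c(rep(1, 10), rep(0, 90)),              # MAF = 0.05
               c(rep(2, 20), rep(0, 80)),              # MAF = 0.2
               rep(1, 100))                            # MAF = 0.5
  g <- make_gm(dos)
  gf <- filter_snps(g, 0.95, 0.05)
  expect_equal(gf$snps$snp_id, c("rs003", "rs004"))
  expect_equal(n_snps(subset_by_maf(g, 0.2, inclusive = TRUE)), 2)
  expect_equal(n_snps(subset_by_maf(g, 0.2, inclusive = FALSE)), 1)
  expect_error(filter_snps(g, 1.5, 0.05), "min_call_rate")
  # monomorphic SNP removed at any positive MAF floor
  g0 <- make_gm(cbind(rep(2, 100)))
  expect_equal(n_snps(filter_snps(g0, 0, 0.05)), 0)
})

test_that("panel merging is additive, cell-faithful and symmetric in SNPs", {
  set.seed(7)
  d1 <- matrix(rbinom(5 * 8, 2, 0.4), 5, 8,
               dimnames = list(paste0("s", 1:5), NULL))
  d2 <- matrix(rbinom(4 * 3, 2, 0.4), 4, 3,
               dimnames = list(paste0("s", c(2, 3, 5, 9)), NULL))
  g1 <- make_gm(d1)
  g2 <- genotype_matrix(d2, data.frame(
    snp_id = paste0("x", 1:3), chrom = "2", pos = 1:3 * 100,
    allele_a = "A", allele_b = "C"))
  gm <- merge_panels(g1, g2)
  expect_equal(n_snps(gm), 11)
  expect_equal(sample_ids(gm), c("s2", "s3", "s5"))
  for (s in sample_ids(gm)) {           # every cell equals its source panel
    expect_equal(gm$dosage[s, 1:8], g1$dosage[s, ])
    expect_equal(unname(gm$dosage[s, 9:11]), unname(g2$dosage[s, ]))
  }
  expect_setequal(merge_panels(g2, g1)$snps$snp_id, gm$snps$snp_id)
  expect_error(merge_panels(g1, g1), "merge conflict")
  g3 <- genotype_matrix(
    matrix(0, 2, 1, dimnames = list(c("t1", "t2"), NULL)),
    data.frame(snp_id = "y1", chrom = "1", pos = 5,
               allele_a = "A", allele_b = "C"))
  expect_error(merge_panels(g1, g3), "no samples")
  # merging an empty panel restricts g1 to the shared samples
  g_empty <- genotype_matrix(
    matrix(numeric(0), 3, 0, dimnames = list(paste0("s", 2:4), NULL)),
    data.frame(snp_id = character(0), chrom = character(0),
               pos = integer(0), allele_a = character(0),
               allele_b = character(0)))
  gme <- merge_panels(g1, g_empty)
  expect_equal(sample_ids(gme), c("s2", "s3", "s4"))
  expect_equal(n_snps(gme), 8)
})

test_that("write_ped_map round-trips dosage, ids and metadata", {
  g <- read_ped_map(extdata("toy.ped"), extdata("toy.map"))
  prefix <- tempfile()
  write_ped_map(g, prefix)
  g2 <- read_ped_map(paste0(prefix, ".ped"), paste0(prefix, ".map"))
  expect_identical(g2$dosage, g$dosage)
  expect_identical(g2$snps, g$snps)

  # larger simulated panel with missingness
  panel <- simulate_panel(sim_config(
    n_snps = 500,
    populations = data.frame(label = "P", n_individuals = 100, drift = 0.1),
    missing_rate = 0.05, seed = 11))
  prefix2 <- tempfile()
  write_ped_map(panel$genotypes, prefix2)
  g3 <- read_ped_map(paste0(prefix2, ".ped"), paste0(prefix2, ".map"))
  expect_identical(is.na(g3$dosage), is.na(panel$genotypes$dosage))
  # orientation is data-driven: a SNP observed monomorphic for the
  # lexicographically larger allele necessarily reads back complemented
  # (PED does not record which allele was counted); all others are
  # reproduced exactly
  same <- g3$snps$allele_a == panel$genotypes$snps$allele_a
  expect_identical(g3$dosage[, same], panel$genotypes$dosage[, same])
  if (any(!same)) {
    expect_true(all(g3$dosage[, !same] ==
                      2 - panel$genotypes$dosage[, !same], na.rm = TRUE))
    flipped <- panel$genotypes$dosage[, !same, drop = FALSE]
    expect_true(all(flipped == 0 | is.na(flipped)))
  }
})
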