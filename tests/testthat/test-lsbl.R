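three_pop_panel <- function(seed = 1, n_snps = 400, drift = c(0.1, 0.1, 0.1),
                            n_ind = c(12, 12, 12), selected = NULL,
                            missing_rate = 0.02) {
  simulate_panel(sim_config(
    n_snps = n_snps,
    populations = data.frame(label = c("A", "B", "C"),
                             n_individuals = n_ind, drift = drift),
    selected = selected, missing_rate = missing_rate, seed = seed))
}

spec_from <- function(assignment, focal, c1, c2) {
  group_spec(names(assignment)[assignment == focal],
             names(assignment)[assignment == c1],
             names(assignment)[assignment == c2],
             labels = c(focal, c1, c2))
}

test_that("group specs demand disjoint non-empty sample sets", {
  expect_error(group_spec(c("a", "b"), c("b"), c("c")), "disjoint")
  expect_error(group_spec(character(0), "b", "c"), "at least one")
  s <- group_spec("a", "b", c("c", "d"))
  expect_s3_class(s, "group_spec")
})

test_that("shared and population-specific spec builders resolve labels", {
  assign <- setNames(rep(c("T1", "T2", "L1", "L2", "L3"), each = 2),
                     paste0("s", 1:10))
  s <- build_shared_spec(assign, c("T1", "T2"), "L1", c("L2", "L3"))
  expect_setequal(s$focal, paste0("s", 1:4))
  expect_setequal(s$contrast1, paste0("s", 5:6))
  expect_setequal(s$contrast2, paste0("s", 7:10))
  expect_error(build_shared_spec(assign, "T1", "T1", "L1"), "reused")
  expect_error(build_shared_spec(assign, "Nope", "L1", "L2"), "Nope")

  sp <- build_specific_spec(assign, "T1", "T2", c("L1", "L2", "L3"))
  expect_equal(sp$labels[1], "T1")
  expect_setequal(sp$contrast1, paste0("s", 3:4))
  expect_error(build_specific_spec(assign, "T1", character(0), "L1"),
               "three groups")
})

test_that("three-group F_ST matches independently computed pairs", {
  # focal fixed for A, both contrasts fixed for the other allele
  dos <- rbind(f1 = 2, f2 = 2, c1 = 0, c2 = 0, d1 = 0, d2 = 0)
  g <- make_gm(dos)
  spec <- group_spec(c("f1", "f2"), c("c1", "c2"), c("d1", "d2"))
  tg <- three_group_fst(g, spec)
  expect_equal(unlist(tg[1, c("d_f1", "d_f2", "d_12")]),
               c(d_f1 = 1, d_f2 = 1, d_12 = 0))
  expect_equal(lsbl(tg$d_f1, tg$d_f2, tg$d_12), 1)

  panel <- three_pop_panel(seed = 9, n_snps = 150)
  spec2 <- spec_from(panel$assignment, "A", "B", "C")
  tg2 <- three_group_fst(panel$genotypes, spec2)
  ca <- allele_counts(panel$genotypes, spec2$focal)
  cb <- allele_counts(panel$genotypes, spec2$contrast1)
  cc <- allele_counts(panel$genotypes, spec2$contrast2)
  expect_equal(tg2$d_f1, reich_fst(ca$a, ca$n, cb$a, cb$n)$clipped)
  expect_equal(tg2$d_f2, reich_fst(ca$a, ca$n, cc$a, cc$n)$clipped)
  expect_equal(tg2$d_12, reich_fst(cb$a, cb$n, cc$a, cc$n)$clipped)
})

test_that("identical groups give an all-zero branch triple", {
  dos <- rbind(a1 = c(2, 1), a2 = c(0, 1),
               b1 = c(2, 1), b2 = c(0, 1),
               c1 = c(2, 1), c2 = c(0, 1))
  g <- make_gm(dos)
  tg <- three_group_fst(g, group_spec(c("a1", "a2"), c("b1", "b2"),
                                      c("c1", "c2")))
  expect_true(all(tg$d_f1 == 0 & tg$d_f2 == 0 & tg$d_12 == 0))
})

test_that("LSBL is the three-branch decomposition and validates inputs", {
  expect_equal(lsbl(0.3, 0.2, 0.1), 0.2)
  expect_equal(lsbl(0.4, 0.4, 0.4), 0.2)  # symmetric star: d/2
  expect_equal(lsbl(1, 1, 0), 1)
  expect_error(lsbl(1.2, 0.5, 0.1), "\\[0, 1\\]")
  expect_error(lsbl(0.5, NA, 0.1), "\\[0, 1\\]")
})

test_that("LSBL additivity and contrast symmetry hold per SNP", {
  panel <- three_pop_panel(seed = 33, n_snps = 300)
  g <- panel$genotypes
  tg_a <- three_group_fst(g, spec_from(panel$assignment, "A", "B", "C"))
  tg_b <- three_group_fst(g, spec_from(panel$assignment, "B", "A", "C"))
  v <- tg_a$valid & tg_b$valid
  lsbl_a <- lsbl(tg_a$d_f1[v], tg_a$d_f2[v], tg_a$d_12[v])
  lsbl_b <- lsbl(tg_b$d_f1[v], tg_b$d_f2[v], tg_b$d_12[v])
  # the two focal branches on either side of the A-B edge sum to d_AB
  expect_equal(lsbl_a + lsbl_b, tg_a$d_f1[v], tolerance = 1e-12)
  # swapping the contrast groups leaves the focal branch unchanged
  tg_sw <- three_group_fst(g, spec_from(panel$assignment, "A", "C", "B"))
  expect_equal(lsbl(tg_sw$d_f1[v], tg_sw$d_f2[v], tg_sw$d_12[v]),
               lsbl_a, tolerance = 1e-12)
})

test_that("empirical outlier calling is floor-counted sort-and-slice", {
  recs <- data.frame(snp_id = paste0("r", 1:100), chrom = "1",
                     pos = 1:100, lsbl = runif(100))
  expect_equal(nrow(empirical_outliers(recs, 0.005)$outliers), 0)

  set.seed(50)
  recs <- data.frame(snp_id = paste0("r", 1:1000), chrom = "1",
                     pos = 1:1000, lsbl = round(runif(1000), 2))
  out <- empirical_outliers(recs, 0.01)
  expect_equal(nrow(out$outliers), 10)
  # sort-and-slice oracle with the same tie rule
  oracle <- recs[order(-recs$lsbl, recs$chrom, recs$pos), ][1:10, ]
  expect_equal(out$outliers$snp_id, oracle$snp_id)
  expect_equal(out$cutoff, oracle$lsbl[10])
  expect_true(all(out$outliers$lsbl >= out$cutoff))
  non <- setdiff(recs$snp_id, out$outliers$snp_id)
  expect_true(all(recs$lsbl[recs$snp_id %in% non] <= out$cutoff))
  # ties at the cutoff resolve by ascending genomic position
  tied <- data.frame(snp_id = c("a", "b", "c", "d"), chrom = "1",
                     pos = c(40, 20, 10, 30), lsbl = c(0.9, 0.5, 0.5, 0.1))
  expect_equal(empirical_outliers(tied, 0.5)$outliers$snp_id, c("a", "c"))
  expect_error(empirical_outliers(tied, 1.2), "top_fraction")
})

test_that("lsbl_scan flags outliers consistently with its records", {
  panel <- three_pop_panel(seed = 4, n_snps = 600)
  scan <- lsbl_scan(panel$genotypes,
                    spec_from(panel$assignment, "A", "B", "C"),
                    top_fraction = 0.01)
  expect_equal(sum(scan$records$is_outlier),
               floor(0.01 * scan$n_valid))
  flagged <- scan$records[scan$records$is_outlier, ]
  expect_true(all(flagged$lsbl >= scan$cutoff))
  expect_equal(sort(flagged$rank), seq_len(nrow(flagged)))
})

test_that("frequency tables match allele-count recomputation", {
  dos <- rbind(a1 = c(2, 1), a2 = c(2, NA), b1 = c(2, 0), b2 = c(2, NA))
  g <- make_gm(dos)
  assign <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  ft <- frequency_table(g, assign, c("rs001", "rs002"))
  expect_equal(ft["A", ], c(rs001 = 1, rs002 = 0.5))
  expect_equal(ft["B", ], c(rs001 = 1, rs002 = 0))
  expect_error(frequency_table(g, assign, "nope"), "unknown snp_id")

  panel <- three_pop_panel(seed = 2, n_snps = 40)
  ids <- panel$truth$snp_id[1:5]
  ft2 <- frequency_table(panel$genotypes, panel$assignment, ids)
  for (p in c("A", "B", "C")) {
    ac <- allele_counts(panel$genotypes,
                        names(panel$assignment)[panel$assignment == p])
    idx <- match(ids, ac$snp_id)
    expect_equal(unname(ft2[p, ]), (ac$a / ac$n)[idx])
  }
})
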