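test_that("per-SNP F_ST matches hand values and the brute-force oracle", {
  expect_equal(snp_fst(1, 0), 1)
  expect_equal(snp_fst(0.3, 0.3), 0)
  expect_equal(snp_fst(0.9, 0.1), (0.5 - 0.18) / 0.5)
  expect_true(is.na(snp_fst(0, 0)))  # H_T = 0: undefined
  expect_true(is.na(snp_fst(1, 1)))
  expect_error(snp_fst(1.2, 0.5), "\\[0, 1\\]")

  set.seed(101)
  p1 <- runif(1000); p2 <- runif(1000)
  expect_equal(snp_fst(p1, p2),
               mapply(oracle_fst, p1, p2), tolerance = 1e-12)

  # Hudson estimator: agrees at the extremes, population form checks out
  expect_equal(snp_fst_hudson(1, 0), 1)
  expect_equal(snp_fst_hudson(0.3, 0.3), 0)
  expect_equal(snp_fst_hudson(0.9, 0.1), 0.64 / 0.82)
  # both estimators rank random pairs almost identically
  expect_gt(cor(snp_fst(p1, p2), snp_fst_hudson(p1, p2),
                method = "spearman"), 0.99)
})

test_that("coverage filter keeps loci covered in both groups", {
  pc <- pool_counts(c("1", "1", "1"), c(10L, 20L, 30L), rep("A", 3),
                    rep("T", 3),
                    wbl_a = c(5, 5, 5), wbl_b = c(5, 5, 5),
                    wbl_n = c(6, 6, 0),
                    wrl_a = c(5, 5, 5), wrl_b = c(5, 5, 5),
                    wrl_n = c(5, 3, 0))
  expect_equal(coverage_filter(pc, 4)$position, 10L)
  expect_equal(nrow(coverage_filter(pc, 0)), 3L)
})

test_that("sliding windows anchor at 1 and average member SNPs", {
  snp <- data.frame(chromosome = c("1", "1"), position = c(1000L, 6000L),
                    fst = c(0.2, 0.4))
  w <- sliding_windows(snp, window = 10000, step = 5000)
  expect_equal(nrow(w), 2L)
  expect_equal(w$start, c(1L, 5001L))
  expect_equal(w$end - w$start, c(10000L, 10000L))
  expect_equal(w$n_snps, c(2L, 1L))
  expect_equal(w$mean_fst, c(0.3, 0.4))

  # single SNP: all its windows carry its F_ST
  one <- data.frame(chromosome = "7", position = 12345L, fst = 0.33)
  w1 <- sliding_windows(one, 10000, 5000)
  expect_true(all(w1$mean_fst == 0.33))
  expect_true(all(w1$n_snps == 1L))

  # a chromosome with only undefined SNPs emits no windows
  na_snp <- data.frame(chromosome = c("1", "2"), position = c(100L, 100L),
                       fst = c(0.5, NA))
  expect_false("2" %in% sliding_windows(na_snp, 10000, 5000)$chromosome)

  unsorted <- data.frame(chromosome = c("1", "1"), position = c(500L, 100L),
                         fst = c(0.1, 0.2))
  expect_error(sliding_windows(unsorted, 10000, 5000), "sorted")
})

test_that("window membership is conserved against brute-force enumeration", {
  set.seed(77)
  snp <- data.frame(chromosome = rep(c("1", "2"), each = 40),
                    position = c(sort(sample.int(60000, 40)),
                                 sort(sample.int(60000, 40))),
                    fst = runif(80))
  for (ws in list(c(10000, 5000), c(9000, 3000), c(5000, 5000))) {
    w <- sliding_windows(snp, ws[1], ws[2])
    expected <- sum(vapply(snp$position, oracle_n_windows, 0L,
                           window = ws[1], step = ws[2]))
    expect_equal(sum(w$n_snps), expected)
  }
})

test_that("high-F_ST selection reports the realized quantile", {
  snp <- data.frame(locus_id = sprintf("L%d", 1:1000),
                    chromosome = "1", position = 1:1000,
                    fst = c(rep(0.1, 999), 0.9))
  hi <- high_fst_snps(snp, 0.5)
  expect_equal(hi$n_high, 1L)
  expect_equal(hi$realized_quantile, 0.999)
  expect_equal(high_fst_snps(snp, 0)$n_high, 1000L)
  low <- data.frame(locus_id = "a", chromosome = "1", position = 1, fst = 0.1)
  expect_equal(high_fst_snps(low, 0.5)$n_high, 0L)
  empty <- high_fst_snps(snp[0, ], 0.5)
  expect_true(is.na(empty$realized_quantile))
})

test_that("chromosome enrichment uses a strict share threshold", {
  high <- data.frame(chromosome = rep(c("chr1", "chr2", "chr3", paste0("c", 4:8)),
                                      c(60, 30, 5, rep(1, 5))))
  enr <- chromosome_enrichment(high, 0.01)
  expect_setequal(enr$enriched, c("chr1", "chr2", "chr3"))
  expect_equal(enr$coverage, 0.95)

  one <- data.frame(chromosome = rep("chrX", 7))
  enr1 <- chromosome_enrichment(one, 0.01)
  expect_equal(enr1$enriched, "chrX")
  expect_equal(enr1$coverage, 1.0)

  unif <- data.frame(chromosome = as.character(1:100))
  expect_length(chromosome_enrichment(unif, 0.01)$enriched, 0L)
})

test_that("candidate allocation is proportional with a floor of two", {
  high <- data.frame(chromosome = rep(c("A", "B"), c(30, 10)),
                     position = c(1:30 * 100L, 1:10 * 100L),
                     fst = c(runif(30, 0.5, 0.9), runif(10, 0.5, 0.9)),
                     locus_id = sprintf("L%d", 1:40))
  sel <- select_candidates(high, c("A", "B"), 4)
  expect_equal(sort(unname(sel$allocation)), c(2L, 2L))
  expect_equal(nrow(sel$candidates), 4L)

  # one enriched chromosome takes everything
  selA <- select_candidates(high, "A", 5)
  expect_true(all(selA$candidates$chromosome == "A"))

  # equal F_ST: positional tie-break keeps the smallest positions
  tied <- data.frame(chromosome = "A", position = c(500L, 100L, 300L, 900L),
                     fst = rep(0.7, 4), locus_id = sprintf("T%d", 1:4))
  selT <- select_candidates(tied, "A", 2)
  expect_setequal(selT$candidates$position, c(100L, 300L))

  expect_warning(select_candidates(tied, "A", 10), "returning all")
})

test_that("genotype refit reproduces hand-computed F_ST", {
  loci <- locus_table("L1", "2", 100L, "A", "T")
  m <- matrix(c("AA", "AT", "TT", "TT"), ncol = 1,
              dimnames = list(c("r1", "r2", "w1", "w2"), "L1"))
  gt <- genotype_table(m, loci, c("r1", "r2", "w1", "w2"))
  ref <- refit_fst_from_genotypes(gt, c("WRL", "WRL", "WBL", "WBL"))
  # p_A: WRL 0.75 vs WBL 0 -> (0.46875 - 0.1875)/0.46875 = 0.6
  expect_equal(ref$fst, 0.6)

  m2 <- matrix(c("AA", "TT", "AA", "TT"), ncol = 1,
               dimnames = list(c("r1", "r2", "w1", "w2"), "L1"))
  gt2 <- genotype_table(m2, loci, c("r1", "r2", "w1", "w2"))
  expect_equal(refit_fst_from_genotypes(gt2, c("WRL", "WRL", "WBL", "WBL"))$fst, 0)

  m3 <- matrix(c("AA", "AA", "TT", "TT"), ncol = 1,
               dimnames = list(c("r1", "r2", "w1", "w2"), "L1"))
  gt3 <- genotype_table(m3, loci, c("r1", "r2", "w1", "w2"))
  expect_equal(refit_fst_from_genotypes(gt3, c("WRL", "WRL", "WBL", "WBL"))$fst, 1)

  # a group with no typed individuals is undefined
  m4 <- matrix(c("AA", "AA", NA, NA), ncol = 1,
               dimnames = list(c("r1", "r2", "w1", "w2"), "L1"))
  gt4 <- genotype_table(m4, loci, c("r1", "r2", "w1", "w2"))
  expect_true(is.na(refit_fst_from_genotypes(gt4, c("WRL", "WRL", "WBL", "WBL"))$fst))
})

test_that("allele designation follows voucher frequencies and flags ties", {
  loci <- locus_table(c("L1", "L2"), c("2", "5"), c(100L, 200L),
                      c("A", "A"), c("T", "T"))
  m <- matrix(c("TT", "TT", "AT", "AA",   # L1: allele T freq WRL 1 vs WBL 0.25
                "AT", "TA", "AT", "TA"),  # L2: both groups 0.5 - tie
              ncol = 2, dimnames = list(c("r1", "r2", "w1", "w2"), c("L1", "L2")))
  gt <- genotype_table(m, loci, c("r1", "r2", "w1", "w2"))
  des <- designate_alleles(gt, c("WRL", "WRL", "WBL", "WBL"))
  expect_equal(des$wrl_allele[1], "T")
  expect_equal(des$wbl_allele[1], "A")
  expect_false(des$diagnostic[2])
  expect_true(is.na(des$wrl_allele[2]))

  m5 <- m; m5[c("r1", "r2"), "L1"] <- NA
  gt5 <- genotype_table(m5, loci, c("r1", "r2", "w1", "w2"))
  expect_error(designate_alleles(gt5, c("WRL", "WRL", "WBL", "WBL")), "L1")
})

test_that("designations recover simulation ground truth at delta = 0.8", {
  isl <- data.frame(chromosome = "1", start_bp = 1, end_bp = 1e6, delta = 0.8)
  cfg <- sim_config(n_chromosomes = 1, loci_per_chromosome = 5,
                    chromosome_length_bp = 1e6, background_fst = 0.01,
                    islands = isl, seed = 31)
  fr <- simulate_allele_frequencies(cfg)
  sim <- simulate_individuals(fr, 50, 50, seed = 32)
  des <- designate_alleles(sim$genotypes, sim$labels)
  truth_wrl <- ifelse(fr$p_wrl > fr$p_wbl, fr$loci$allele_b, fr$loci$allele_a)
  expect_equal(des$wrl_allele, truth_wrl)
})

test_that("panel selection takes the top refit F_ST with positional ties", {
  refit <- data.frame(locus_id = sprintf("L%d", 1:7), chromosome = "2",
                      position = c(700L, 100L, 300L, 200L, 500L, 600L, 400L),
                      fst = c(0.58, 0.51, 0.48, 0.46, 0.45, 0.30, 0.45))
  sel <- select_panel(refit, 5)
  expect_equal(sel$fst, c(0.58, 0.51, 0.48, 0.46, 0.45))
  # tie at 0.45 resolved toward the smaller position (400 < 500)
  expect_equal(sel$position[5], 400L)
  expect_warning(sel_all <- select_panel(refit, 10), "returning all")
  expect_equal(nrow(sel_all), 7L)
})

test_that("expected pooled F_ST increases with the island differential", {
  loci <- locus_table("L1", "1", 100L, "A", "T")
  deltas <- c(0.2, 0.4, 0.6, 0.8, 1.0)
  mean_fst <- vapply(seq_along(deltas), function(i) {
    d <- deltas[i]
    fr <- list(loci = loci, p_wbl = 0.5 - d / 2, p_wrl = 0.5 + d / 2)
    vals <- vapply(1:50, function(rep) {
      sim <- simulate_individuals(fr, 24, 15, seed = 1000 * i + rep)
      pc <- simulate_pool_counts(sim, mean_depth = 3, seed = 2000 * i + rep)
      pool_allele_freqs(pc)$fst
    }, 0)
    mean(vals, na.rm = TRUE)
  }, 0)
  expect_true(all(diff(mean_fst) > -0.02))
  expect_gt(mean_fst[5], mean_fst[1])
})

test_that("the assembled scan object ties the stages together", {
  isl <- data.frame(chromosome = "2", start_bp = 4e5, end_bp = 5e5, delta = 0.95)
  cfg <- sim_config(n_chromosomes = 3, loci_per_chromosome = 200,
                    chromosome_length_bp = 1e6, background_fst = 0.01,
                    islands = isl, seed = 41)
  fr <- simulate_allele_frequencies(cfg)
  sim <- simulate_individuals(fr, 24, 15, seed = 42)
  pc <- simulate_pool_counts(sim, mean_depth = 3, seed = 43)
  scan <- ecotype_scan(pc, scan_config(n_candidates = 6))
  expect_s3_class(scan, "ecotype_scan")
  expect_lte(scan$n_retained, scan$n_input)
  expect_true(all(scan$candidates$candidates$fst > 0.5))
  expect_true("2" %in% scan$enrichment$enriched)
  expect_output(print(scan), "high-F_ST")
})
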