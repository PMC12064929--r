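# call-record data.frame from category counts
records_from_counts <- function(e, unk, wbl, int, wrl) {
  genus <- c(rep("Entosphenus", e), rep("Lampetra", unk + wbl + int + wrl))
  eco <- c(rep("Unknown", e + unk), rep("WBL", wbl), rep("Intermediate", int),
           rep("WRL", wrl))
  data.frame(genus = genus, ecotype = eco, stringsAsFactors = FALSE)
}

test_that("composition point estimates match published collection rows", {
  # 86 Entosphenus; Lampetra: 10 unknown + 79 WBL + 11 Int + 67 WRL
  rc <- records_from_counts(86, 10, 79, 11, 67)
  gen <- composition(rc, "genus")
  expect_equal(gen$proportions[["Lampetra"]], 167 / 253)
  expect_equal(percent(gen$proportions[["Lampetra"]]), 66.0)
  eco <- composition(rc, "ecotype")
  expect_equal(eco$n, 157L)
  expect_equal(eco$proportions[["WRL"]], 67 / 157)
  expect_equal(percent(eco$proportions[["WRL"]]), 42.7)

  # single-category collection
  one <- composition(records_from_counts(0, 0, 12, 0, 0), "ecotype")
  expect_equal(one$proportions[["WBL"]], 1)

  # (45 WBL, 4 Int, 1 WRL) -> WBL 90.0%
  mix <- composition(records_from_counts(0, 0, 45, 4, 1), "ecotype")
  expect_equal(percent(mix$proportions[["WBL"]]), 90.0)

  # zero denominator -> undefined proportions
  none <- composition(records_from_counts(5, 0, 0, 0, 0), "ecotype")
  expect_true(all(is.na(none$proportions)))
})

test_that("every printed collection percentage is reproduced from its counts", {
  tab <- read_example("survey_collection_counts.tsv")
  printed_E <- c(0.0, 34.0, 43.4, 9.1, 92.6, 57.9, 70.5, 46.8, 34.6, 38.5,
                 41.7, 15.3, 66.7, 22.7, 76.5, 43.6, 100.0, 95.4, 89.7, 60.0,
                 57.1, 5.9, 0.0, 4.0)
  printed_WBL <- c(0.0, 50.3, 33.9, 100.0, 94.1, 100.0, 100.0, 100.0, 100.0,
                   100.0, 96.4, 100.0, 100.0, 90.0, 100.0, 98.2, NA, 83.3,
                   100.0, 100.0, 100.0, 100.0, 100.0, 100.0)
  printed_WRL <- c(100.0, 42.7, 57.1, 0.0, 5.9, 0.0, 0.0, 0.0, 0.0, 0.0, 0.0,
                   0.0, 0.0, 2.0, 0.0, 0.0, NA, 16.7, 0.0, 0.0, 0.0, 0.0,
                   0.0, 0.0)
  for (i in seq_len(nrow(tab))) {
    rc <- records_from_counts(tab$n_entosphenus[i], tab$n_lampetra_unknown[i],
                              tab$n_wbl[i], tab$n_intermediate[i], tab$n_wrl[i])
    gen <- composition(rc, "genus")
    expect_equal(percent(gen$proportions[["Entosphenus"]]), printed_E[i],
                 info = paste("collection", tab$collection[i]))
    eco <- composition(rc, "ecotype")
    if (is.na(printed_WBL[i])) {
      expect_true(all(is.na(eco$proportions)))
    } else {
      expect_equal(percent(eco$proportions[["WBL"]]), printed_WBL[i],
                   info = paste("collection", tab$collection[i]))
      expect_equal(percent(eco$proportions[["WRL"]]), printed_WRL[i],
                   info = paste("collection", tab$collection[i]))
    }
  }
})

test_that("cross-collection averages are unweighted means over defined collections", {
  tab <- read_example("survey_collection_counts.tsv")
  trib <- tab[tab$collection != 1, ]  # exclude the ocean positive control
  comps_g <- lapply(seq_len(nrow(trib)), function(i)
    composition(records_from_counts(trib$n_entosphenus[i],
                                    trib$n_lampetra_unknown[i], trib$n_wbl[i],
                                    trib$n_intermediate[i], trib$n_wrl[i]),
                "genus"))
  avg_g <- average_composition(comps_g)
  expect_equal(avg_g$n_collections[1], 23L)
  expect_equal(percent(avg_g$mean[avg_g$category == "Entosphenus"]), 48.1)
  expect_equal(avg_g$min[avg_g$category == "Entosphenus"], 0)
  expect_equal(avg_g$max[avg_g$category == "Entosphenus"], 1)

  comps_e <- lapply(seq_len(nrow(trib)), function(i)
    composition(records_from_counts(trib$n_entosphenus[i],
                                    trib$n_lampetra_unknown[i], trib$n_wbl[i],
                                    trib$n_intermediate[i], trib$n_wrl[i]),
                "ecotype"))
  avg_e <- average_composition(comps_e)
  expect_equal(avg_e$n_collections[1], 22L)  # one all-Entosphenus collection drops
  expect_equal(percent(avg_e$mean[avg_e$category == "WBL"]), 93.0)

  same <- list(composition(records_from_counts(0, 0, 3, 0, 1), "ecotype"),
               composition(records_from_counts(0, 0, 6, 0, 2), "ecotype"))
  avg_s <- average_composition(same)
  expect_equal(avg_s$mean[avg_s$category == "WBL"], 0.75)
  expect_equal(avg_s$min, avg_s$max)
})

test_that("bootstrap CI covers degenerate and exhaustively enumerable cases", {
  est1 <- bootstrap_ci(c(WBL = 20L), n_boot = 500, seed = 1)
  expect_equal(unname(est1$ci[, "WBL"]), c(1, 1))

  # n = 2, one individual per category: resample distribution is known
  # exactly (pA in {0, .5, 1} with weights 1/4, 1/2, 1/4); at the 99% level
  # both percentile endpoints hit the extremes
  est2 <- bootstrap_ci(c(A = 1L, B = 1L), n_boot = 10000, seed = 2)
  expect_equal(unname(est2$ci["lower", "A"]), 0)
  expect_equal(unname(est2$ci["upper", "A"]), 1)
  # frequencies of the three resample outcomes match the exact weights
  set.seed(2); reps <- stats::rmultinom(10000, 2, c(0.5, 0.5))[1, ] / 2
  expect_lt(abs(mean(reps == 0.5) - 0.5), 0.02)

  expect_error(bootstrap_ci(c(A = 1), n_boot = 0), "n_boot")
  expect_error(bootstrap_ci(c(A = 0)), ">= 1")
})

test_that("bootstrap CI coverage matches the exactly enumerated coverage", {
  # with two categories the percentile interval's coverage can be computed
  # exactly: sum over k of P(k) * [Q_k(0.005) <= p <= Q_k(0.995)] with
  # Q_k the binomial quantile of the resample distribution
  n <- 50; p <- 0.9
  exact <- sum(vapply(0:n, function(k) {
    lo <- qbinom(0.005, n, k / n) / n
    hi <- qbinom(0.995, n, k / n) / n
    if (lo <= p && p <= hi) dbinom(k, n, p) else 0
  }, 0))
  set.seed(123)
  ks <- rbinom(1000, n, p)
  covered <- vapply(seq_along(ks), function(i) {
    est <- bootstrap_ci(c(X = ks[i], Y = n - ks[i]), n_boot = 2000,
                        seed = i)
    est$ci["lower", "X"] <= p && p <= est$ci["upper", "X"]
  }, TRUE)
  expect_lt(abs(mean(covered) - exact), 0.015)
})

test_that("bootstrap CI width shrinks with sample size", {
  set.seed(55)
  widths <- vapply(c(25, 50, 100, 400), function(n) {
    mean(vapply(1:100, function(i) {
      k <- rbinom(1, n, 0.5)
      k <- min(max(k, 1), n - 1)
      est <- bootstrap_ci(c(X = k, Y = n - k), n_boot = 1000, seed = i)
      est$ci["upper", "X"] - est$ci["lower", "X"]
    }, 0))
  }, 0)
  expect_true(all(diff(widths) < 0))
})

test_that("stability is non-overlap of the two confidence intervals", {
  mk <- function(lo, hi) {
    est <- bootstrap_ci(c(X = 5, Y = 5), n_boot = 100, seed = 1)
    est$ci["lower", "X"] <- lo; est$ci["upper", "X"] <- hi
    est
  }
  expect_equal(stability_test(mk(0.1, 0.3), mk(0.4, 0.6), "X"), "unstable")
  expect_equal(stability_test(mk(0.1, 0.4), mk(0.4, 0.6), "X"), "stable")
  expect_equal(stability_test(mk(0.2, 0.5), mk(0.2, 0.5), "X"), "stable")
  b <- mk(0.1, 0.2); b$basis <- "genus"
  a <- mk(0.1, 0.2); a$basis <- "ecotype"
  expect_error(stability_test(a, b, "X"), "different bases")
})

test_that("Mantel statistic and p-value behave as a permutation test", {
  set.seed(9)
  x <- runif(5)
  a <- abs(outer(x, x, "-"))
  r <- mantel_test(a, a, n_perm = 99, seed = 1)
  expect_equal(r$r, 1.0)
  expect_equal(r$p, 1 / 100)

  b <- matrix(0, 5, 5)
  expect_error(mantel_test(a, b, n_perm = 9, seed = 1), "constant")
  expect_error(mantel_test(a[1:4, 1:5], a, n_perm = 9), "square")
  asym <- a; asym[1, 2] <- asym[1, 2] + 1
  expect_error(mantel_test(asym, a, n_perm = 9), "symmetric")

  # p agrees with exhaustive enumeration of all 24 permutations at n = 4
  set.seed(10)
  for (k in 1:3) {
    u <- runif(4); v <- runif(4)
    da <- abs(outer(u, u, "-")); db <- abs(outer(v, v, "-"))
    exact <- oracle_mantel_p(da, db)
    mt <- mantel_test(da, db, n_perm = 9999, seed = k)
    expect_lt(abs(mt$p - exact), 0.02)
  }
})

test_that("Mantel statistic and p-value agree with an independent implementation", {
  set.seed(12)
  u <- runif(7); v <- 2 * u + rnorm(7, 0, 0.3)
  da <- abs(outer(u, u, "-")); db <- abs(outer(v, v, "-"))
  mt <- mantel_test(da, db, n_perm = 999, seed = 3)
  vg <- vegan::mantel(stats::as.dist(da), stats::as.dist(db),
                      permutations = 999)
  expect_equal(mt$r, unname(vg$statistic), tolerance = 1e-12)
  expect_lt(abs(mt$p - vg$signif), 0.05)
})

test_that("Mantel p-values are uniform on average under independence", {
  set.seed(11)
  ps <- vapply(1:200, function(i) {
    u <- runif(6); v <- runif(6)
    mantel_test(abs(outer(u, u, "-")), abs(outer(v, v, "-")),
                n_perm = 99, seed = i)$p
  }, 0)
  expect_gt(mean(ps), 0.45)
  expect_lt(mean(ps), 0.55)
})
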