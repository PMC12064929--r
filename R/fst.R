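#' Per-SNP F_ST between two groups
#'
#' Nei-style fixation index with equal group weighting:
#' \deqn{H_S = \frac{2p_1(1-p_1) + 2p_2(1-p_2)}{2}, \quad
#'       \bar p = \frac{p_1+p_2}{2}, \quad H_T = 2\bar p(1-\bar p),}
#' \deqn{F_{ST} = \frac{H_T - H_S}{H_T}.}
#' Undefined (`NA`) when the total heterozygosity \eqn{H_T} is zero (both
#' groups fixed for the same allele); negative raw values are clamped to 0.
#'
#' @param p1,p2 allele frequencies in the two groups, in `[0, 1]` (vectorised).
#' @return numeric vector of F_ST values in `[0, 1]`, `NA` where undefined.
#' @examples
#' snp_fst(1, 0)      # fixed difference: 1
#' snp_fst(0.9, 0.1)  # 0.64
#' @export
snp_fst <- function(p1, p2) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  bad <- (!is.na(p1) & (p1 < 0 | p1 > 1)) | (!is.na(p2) & (p2 < 0 | p2 > 1))
  if (any(bad)) stop("snp_fst: allele frequencies must lie in [0, 1]")
  hs <- (2 * p1 * (1 - p1) + 2 * p2 * (1 - p2)) / 2
  pbar <- (p1 + p2) / 2
  ht <- 2 * pbar * (1 - pbar)
  fst <- ifelse(ht == 0, NA_real_, (ht - hs) / ht)
  pmax(fst, 0)
}

#' Hudson-estimator per-SNP F_ST
#'
#' An alternative estimator shipped for cross-checking the default Nei-style
#' [snp_fst()]: \eqn{F_{ST} = \frac{(p_1-p_2)^2 - p_1(1-p_1)/(n_1-1) -
#' p_2(1-p_2)/(n_2-1)}{p_1(1-p_2) + p_2(1-p_1)}}. With `n1 = n2 = Inf` the
#' sample-size corrections vanish and the population-parameter form
#' \eqn{(p_1-p_2)^2 / (p_1(1-p_2)+p_2(1-p_1))} is returned.
#'
#' @param p1,p2 allele frequencies in `[0, 1]` (vectorised).
#' @param n1,n2 allele-copy sample sizes per group (default `Inf`: no
#'   finite-sample correction).
#' @return numeric vector of F_ST values, clamped to `[0, 1]`, `NA` where the
#'   denominator is zero.
#' @export
snp_fst_hudson <- function(p1, p2, n1 = Inf, n2 = Inf) {
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (any(p1 < 0 | p1 > 1 | p2 < 0 | p2 > 1, na.rm = TRUE))
    stop("snp_fst_hudson: allele frequencies must lie in [0, 1]")
  c1 <- ifelse(is.finite(n1), p1 * (1 - p1) / pmax(n1 - 1, 1), 0)
  c2 <- ifelse(is.finite(n2), p2 * (1 - p2) / pmax(n2 - 1, 1), 0)
  num <- (p1 - p2)^2 - c1 - c2
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  fst <- ifelse(den == 0, NA_real_, num / den)
  pmin(pmax(fst, 0), 1)
}

#' Per-group allele frequencies and F_ST from pool counts
#'
#' Computes, for each locus in a [pool_counts()] table, the `allele_b` read
#' frequency in each ecotype pool and the per-SNP [snp_fst()]. Loci where a
#' group has zero reads get `NA` frequency and `NA` F_ST.
#'
#' @param pc a [pool_counts()] table.
#' @return a `data.frame` with columns `chromosome`, `position`, `locus_id`,
#'   `p_wbl`, `p_wrl`, `n_ind_wbl`, `n_ind_wrl`, `fst`.
#' @export
pool_allele_freqs <- function(pc) {
  stopifnot(inherits(pc, "pool_counts"))
  tw <- pc$wbl_a + pc$wbl_b
  tr <- pc$wrl_a + pc$wrl_b
  p_wbl <- ifelse(tw > 0, pc$wbl_b / tw, NA_real_)
  p_wrl <- ifelse(tr > 0, pc$wrl_b / tr, NA_real_)
  fst <- rep(NA_real_, nrow(pc))
  ok <- !is.na(p_wbl) & !is.na(p_wrl)
  fst[ok] <- snp_fst(p_wbl[ok], p_wrl[ok])
  data.frame(chromosome = pc$chromosome, position = pc$position,
             locus_id = locus_name(pc$chromosome, pc$position),
             p_wbl = p_wbl, p_wrl = p_wrl,
             n_ind_wbl = pc$wbl_n, n_ind_wrl = pc$wrl_n,
             fst = fst, stringsAsFactors = FALSE)
}

#' Coverage filter for pooled loci
#'
#' Retains loci where *both* ecotype groups have at least `min_ind_per_group`
#' individuals covered by one or more reads.
#'
#' @param pc a [pool_counts()] table.
#' @param min_ind_per_group minimum covered individuals per group (default 4).
#' @return the filtered [pool_counts()] table.
#' @export
coverage_filter <- function(pc, min_ind_per_group = 4L) {
  stopifnot(inherits(pc, "pool_counts"))
  keep <- pc$wbl_n >= min_ind_per_group & pc$wrl_n >= min_ind_per_group
  out <- pc[keep, , drop = FALSE]
  class(out) <- c("pool_counts", "data.frame")
  out
}

#' Re-estimate per-SNP F_ST from called genotypes
#'
#' Allele frequencies are recomputed from amplicon genotype calls (two allele
#' copies per successfully typed individual; missing calls excluded) and fed
#' through the same estimator as [snp_fst()]. Loci with zero typed individuals
#' in a group are undefined (`NA`).
#'
#' @param gt a [genotype_table()].
#' @param labels ecotype label per individual, `"WBL"` or `"WRL"`, in the
#'   order of `gt$individuals`.
#' @return a `data.frame` with columns `locus_id`, `chromosome`, `position`,
#'   `p_wbl`, `p_wrl` (allele_b frequencies), `n_wbl`, `n_wrl` (typed
#'   individuals) and `fst`.
#' @export
refit_fst_from_genotypes <- function(gt, labels) {
  stopifnot(inherits(gt, "genotype_table"))
  labels <- as.character(labels)
  if (length(labels) != length(gt$individuals))
    stop("labels must match the individuals of the genotype table")
  if (!all(labels %in% c("WBL", "WRL")))
    stop("labels must be 'WBL' or 'WRL'")
  dos <- allele_dosage(gt, "b")
  grp_freq <- function(rows) {
    d <- dos[rows, , drop = FALSE]
    n <- colSums(!is.na(d))
    p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / (2 * n), NA_real_)
    list(p = p, n = n)
  }
  w <- grp_freq(labels == "WBL")
  r <- grp_freq(labels == "WRL")
  fst <- rep(NA_real_, nrow(gt$loci))
  ok <- !is.na(w$p) & !is.na(r$p)
  fst[ok] <- snp_fst(w$p[ok], r$p[ok])
  data.frame(locus_id = gt$loci$locus_id, chromosome = gt$loci$chromosome,
             position = gt$loci$position,
             p_wbl = unname(w$p), p_wrl = unname(r$p),
             n_wbl = unname(w$n), n_wrl = unname(r$n),
             fst = fst, stringsAsFactors = FALSE)
}
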