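# Shared fixtures and independent oracles.

# small two-locus table used across IO and classifier tests
tiny_loci <- function() {
  locus_table(c("Lri2P100", "Lri5P200"), c("2", "5"), c(100L, 200L),
              c("A", "G"), c("T", "A"))
}

tiny_genotypes <- function() {
  m <- matrix(c("AT", "TT", "GA", NA), nrow = 2,
              dimnames = list(c("i1", "i2"), c("Lri2P100", "Lri5P200")))
  genotype_table(m, tiny_loci(), c("i1", "i2"))
}

# a 5-SNP panel with known designations: allele_b is the WRL allele at every
# locus; two loci sit on chromosome 2 (the required chromosome)
toy_panel_loci <- function() {
  loci <- locus_table(
    c("Lri2P1000", "Lri2P2000", "Lri5P1000", "Lri12P1000", "Lri14P1000"),
    c("2", "2", "5", "12", "14"), c(1000L, 2000L, 1000L, 1000L, 1000L),
    c("T", "A", "T", "C", "C"), c("A", "G", "A", "T", "A"))
  panel <- data.frame(as.data.frame(loci),
                      wrl_allele = loci$allele_b, wbl_allele = loci$allele_a,
                      diagnostic = TRUE, required = c(TRUE, TRUE, FALSE, FALSE, FALSE),
                      fst = c(0.58, 0.51, 0.48, 0.46, 0.45),
                      stringsAsFactors = FALSE)
  class(panel) <- c("panel_loci", "data.frame")
  panel
}

# wraps a toy panel as an "ecotype_panel" fit without fitting
toy_panel_fit <- function() {
  structure(list(panel = toy_panel_loci(), refit = NULL,
                 required_chromosome = "2", min_loci = 3L,
                 n_vouchers = c(WBL = 0L, WRL = 0L)),
            class = "ecotype_panel")
}

# independently coded Nei-style estimator (different arithmetic arrangement)
oracle_fst <- function(p1, p2) {
  freqs <- c(p1, p2)
  hs <- mean(2 * freqs * (1 - freqs))
  ht <- 2 * mean(freqs) * (1 - mean(freqs))
  if (ht == 0) return(NA_real_)
  max(0, 1 - hs / ht)
}

# brute-force window membership count for one SNP: enumerate starts directly
oracle_n_windows <- function(pos, window, step) {
  starts <- seq(1L, pos, by = step)
  sum(starts <= pos & pos < starts + window)
}

# exhaustive Mantel p-value over all n! joint row/column permutations
oracle_mantel_p <- function(a, b) {
  n <- nrow(a)
  perms <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  tri <- lower.tri(a)
  r_obs <- cor(a[tri], b[tri])
  rs <- vapply(perms(seq_len(n)),
               function(p) cor(a[tri], b[p, p][tri]), 0)
  mean(rs >= r_obs - 1e-12)
}

# expand a long-format cross-tab (genetic, morph, count) into paired vectors
expand_crosstab <- function(df) {
  list(genetic = rep(df$genetic, df$count), morph = rep(df$morph, df$count))
}

read_example <- function(file) {
  utils::read.delim(lampid_example(file), stringsAsFactors = FALSE,
                    check.names = FALSE)
}
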