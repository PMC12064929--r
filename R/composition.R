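#' Collection composition point estimate
#'
#' On the genus basis, the proportion of *Entosphenus* and *Lampetra* among
#' all genotyped individuals with a definitive genus call (*Lampetra* includes
#' individuals whose ecotype could not be resolved). On the ecotype basis, the
#' proportions of `WBL`, `Intermediate` and `WRL` among ecotype-classified
#' *Lampetra* only (ecotype-`Unknown` individuals are excluded).
#'
#' @param calls a call-record `data.frame` with columns `genus` and `ecotype`
#'   (see [classify_specimens()]), typically one collection's records.
#' @param basis `"genus"` or `"ecotype"`.
#' @return an object of class `"composition"`: list with `basis`, `counts`
#'   (named integer vector), `n`, `proportions` (named, summing to 1;
#'   all-`NA` when the denominator is zero).
#' @export
composition <- function(calls, basis = c("genus", "ecotype")) {
  basis <- match.arg(basis)
  if (basis == "genus") {
    counts <- c(Entosphenus = sum(calls$genus == "Entosphenus"),
                Lampetra = sum(calls$genus == "Lampetra"))
  } else {
    lam <- calls[calls$genus == "Lampetra", , drop = FALSE]
    counts <- c(WBL = sum(lam$ecotype == "WBL"),
                Intermediate = sum(lam$ecotype == "Intermediate"),
                WRL = sum(lam$ecotype == "WRL"))
  }
  n <- sum(counts)
  props <- if (n > 0) counts / n else stats::setNames(rep(NA_real_, length(counts)),
                                                      names(counts))
  structure(list(basis = basis, counts = counts, n = n, proportions = props),
            class = "composition")
}

#' Percentile-bootstrap confidence intervals for composition proportions
#'
#' Resamples `n` individuals with replacement from the empirical category
#' distribution (equivalently, draws multinomial replicates of the category
#' counts), recomputes the proportions per replicate, and takes the
#' percentile interval at `(1 - ci_level)/2` and `1 - (1 - ci_level)/2`
#' (linear-interpolation empirical quantiles). Deterministic given `seed`.
#'
#' @param counts named non-negative integer vector of category counts,
#'   `sum(counts) >= 1`; or a `"composition"` object.
#' @param n_boot number of bootstrap replicates (default 10000).
#' @param ci_level confidence level (default 0.99).
#' @param seed integer seed.
#' @return an object of class `"composition_estimate"`: list with `counts`,
#'   `n`, `proportions`, `ci` (matrix with rows `lower`/`upper`, one column
#'   per category), `ci_level`, `n_boot`, `seed`, `basis`.
#' @examples
#' est <- bootstrap_ci(c(WBL = 45, Intermediate = 4, WRL = 1), seed = 1)
#' est$ci["lower", "WBL"]  # about 0.78
#' @export
bootstrap_ci <- function(counts, n_boot = 10000L, ci_level = 0.99, seed = 1L) {
  basis <- NA_character_
  if (inherits(counts, "composition")) {
    basis <- counts$basis
    counts <- counts$counts
  }
  if (n_boot < 1L) stop("bootstrap_ci: n_boot must be >= 1")
  counts <- round(counts)
  n <- sum(counts)
  if (n < 1L) stop("bootstrap_ci: total count must be >= 1")
  if (any(counts < 0)) stop("bootstrap_ci: counts must be non-negative")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  reps <- stats::rmultinom(n_boot, n, counts / n) / n
  alpha <- (1 - ci_level) / 2
  ci <- apply(reps, 1L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  dimnames(ci) <- list(c("lower", "upper"), names(counts))
  structure(list(basis = basis, counts = counts, n = n,
                 proportions = counts / n, ci = ci, ci_level = ci_level,
                 n_boot = as.integer(n_boot), seed = as.integer(seed)),
            class = "composition_estimate")
}

# save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.composition_estimate <- function(x, ...) {
  cat("Composition estimate (n = ", x$n, ", ", x$n_boot, " bootstraps, ",
      100 * x$ci_level, "% CI, seed ", x$seed, ")\n", sep = "")
  df <- data.frame(category = names(x$counts), count = as.integer(x$counts),
                   proportion = sprintf("%.1f%%", 100 * x$proportions),
                   ci = sprintf("[%.1f%%, %.1f%%]", 100 * x$ci["lower", ],
                                100 * x$ci["upper", ]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.composition <- function(x, ...) {
  cat("Composition (", x$basis, " basis, n = ", x$n, ")\n", sep = "")
  print(data.frame(category = names(x$counts), count = as.integer(x$counts),
                   proportion = sprintf("%.1f%%", 100 * x$proportions)),
        row.names = FALSE)
  invisible(x)
}

#' Overlapping-CI stability test
#'
#' Two collections are called `"unstable"` for a category when their
#' bootstrap confidence intervals do not overlap (strictly:
#' `a_upper < b_lower` or `b_upper < a_lower`); touching intervals count as
#' overlap, hence `"stable"`.
#'
#' @param estimate_a,estimate_b `"composition_estimate"` objects on the same
#'   basis.
#' @param category category name present in both estimates.
#' @return `"stable"` or `"unstable"`.
#' @export
stability_test <- function(estimate_a, estimate_b, category) {
  stopifnot(inherits(estimate_a, "composition_estimate"),
            inherits(estimate_b, "composition_estimate"))
  if (!identical(estimate_a$basis, estimate_b$basis))
    stop("stability_test: estimates are on different bases")
  if (!(category %in% colnames(estimate_a$ci)) ||
      !(category %in% colnames(estimate_b$ci)))
    stop("stability_test: category not present in both estimates")
  a <- estimate_a$ci[, category]; b <- estimate_b$ci[, category]
  if (a[["upper"]] < b[["lower"]] || b[["upper"]] < a[["lower"]])
    "unstable" else "stable"
}

#' Cross-collection average composition
#'
#' Unweighted arithmetic mean (and range) of per-collection proportions,
#' over collections where the basis denominator is non-zero.
#'
#' @param estimates a list of `"composition"` or `"composition_estimate"`
#'   objects sharing the same categories.
#' @return a `data.frame` with one row per category: `mean`, `min`, `max`,
#'   `n_collections`.
#' @export
average_composition <- function(estimates) {
  props <- lapply(estimates, function(e) e$proportions)
  props <- props[!vapply(props, function(p) all(is.na(p)), TRUE)]
  if (!length(props)) stop("average_composition: no collections with defined proportions")
  m <- do.call(rbind, props)
  data.frame(category = colnames(m),
             mean = colMeans(m),
             min = apply(m, 2, min),
             max = apply(m, 2, max),
             n_collections = nrow(m),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Mantel permutation test
#'
#' Pearson correlation of the off-diagonal entries of two distance matrices,
#' with a one-sided upper-tail permutation p-value: the rows and columns of
#' the second matrix are permuted jointly `n_perm` times and
#' \eqn{p = (1 + \#\{r^* \ge r\}) / (1 + n_{perm})}. Deterministic given
#' `seed`. Typical upstream use: `a[i, j] = |rkm_i - rkm_j|` and
#' `b[i, j] = |f_i - f_j|` for per-collection WRL-allele frequencies `f`.
#'
#' @param a,b square symmetric numeric matrices with zero diagonal and equal
#'   dimension `n >= 3`.
#' @param n_perm number of permutations (default 9999).
#' @param seed integer seed.
#' @return an object of class `"mantel_result"`: list with `r`, `p`,
#'   `n_perm`, `seed`, `n`.
#' @export
mantel_test <- function(a, b, n_perm = 9999L, seed = 1L) {
  check <- function(m, nm) {
    if (!is.matrix(m) || nrow(m) != ncol(m))
      stop("mantel_test: ", nm, " must be a square matrix")
    if (any(abs(m - t(m)) > 1e-12)) stop("mantel_test: ", nm, " must be symmetric")
    if (any(diag(m) != 0)) stop("mantel_test: ", nm, " must have a zero diagonal")
  }
  check(a, "a"); check(b, "b")
  n <- nrow(a)
  if (n != nrow(b)) stop("mantel_test: matrices must have equal dimension")
  if (n < 3L) stop("mantel_test: need n >= 3")
  tri <- lower.tri(a)
  if (stats::sd(a[tri]) == 0 || stats::sd(b[tri]) == 0)
    stop("mantel_test: constant distance matrix, correlation undefined")
  r_obs <- stats::cor(a[tri], b[tri])
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    p <- sample.int(n)
    r_star <- stats::cor(a[tri], b[p, p][tri])
    if (r_star >= r_obs - 1e-12) hits <- hits + 1L  # fp-safe tie handling
  }
  structure(list(r = r_obs, p = (1 + hits) / (1 + n_perm),
                 n_perm = as.integer(n_perm), seed = as.integer(seed), n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.3f, p = %.4g (%d permutations, n = %d)\n",
              x$r, x$p, x$n_perm, x$n))
  invisible(x)
}
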