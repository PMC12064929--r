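#' Genus identification concordance
#'
#' Cross-tabulates genetic against morphological genus identifications and
#' computes agreement rates over specimens with a definitive ID on both sides
#' (genetic *Entosphenus*/*Lampetra*; morphological *Entosphenus*/*Lampetra*).
#' `Hybrid`, `Conflict`, `Unknown` and `unknown` entries are dropped before
#' any rate is computed.
#'
#' Per-class rates are reported on both denominators: the genetic row total
#' (fraction of genetically identified class X confirmed by morphology) and
#' the morphological column total (fraction of morphologically identified
#' class X confirmed genetically). Survey reporting conventionally quotes the
#' row basis for *Entosphenus* and the column basis for *Lampetra*.
#'
#' @param genetic character vector of genus calls (`Entosphenus`, `Lampetra`,
#'   `Hybrid`, `Conflict`, `Unknown`).
#' @param morph character vector of morphological genus IDs (`Entosphenus`,
#'   `Lampetra`, `unknown`).
#' @return an object of class `"concordance"`: list with `cross_tab` (full
#'   table including non-definitive categories), `n_definitive`, `overall`
#'   (rate, numerator, denominator) and `by_class` (one row per class and
#'   denominator basis).
#' @export
genus_concordance <- function(genetic, morph) {
  stopifnot(length(genetic) == length(morph))
  genetic <- factor(genetic, c("Entosphenus", "Lampetra", "Hybrid",
                               "Conflict", "Unknown"))
  morph <- factor(morph, c("Entosphenus", "Lampetra", "unknown"))
  if (anyNA(genetic) || anyNA(morph))
    stop("genus_concordance: unrecognised category")
  xt <- table(genetic = genetic, morph = morph)
  def <- xt[c("Entosphenus", "Lampetra"), c("Entosphenus", "Lampetra")]
  n_def <- sum(def)
  matches <- sum(diag(def))
  overall <- list(rate = if (n_def) matches / n_def else NA_real_,
                  matches = matches, n = n_def)
  by_class <- do.call(rbind, lapply(c("Entosphenus", "Lampetra"), function(cl) {
    row_n <- sum(def[cl, ]); col_n <- sum(def[, cl])
    data.frame(class = cl,
               basis = c("genetic_row", "morph_column"),
               matches = def[cl, cl],
               n = c(row_n, col_n),
               rate = c(if (row_n) def[cl, cl] / row_n else NA_real_,
                        if (col_n) def[cl, cl] / col_n else NA_real_),
               stringsAsFactors = FALSE)
  }))
  structure(list(cross_tab = xt, n_definitive = n_def, overall = overall,
                 by_class = by_class, basis = "genus"),
            class = "concordance")
}

#' Ecotype identification concordance (survey convention)
#'
#' Cross-tabulates genetic ecotype calls (`WBL`, `WRL`, `Intermediate`,
#' `Unknown`) against morphological ecotype IDs (`WBL`, `WRL`, `unknown`) and
#' computes:
#' \describe{
#'   \item{definitive rate}{matches / (matches + mismatches) over pairs
#'     definitive on both sides.}
#'   \item{per-class rates}{for class X, matches_X divided by matches_X plus
#'     every definitive mismatch involving X on either side.}
#'   \item{morph-denominator rate}{matches over all definitive morphological
#'     IDs (with a genetic call other than Unknown), so genetic Intermediates
#'     count as non-matching.}
#'   \item{resolution}{how much each method rescues from the non-definitive
#'     pool. The pool size follows survey bookkeeping: the number of
#'     morphologically unknown specimens plus the number of genetically
#'     non-definitive (Intermediate/Unknown) specimens, summed — a specimen
#'     non-definitive on both sides contributes to both counts. Genetics
#'     resolves the morph-unknowns with a definitive genetic call;
#'     morphology resolves the genetic non-definitives with a definitive
#'     morphological ID.}
#' }
#'
#' @param genetic character vector of genetic ecotype calls.
#' @param morph character vector of morphological ecotype IDs.
#' @return an object of class `"concordance"`: list with `cross_tab`,
#'   `definitive` (rate/matches/n), `by_class`, `morph_basis`
#'   (rate/matches/n), `resolution` (n_nondefinitive, genetic_resolved,
#'   morph_resolved and their rates).
#' @export
ecotype_concordance <- function(genetic, morph) {
  stopifnot(length(genetic) == length(morph))
  genetic <- factor(genetic, c("WRL", "Intermediate", "WBL", "Unknown"))
  morph <- factor(morph, c("WRL", "unknown", "WBL"))
  if (anyNA(genetic) || anyNA(morph))
    stop("ecotype_concordance: unrecognised category")
  xt <- table(genetic = genetic, morph = morph)
  def <- xt[c("WRL", "WBL"), c("WRL", "WBL")]
  matches <- sum(diag(def))
  n_def <- sum(def)
  definitive <- list(rate = if (n_def) matches / n_def else NA_real_,
                     matches = matches, n = n_def)
  by_class <- do.call(rbind, lapply(c("WRL", "WBL"), function(cl) {
    mm <- sum(def) - sum(diag(def))  # all definitive mismatches involve both classes here
    n <- def[cl, cl] + mm
    data.frame(class = cl, matches = def[cl, cl], n = n,
               rate = if (n) def[cl, cl] / n else NA_real_,
               stringsAsFactors = FALSE)
  }))
  # definitive morphological IDs with a non-Unknown genetic call
  morph_def <- sum(xt[c("WRL", "Intermediate", "WBL"), c("WRL", "WBL")])
  morph_basis <- list(rate = if (morph_def) matches / morph_def else NA_real_,
                      matches = matches, n = morph_def)
  gen_nondef <- genetic %in% c("Intermediate", "Unknown")
  mor_nondef <- morph == "unknown"
  # additive pool: a pair non-definitive on both sides counts in both terms
  n_nondef <- sum(mor_nondef) + sum(gen_nondef)
  gen_res <- sum(mor_nondef & !gen_nondef)
  mor_res <- sum(gen_nondef & !mor_nondef)
  resolution <- list(n_nondefinitive = n_nondef,
                     genetic_resolved = gen_res,
                     morph_resolved = mor_res,
                     genetic_rate = if (n_nondef) gen_res / n_nondef else NA_real_,
                     morph_rate = if (n_nondef) mor_res / n_nondef else NA_real_)
  structure(list(cross_tab = xt, definitive = definitive, by_class = by_class,
                 morph_basis = morph_basis, resolution = resolution,
                 basis = "ecotype"),
            class = "concordance")
}

#' Ecotype identification concordance (voucher convention)
#'
#' The validation-style rate used when auditing a panel against
#' morphologically confident vouchers: specimens are grouped by their
#' *morphological* class, genetic `Unknown`s are excluded, and genetic
#' Intermediates stay in the denominator, giving
#' matches / (matches + mismatches + intermediates) per morphological class
#' and in total.
#'
#' @param genetic character vector of genetic ecotype calls (`WBL`, `WRL`,
#'   `Intermediate`, `Unknown`).
#' @param morph character vector of morphological ecotype IDs (`WBL`, `WRL`).
#' @return an object of class `"voucher_concordance"`: list with `by_class`
#'   (per morphological class: matches, mismatches, intermediates, unknowns,
#'   n, rate) and `total`.
#' @export
voucher_concordance <- function(genetic, morph) {
  stopifnot(length(genetic) == length(morph))
  if (!all(morph %in% c("WBL", "WRL")))
    stop("voucher_concordance: morph IDs must be definitive (WBL or WRL)")
  if (!all(genetic %in% c("WBL", "WRL", "Intermediate", "Unknown")))
    stop("voucher_concordance: unrecognised genetic call")
  per <- lapply(c("WBL", "WRL"), function(cl) {
    g <- genetic[morph == cl]
    m <- sum(g == cl)
    mm <- sum(g %in% c("WBL", "WRL") & g != cl)
    int <- sum(g == "Intermediate")
    unk <- sum(g == "Unknown")
    n <- m + mm + int
    data.frame(morph_class = cl, matches = m, mismatches = mm,
               intermediates = int, unknowns = unk, n = n,
               rate = if (n) m / n else NA_real_, stringsAsFactors = FALSE)
  })
  by_class <- do.call(rbind, per)
  tot_n <- sum(by_class$n)
  total <- list(matches = sum(by_class$matches),
                n = tot_n,
                rate = if (tot_n) sum(by_class$matches) / tot_n else NA_real_)
  structure(list(by_class = by_class, total = total),
            class = "voucher_concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat("Genetic vs morphological ID concordance (", x$basis, ")\n", sep = "")
  print(x$cross_tab)
  if (x$basis == "genus") {
    cat(sprintf("\noverall: %d/%d = %.1f%%\n", x$overall$matches,
                x$overall$n, 100 * x$overall$rate))
  } else {
    cat(sprintf("\ndefinitive-both: %d/%d = %.1f%%\n", x$definitive$matches,
                x$definitive$n, 100 * x$definitive$rate))
    cat(sprintf("morph-denominator: %d/%d = %.1f%%\n", x$morph_basis$matches,
                x$morph_basis$n, 100 * x$morph_basis$rate))
    cat(sprintf("nondefinitive resolved by genetics: %d/%d = %.0f%%\n",
                x$resolution$genetic_resolved, x$resolution$n_nondefinitive,
                100 * x$resolution$genetic_rate))
  }
  cat("\nby class:\n")
  print(x$by_class, row.names = FALSE)
  invisible(x)
}

#' @export
print.voucher_concordance <- function(x, ...) {
  cat("Voucher ecotype ID concordance\n")
  print(x$by_class, row.names = FALSE)
  cat(sprintf("total: %d match / %d = %.1f%%\n", x$total$matches, x$total$n,
              100 * x$total$rate))
  invisible(x)
}
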