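#' Designate WRL/WBL diagnostic alleles from voucher genotypes
#'
#' For each locus, the allele with the higher relative frequency among WRL
#' vouchers than among WBL vouchers becomes the `wrl_allele` and the other the
#' `wbl_allele`. Loci where the two groups have exactly equal frequencies are
#' flagged non-diagnostic (`diagnostic = FALSE`) and should be excluded from
#' classification.
#'
#' @param gt a [genotype_table()] of voucher individuals at candidate loci.
#' @param labels `"WBL"`/`"WRL"` voucher label per individual.
#' @return a `data.frame` (class `"panel_loci"`) with the locus columns plus
#'   `wrl_allele`, `wbl_allele`, `diagnostic`, and the per-group
#'   `allele_b` frequencies `p_wbl`, `p_wrl`.
#' @export
designate_alleles <- function(gt, labels) {
  ref <- refit_fst_from_genotypes(gt, labels)
  dead <- ref$n_wbl == 0L | ref$n_wrl == 0L
  if (any(dead))
    stop("designate_alleles: group entirely missing at locus ",
         paste(ref$locus_id[dead], collapse = ", "))
  loci <- as.data.frame(gt$loci)
  # p_* are allele_b frequencies: allele_b is the WRL allele when its
  # frequency is higher among WRL vouchers
  wrl_is_b <- ref$p_wrl > ref$p_wbl
  tie <- ref$p_wrl == ref$p_wbl
  out <- data.frame(loci,
                    wrl_allele = ifelse(wrl_is_b, loci$allele_b, loci$allele_a),
                    wbl_allele = ifelse(wrl_is_b, loci$allele_a, loci$allele_b),
                    diagnostic = !tie,
                    p_wbl = ref$p_wbl, p_wrl = ref$p_wrl,
                    fst = ref$fst, stringsAsFactors = FALSE)
  out$wrl_allele[tie] <- NA_character_
  out$wbl_allele[tie] <- NA_character_
  class(out) <- c("panel_loci", "data.frame")
  out
}

#' Select the final SNP panel by refit F_ST
#'
#' Ranks loci by genotype-refit F_ST (ties broken by smaller position) and
#' keeps the top `panel_size`. Loci with undefined F_ST are never selected.
#'
#' @param refit a `data.frame` from [refit_fst_from_genotypes()].
#' @param panel_size number of loci to keep (default 5).
#' @return the selected rows, in rank order.
#' @export
select_panel <- function(refit, panel_size = 5L) {
  def <- refit[!is.na(refit$fst), , drop = FALSE]
  if (nrow(def) < panel_size) {
    warning("select_panel: only ", nrow(def), " loci with defined F_ST; ",
            "returning all")
    panel_size <- nrow(def)
  }
  def <- def[order(-def$fst, def$position), , drop = FALSE]
  out <- utils::head(def, panel_size)
  rownames(out) <- NULL
  out
}

#' Fit a diagnostic ecotype panel from voucher genotypes
#'
#' The panel "fit": re-estimates per-SNP F_ST from amplicon genotypes of the
#' candidate loci (see [refit_fst_from_genotypes()]), keeps the top
#' `panel_size` SNPs ([select_panel()]), designates the WRL and WBL allele at
#' each ([designate_alleles()]), and records which panel loci sit on the most
#' diagnostic chromosome — the chromosome of the top-ranked SNP. Classification
#' of new individuals ([predict.ecotype_panel()]) requires at least
#' `min_loci` typed panel SNPs including at least one SNP on that chromosome.
#'
#' @param gt a [genotype_table()] of voucher individuals at candidate loci.
#' @param labels `"WBL"`/`"WRL"` voucher label per individual, in the order of
#'   `gt$individuals`.
#' @param panel_size panel size (default 5).
#' @param min_loci minimum typed panel loci for a defined percent-WRL
#'   (default 3).
#' @return an object of class `"ecotype_panel"`: list with `panel` (a
#'   `"panel_loci"` data.frame with refit F_ST, allele designations and a
#'   `required` flag marking loci on the most diagnostic chromosome), `refit`
#'   (the full refit table), `required_chromosome`, `min_loci`, `n_vouchers`
#'   (named WBL/WRL counts).
#' @examples
#' \dontrun{
#' fit <- ecotype_panel(voucher_gt, voucher_labels)
#' calls <- predict(fit, survey_gt)
#' }
#' @export
ecotype_panel <- function(gt, labels, panel_size = 5L, min_loci = 3L) {
  refit <- refit_fst_from_genotypes(gt, labels)
  sel <- select_panel(refit, panel_size)
  keep <- match(sel$locus_id, gt$loci$locus_id)
  des <- designate_alleles(gt[, keep], labels)
  if (any(!des$diagnostic)) {
    warning("ecotype_panel: dropping non-diagnostic (tied-frequency) loci: ",
            paste(des$locus_id[!des$diagnostic], collapse = ", "))
    des <- des[des$diagnostic, , drop = FALSE]
  }
  des <- des[order(-des$fst, des$position), , drop = FALSE]
  req_chrom <- des$chromosome[1L]
  des$required <- des$chromosome == req_chrom
  rownames(des) <- NULL
  structure(list(panel = des, refit = refit,
                 required_chromosome = req_chrom,
                 min_loci = as.integer(min_loci),
                 n_vouchers = c(WBL = sum(labels == "WBL"),
                                WRL = sum(labels == "WRL"))),
            class = "ecotype_panel")
}

#' @export
print.ecotype_panel <- function(x, ...) {
  cat("Diagnostic ecotype panel (", nrow(x$panel), " SNPs; fit on ",
      x$n_vouchers[["WBL"]], " WBL + ", x$n_vouchers[["WRL"]],
      " WRL vouchers)\n", sep = "")
  cat("  required chromosome: ", x$required_chromosome,
      " (>= 1 typed SNP there, and >= ", x$min_loci,
      " typed panel SNPs overall)\n\n", sep = "")
  print(x$panel[, c("locus_id", "chromosome", "position", "wrl_allele",
                    "wbl_allele", "fst", "required")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.ecotype_panel <- function(object, ...) {
  print(object)
  cat("\nRefit F_ST over all", nrow(object$refit), "candidate loci:\n")
  def <- object$refit$fst[!is.na(object$refit$fst)]
  cat(sprintf("  mean %.3f, range %.3f-%.3f\n",
              mean(def), min(def), max(def)))
  invisible(object)
}

#' @export
coef.ecotype_panel <- function(object, ...) {
  stats::setNames(object$panel$fst, object$panel$locus_id)
}

#' Percent WRL alleles per individual
#'
#' For each individual: the number of WRL-designated allele copies across
#' successfully typed panel SNPs, divided by the total number of typed allele
#' copies (2 per typed SNP). Undefined (`NA`) unless at least `min_loci` panel
#' SNPs are typed *and* at least one typed SNP lies on the required (most
#' diagnostic) chromosome.
#'
#' @param gt a [genotype_table()] containing the panel loci.
#' @param panel an `"ecotype_panel"` fit or its `panel` data.frame (needs
#'   `locus_id`, `wrl_allele`, `required`).
#' @param min_loci minimum typed loci (default: the fit's setting, else 3).
#' @return a `data.frame` with `individual_id`, `n_loci_typed`,
#'   `n_alleles_typed`, `n_wrl_alleles`, `pct_wrl` (fraction in `[0, 1]` or
#'   `NA`).
#' @export
pct_wrl <- function(gt, panel, min_loci = NULL) {
  if (inherits(panel, "ecotype_panel")) {
    if (is.null(min_loci)) min_loci <- panel$min_loci
    panel <- panel$panel
  }
  if (is.null(min_loci)) min_loci <- 3L
  if (!all(c("locus_id", "wrl_allele", "required") %in% names(panel)))
    stop("pct_wrl: panel must carry locus_id, wrl_allele and required columns")
  idx <- match(panel$locus_id, gt$loci$locus_id)
  if (anyNA(idx))
    stop("pct_wrl: genotype table lacks panel locus ",
         paste(panel$locus_id[is.na(idx)], collapse = ", "))
  sub <- gt[, idx]
  calls <- sub$calls
  wrl <- panel$wrl_allele
  # copies of the WRL allele per call (0/1/2), NA where missing
  nw <- matrix(NA_integer_, nrow(calls), ncol(calls))
  for (j in seq_len(ncol(calls))) {
    cj <- calls[, j]
    nw[, j] <- (substr(cj, 1, 1) == wrl[j]) + (substr(cj, 2, 2) == wrl[j])
  }
  typed <- !is.na(calls)
  n_loci <- rowSums(typed)
  n_wrl <- rowSums(nw, na.rm = TRUE)
  req_typed <- rowSums(typed[, panel$required, drop = FALSE]) > 0L
  valid <- n_loci >= min_loci & req_typed
  data.frame(individual_id = sub$individuals,
             n_loci_typed = n_loci,
             n_alleles_typed = 2L * n_loci,
             n_wrl_alleles = as.integer(n_wrl),
             pct_wrl = ifelse(valid, n_wrl / (2 * n_loci), NA_real_),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Ecotype call from percent WRL
#'
#' Applies the 50% rule: more than 50% WRL alleles is `WRL`, less is `WBL`,
#' exactly 50% is `Intermediate`, and an undefined percent (`NA`) is
#' `Unknown`.
#'
#' @param pct fraction of WRL alleles in `[0, 1]`, `NA` allowed (vectorised).
#' @return character vector of calls.
#' @examples
#' call_ecotype(c(0.70, 0.50, 0.25, NA))
#' @export
call_ecotype <- function(pct) {
  if (any(pct < 0 | pct > 1, na.rm = TRUE))
    stop("call_ecotype: pct must lie in [0, 1]")
  out <- rep("Unknown", length(pct))
  out[!is.na(pct) & pct > 0.5] <- "WRL"
  out[!is.na(pct) & pct < 0.5] <- "WBL"
  out[!is.na(pct) & pct == 0.5] <- "Intermediate"
  out
}

#' Classify individuals with a fitted ecotype panel
#'
#' @param object an `"ecotype_panel"` fit.
#' @param newdata a [genotype_table()] containing the panel loci.
#' @param ... unused.
#' @return a `data.frame` with `individual_id`, `n_loci_typed`,
#'   `n_alleles_typed`, `n_wrl_alleles`, `pct_wrl` and `ecotype`
#'   (`WBL`/`WRL`/`Intermediate`/`Unknown`).
#' @export
predict.ecotype_panel <- function(object, newdata, ...) {
  res <- pct_wrl(newdata, object)
  res$ecotype <- call_ecotype(res$pct_wrl)
  res
}
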