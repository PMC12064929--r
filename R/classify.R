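#' Genus call from the two redundant diagnostic markers
#'
#' The conditional two-SNP rule for separating *Entosphenus* from *Lampetra*
#' with markers LampSD_478 (alleles G/A) and LampSD_700 (alleles G/T):
#' a heterozygous genotype at either marker calls `Hybrid`; otherwise
#' `"AA"` at 478 or `"TT"` at 700 signals *Lampetra* and `"GG"` at either
#' marker signals *Entosphenus*. With both markers missing the call is
#' `Unknown`; with one marker missing the other decides (single-marker calls
#' are made); two homozygous markers that disagree call `Conflict`, a
#' category excluded from all downstream denominators.
#'
#' @param geno_478 genotype at LampSD_478: `"AA"`, `"GA"`/`"AG"`, `"GG"` or
#'   `NA` (vectorised).
#' @param geno_700 genotype at LampSD_700: `"TT"`, `"GT"`/`"TG"`, `"GG"` or
#'   `NA`.
#' @return a `data.frame` with columns `call` (`Entosphenus`, `Lampetra`,
#'   `Hybrid`, `Conflict`, `Unknown`) and `markers_typed` (0-2).
#' @examples
#' call_genus(c("AA", NA, "GA", "AA"), c("TT", "GG", "GG", "GG"))$call
#' @export
call_genus <- function(geno_478, geno_700) {
  norm <- function(g, legal, marker) {
    g <- as.character(g)
    typed <- !is.na(g)
    if (any(nchar(g[typed]) != 2L))
      stop("call_genus: malformed genotype at ", marker)
    a1 <- substr(g, 1, 1); a2 <- substr(g, 2, 2)
    bad <- typed & (!(a1 %in% legal) | !(a2 %in% legal))
    if (any(bad))
      stop("call_genus: allele outside {", paste(legal, collapse = ","),
           "} at ", marker, ": '", g[bad][1L], "'")
    swap <- typed & a1 > a2
    g[swap] <- paste0(a2[swap], a1[swap])
    g
  }
  g478 <- norm(geno_478, c("G", "A"), "LampSD_478")
  g700 <- norm(geno_700, c("G", "T"), "LampSD_700")
  if (length(g478) != length(g700))
    stop("call_genus: marker vectors must have equal length")
  het <- (!is.na(g478) & g478 == "AG") | (!is.na(g700) & g700 == "GT")
  sig478 <- ifelse(is.na(g478), NA,
                   ifelse(g478 == "AA", "Lampetra",
                          ifelse(g478 == "GG", "Entosphenus", NA)))
  sig700 <- ifelse(is.na(g700), NA,
                   ifelse(g700 == "TT", "Lampetra",
                          ifelse(g700 == "GG", "Entosphenus", NA)))
  call <- rep("Unknown", length(g478))
  one <- is.na(sig478) != is.na(sig700)
  call[one] <- ifelse(is.na(sig478[one]), sig700[one], sig478[one])
  both <- !is.na(sig478) & !is.na(sig700)
  call[both & sig478 == sig700] <- sig478[both & sig478 == sig700]
  call[both & sig478 != sig700] <- "Conflict"
  call[het] <- "Hybrid"  # any heterozygous marker takes precedence
  data.frame(call = call,
             markers_typed = (!is.na(g478)) + (!is.na(g700)),
             stringsAsFactors = FALSE)
}

#' Classify specimens: genus then ecotype
#'
#' Runs the two-marker genus rule on every individual, then applies the
#' fitted ecotype panel to those called *Lampetra*. Individuals not called
#' *Lampetra* get ecotype `Unknown` and an undefined percent WRL.
#'
#' @param gt a [genotype_table()] containing the genus markers and the panel
#'   loci.
#' @param panel an `"ecotype_panel"` fit (see [ecotype_panel()]).
#' @param genus_markers names of the two genus marker loci in `gt`, in the
#'   order (478-type, 700-type). Default `c("LampSD_478", "LampSD_700")`.
#' @return a `data.frame` of call records: `individual_id`, `genus`,
#'   `genus_markers_typed`, `n_loci_typed`, `n_alleles_typed`,
#'   `n_wrl_alleles`, `pct_wrl`, `ecotype`.
#' @export
classify_specimens <- function(gt, panel,
                               genus_markers = c("LampSD_478", "LampSD_700")) {
  stopifnot(inherits(gt, "genotype_table"), inherits(panel, "ecotype_panel"))
  miss <- setdiff(genus_markers, gt$loci$locus_id)
  if (length(miss))
    stop("classify_specimens: genotype table lacks genus marker(s): ",
         paste(miss, collapse = ", "))
  gen <- call_genus(gt$calls[, genus_markers[1L]], gt$calls[, genus_markers[2L]])
  eco <- predict(panel, gt)
  is_lam <- gen$call == "Lampetra"
  eco$pct_wrl[!is_lam] <- NA_real_
  eco$ecotype[!is_lam] <- "Unknown"
  data.frame(individual_id = gt$individuals, genus = gen$call,
             genus_markers_typed = gen$markers_typed,
             n_loci_typed = eco$n_loci_typed,
             n_alleles_typed = eco$n_alleles_typed,
             n_wrl_alleles = eco$n_wrl_alleles,
             pct_wrl = eco$pct_wrl, ecotype = eco$ecotype,
             stringsAsFactors = FALSE)
}

#' Format a fraction as a one-decimal percentage
#'
#' Reporting helper using round-half-away-from-zero (so 0.33335 prints as
#' "33.3" and 0.125 as "12.5", matching field reporting conventions).
#'
#' @param x fractions in `[0, 1]` (or `NA`).
#' @param digits decimal places (default 1).
#' @return numeric vector of percentages.
#' @export
percent <- function(x, digits = 1L) {
  s <- sign(x)
  s * floor(abs(x) * 100 * 10^digits + 0.5) / 10^digits
}
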