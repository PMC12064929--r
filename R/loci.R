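#' Build and validate a locus table
#'
#' A locus table describes bi-allelic genomic sites: one row per SNP with a
#' unique identifier, chromosome, 1-based position and the two allele symbols.
#' All genotype and pool-count containers in the package cross-check their
#' calls against a locus table.
#'
#' @param locus_id character vector of unique locus identifiers.
#' @param chromosome character vector of chromosome (scaffold) names.
#' @param position integer vector of 1-based positions.
#' @param allele_a,allele_b single-character allele symbols; `allele_a` must
#'   differ from `allele_b` at every locus.
#' @return A `data.frame` with class `"locus_table"` and columns `locus_id`,
#'   `chromosome`, `position`, `allele_a`, `allele_b`.
#' @examples
#' locus_table("Lri2P16333005", "2", 16333005, "A", "T")
#' @export
locus_table <- function(locus_id, chromosome, position, allele_a, allele_b) {
  locus_id <- as.character(locus_id)
  chromosome <- as.character(chromosome)
  position <- as.integer(position)
  allele_a <- as.character(allele_a)
  allele_b <- as.character(allele_b)
  n <- length(locus_id)
  if (!all(lengths(list(chromosome, position, allele_a, allele_b)) == n))
    stop("locus_table: all columns must have the same length")
  if (anyDuplicated(locus_id))
    stop("locus_table: duplicate locus_id: ",
         paste(unique(locus_id[duplicated(locus_id)]), collapse = ", "))
  if (any(is.na(position)) || any(position < 1L))
    stop("locus_table: positions must be integers >= 1")
  if (any(nchar(allele_a) != 1L) || any(nchar(allele_b) != 1L))
    stop("locus_table: alleles must be single-character symbols")
  if (any(allele_a == allele_b))
    stop("locus_table: allele_a equals allele_b at: ",
         paste(locus_id[allele_a == allele_b], collapse = ", "))
  out <- data.frame(locus_id = locus_id, chromosome = chromosome,
                    position = position, allele_a = allele_a,
                    allele_b = allele_b, stringsAsFactors = FALSE)
  class(out) <- c("locus_table", "data.frame")
  out
}

#' Systematic locus name from chromosome and position
#'
#' Encodes a SNP as `<prefix><chromosome>P<position>`, the naming scheme used
#' for *Lampetra richardsoni* assay loci (e.g. `Lri2P16333005` for chromosome 2,
#' position 16,333,005).
#'
#' @param chromosome chromosome name(s).
#' @param position 1-based position(s).
#' @param prefix genome prefix, default `"Lri"`.
#' @return character vector of locus names.
#' @export
locus_name <- function(chromosome, position, prefix = "Lri") {
  paste0(prefix, chromosome, "P", format(position, scientific = FALSE, trim = TRUE))
}

# internal: check that a vector of allele symbols is legal for given loci rows
.check_alleles <- function(alleles, loci, what = "allele") {
  ok <- alleles == loci$allele_a | alleles == loci$allele_b
  if (!all(ok)) {
    bad <- which(!ok)[1L]
    stop(what, " '", alleles[bad], "' is not one of {", loci$allele_a[bad],
         ",", loci$allele_b[bad], "} at locus ", loci$locus_id[bad])
  }
  invisible(TRUE)
}
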