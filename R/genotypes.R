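#' Construct a genotype table
#'
#' An individuals-by-loci matrix of unphased, unordered bi-allelic genotype
#' calls. Calls are stored as two-character strings with the alleles in sorted
#' order ("GT" and "TG" are the same genotype and both normalise to "GT");
#' missing calls are `NA`. Every non-missing call is validated against the two
#' alleles of its locus.
#'
#' @param calls character matrix (individuals x loci) of two-character
#'   genotype strings or `NA`. Row and column order must match `individuals`
#'   and `loci`.
#' @param loci a [locus_table()].
#' @param individuals character vector of unique individual identifiers.
#' @return An object of class `"genotype_table"`: a list with elements
#'   `calls` (normalised matrix), `loci`, `individuals`.
#' @examples
#' loci <- locus_table(c("L1", "L2"), c("2", "5"), c(100, 200),
#'                     c("A", "G"), c("T", "A"))
#' gt <- genotype_table(matrix(c("AT", "TA", "GG", NA), nrow = 2,
#'                             dimnames = list(c("i1", "i2"), c("L1", "L2"))),
#'                      loci, c("i1", "i2"))
#' gt$calls["i2", "L1"]  # "AT": unordered pair
#' @export
genotype_table <- function(calls, loci, individuals) {
  stopifnot(inherits(loci, "locus_table"))
  individuals <- as.character(individuals)
  if (anyDuplicated(individuals))
    stop("genotype_table: duplicate individual_id: ",
         paste(unique(individuals[duplicated(individuals)]), collapse = ", "))
  calls <- as.matrix(calls)
  if (nrow(calls) != length(individuals) || ncol(calls) != nrow(loci))
    stop("genotype_table: calls matrix must be ", length(individuals), " x ",
         nrow(loci))
  dimnames(calls) <- list(individuals, loci$locus_id)
  for (j in seq_len(ncol(calls))) {
    cj <- calls[, j]
    typed <- !is.na(cj)
    if (!any(typed)) next
    if (any(nchar(cj[typed]) != 2L))
      stop("genotype_table: malformed call at locus ", loci$locus_id[j],
           ", individual ",
           individuals[typed][which(nchar(cj[typed]) != 2L)[1L]])
    a1 <- substr(cj[typed], 1L, 1L)
    a2 <- substr(cj[typed], 2L, 2L)
    legal <- c(loci$allele_a[j], loci$allele_b[j])
    bad <- !(a1 %in% legal) | !(a2 %in% legal)
    if (any(bad))
      stop("genotype_table: call '", cj[typed][bad][1L], "' at locus ",
           loci$locus_id[j], ", individual ",
           individuals[typed][bad][1L], " uses an allele outside {",
           legal[1L], ",", legal[2L], "}")
    # normalise to sorted allele order so "TG" == "GT"
    swap <- a1 > a2
    cj[typed][swap] <- paste0(a2[swap], a1[swap])
    calls[, j] <- cj
  }
  structure(list(calls = calls, loci = loci, individuals = individuals),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("genotype_table: ", length(x$individuals), " individuals x ",
      nrow(x$loci), " loci; ",
      sum(is.na(x$calls)), " missing call(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$calls)

#' Subset a genotype table
#'
#' @param x a [genotype_table()].
#' @param i individual index (character ids, logical or integer).
#' @param j locus index (character locus_ids, logical or integer).
#' @param ... unused.
#' @return a `genotype_table` restricted to the selected rows/columns.
#' @export
`[.genotype_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$individuals)
  if (missing(j)) j <- seq_len(nrow(x$loci))
  if (is.character(j)) j <- match(j, x$loci$locus_id)
  if (anyNA(j)) stop("unknown locus_id in genotype table subset")
  calls <- x$calls[i, j, drop = FALSE]
  loci <- x$loci[j, , drop = FALSE]
  class(loci) <- c("locus_table", "data.frame")
  structure(list(calls = calls, loci = loci, individuals = rownames(calls)),
            class = "genotype_table")
}

#' Allele dosage matrix
#'
#' Counts copies of a chosen allele per call: 0, 1 or 2 (`NA` where missing).
#'
#' @param gt a [genotype_table()].
#' @param allele which allele to count, `"b"` (default) or `"a"`.
#' @return integer matrix of the same shape as `gt$calls`.
#' @export
allele_dosage <- function(gt, allele = c("b", "a")) {
  allele <- match.arg(allele)
  sym <- if (allele == "b") gt$loci$allele_b else gt$loci$allele_a
  d <- matrix(NA_integer_, nrow(gt$calls), ncol(gt$calls),
              dimnames = dimnames(gt$calls))
  for (j in seq_len(ncol(d))) {
    cj <- gt$calls[, j]
    d[, j] <- (substr(cj, 1, 1) == sym[j]) + (substr(cj, 2, 2) == sym[j])
  }
  d
}
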