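#' Read a genotype table from TSV
#'
#' The dialect is one header row (`individual_id` then locus ids), one row per
#' individual, calls encoded as two-character strings (e.g. `"AA"`, `"GA"`) and
#' missing calls as `"--"`. Genotypes are unordered pairs: `"GT"` and `"TG"`
#' are the same call. Every call is validated against `loci`.
#'
#' @param path file to read.
#' @param loci a [locus_table()] giving the legal alleles per locus; the file
#'   must contain exactly these loci (any column order).
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, loci) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  if (names(df)[1L] != "individual_id")
    stop("genotype TSV must start with an 'individual_id' column")
  ind <- df$individual_id
  if (anyDuplicated(ind))
    stop("duplicate individual_id in ", path, ": ",
         paste(unique(ind[duplicated(ind)]), collapse = ", "))
  want <- loci$locus_id
  miss <- setdiff(want, names(df))
  if (length(miss))
    stop("genotype TSV is missing locus column(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(df[, want, drop = FALSE])
  m[m == "--" | m == ""] <- NA_character_
  rownames(m) <- ind
  genotype_table(m, loci, ind)
}

#' Write a genotype table to TSV
#'
#' Inverse of [read_genotype_table()]; missing calls are written as `"--"`.
#'
#' @param gt a [genotype_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(gt, path) {
  m <- gt$calls
  m[is.na(m)] <- "--"
  df <- data.frame(individual_id = gt$individuals, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a pool-counts table
#'
#' Per-locus, per-ecotype allele counts for F_ST scanning of pooled
#' low-coverage data. For each group (WBL, WRL) a locus carries the number of
#' reads (or allele copies) supporting `allele_a` and `allele_b`, and the
#' number of individuals with at least one read (`n`).
#'
#' @param chromosome,position,allele_a,allele_b locus descriptors.
#' @param wbl_a,wbl_b,wbl_n,wrl_a,wrl_b,wrl_n non-negative integer counts.
#' @return a `data.frame` of class `"pool_counts"`.
#' @export
pool_counts <- function(chromosome, position, allele_a, allele_b,
                        wbl_a, wbl_b, wbl_n, wrl_a, wrl_b, wrl_n) {
  out <- data.frame(chromosome = as.character(chromosome),
                    position = as.integer(position),
                    allele_a = as.character(allele_a),
                    allele_b = as.character(allele_b),
                    wbl_a = as.integer(wbl_a), wbl_b = as.integer(wbl_b),
                    wbl_n = as.integer(wbl_n),
                    wrl_a = as.integer(wrl_a), wrl_b = as.integer(wrl_b),
                    wrl_n = as.integer(wrl_n), stringsAsFactors = FALSE)
  cnt <- as.matrix(out[, 5:10])
  if (anyNA(cnt) || any(cnt < 0L)) stop("pool_counts: counts must be non-negative")
  class(out) <- c("pool_counts", "data.frame")
  out
}

#' Read pool counts from a sync-style TSV
#'
#' One line per locus: chromosome, position, allele_a, allele_b, then one
#' `countA:countB:nInd` triple per group (WBL then WRL). Lines starting with
#' `#` are comments. A fully uncovered group is encoded `0:0:0`.
#'
#' @param path file to read.
#' @return a [pool_counts()] table keyed by (chromosome, position).
#' @examples
#' tf <- tempfile()
#' writeLines("chr2\t16333005\tA\tT\t10:2:6\t1:11:5", tf)
#' read_pool_counts(tf)
#' @export
read_pool_counts <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(pool_counts(character(), integer(), character(), character(),
                       integer(), integer(), integer(),
                       integer(), integer(), integer()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 6L))
    stop("pool-counts parse error at line ", lineno[which(nf != 6L)[1L]],
         ": expected 6 tab-separated fields, got ", nf[nf != 6L][1L])
  m <- do.call(rbind, fields)
  parse_triple <- function(x, col) {
    p <- strsplit(x, ":", fixed = TRUE)
    if (any(lengths(p) != 3L))
      stop("pool-counts parse error at line ",
           lineno[which(lengths(p) != 3L)[1L]], ": malformed triple '",
           x[lengths(p) != 3L][1L], "' (expected countA:countB:nInd)")
    v <- suppressWarnings(matrix(as.integer(unlist(p)), ncol = 3L, byrow = TRUE))
    if (anyNA(v) || any(v < 0L))
      stop("pool-counts parse error at line ",
           lineno[which(rowSums(is.na(v) | v < 0L) > 0L)[1L]],
           ": negative or non-integer count")
    v
  }
  wbl <- parse_triple(m[, 5L], 5L)
  wrl <- parse_triple(m[, 6L], 6L)
  pool_counts(m[, 1L], as.integer(m[, 2L]), m[, 3L], m[, 4L],
              wbl[, 1L], wbl[, 2L], wbl[, 3L],
              wrl[, 1L], wrl[, 2L], wrl[, 3L])
}

#' Write pool counts to a sync-style TSV
#'
#' @param pc a [pool_counts()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pool_counts <- function(pc, path) {
  lines <- paste(pc$chromosome, pc$position, pc$allele_a, pc$allele_b,
                 paste(pc$wbl_a, pc$wbl_b, pc$wbl_n, sep = ":"),
                 paste(pc$wrl_a, pc$wrl_b, pc$wrl_n, sep = ":"),
                 sep = "\t")
  writeLines(c("#chromosome\tposition\tallele_a\tallele_b\tWBL\tWRL", lines),
             path)
  invisible(path)
}

#' Read a locus table from TSV
#'
#' Columns: `locus_id`, `chromosome`, `position`, `allele_a`, `allele_b`.
#'
#' @param path file to read.
#' @return a [locus_table()].
#' @export
read_locus_table <- function(path) {
  df <- utils::read.delim(path, colClasses = "character")
  locus_table(df$locus_id, df$chromosome, as.integer(df$position),
              df$allele_a, df$allele_b)
}

#' Write a locus table to TSV
#' @param loci a [locus_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_locus_table <- function(loci, path) {
  utils::write.table(as.data.frame(loci), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a specimen metadata table from TSV
#'
#' Columns: `individual_id`, `collection_id`, `life_stage` (larva, juvenile,
#' adult, ocean-phase or unknown), `length_mm` (optional, `NA` allowed),
#' `morph_genus` (Entosphenus, Lampetra, unknown), `morph_ecotype`
#' (WBL, WRL, unknown). A specimen with a definitive morphological ecotype
#' must have `morph_genus == "Lampetra"`.
#'
#' @param path file to read.
#' @return a validated `data.frame`.
#' @export
read_specimen_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_specimens(df)
}

#' Validate specimen metadata
#' @param df a data.frame with the columns of [read_specimen_table()].
#' @return `df`, with `length_mm` coerced to numeric.
#' @export
validate_specimens <- function(df) {
  need <- c("individual_id", "collection_id", "life_stage", "morph_genus",
            "morph_ecotype")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("specimen table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$individual_id)) stop("duplicate individual_id in specimens")
  if (!all(df$life_stage %in% c("larva", "juvenile", "adult", "ocean-phase",
                                "unknown")))
    stop("specimen table: invalid life_stage value")
  if (!all(df$morph_genus %in% c("Entosphenus", "Lampetra", "unknown")))
    stop("specimen table: invalid morph_genus value")
  if (!all(df$morph_ecotype %in% c("WBL", "WRL", "unknown")))
    stop("specimen table: invalid morph_ecotype value")
  bad <- df$morph_ecotype != "unknown" & df$morph_genus != "Lampetra"
  if (any(bad))
    stop("specimen(s) with a definitive morph_ecotype but morph_genus != Lampetra: ",
         paste(df$individual_id[bad], collapse = ", "))
  if ("length_mm" %in% names(df)) df$length_mm <- as.numeric(df$length_mm)
  df
}

#' Read a collection metadata table from TSV
#'
#' Columns: `collection_id`, `site_code`, `region`, `years`, `rkm` (river
#' kilometres from the river mouth; `NA` allowed).
#'
#' @param path file to read.
#' @return a `data.frame`.
#' @export
read_collection_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (anyDuplicated(df$collection_id)) stop("duplicate collection_id")
  if ("rkm" %in% names(df)) {
    df$rkm <- as.numeric(df$rkm)
    if (any(!is.na(df$rkm) & df$rkm < 0)) stop("rkm must be non-negative")
  }
  df
}

#' Write pipeline result records
#'
#' Writes a result object to disk as TSV (for rectangular record lists such as
#' per-individual call records) or JSON (any result, preserving nested
#' metadata such as bootstrap seed/reps/level). `read_results()` inverts the
#' write, so `read_results(write_results(x))` reproduces `x`'s fields.
#'
#' @param records a `data.frame` (TSV or JSON) or a list (JSON only).
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(records))
      stop("TSV output requires a data.frame of records")
    utils::write.table(records, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    cls <- class(records)
    if (is.data.frame(records)) records <- as.data.frame(records)
    else if (is.list(records)) records <- unclass(records)
    jsonlite::write_json(list(class = cls, records = records), path,
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Read result records written by [write_results()]
#'
#' @param path file to read.
#' @param format `"tsv"` or `"json"`.
#' @return the stored records (`data.frame` for TSV; original structure for
#'   JSON, with the recorded class reattached).
#' @export
read_results <- function(path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv")
    return(utils::read.delim(path, stringsAsFactors = FALSE))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rec <- obj$records
  cls <- unlist(obj$class)
  if (!is.null(cls) && !identical(cls, "list") && !is.data.frame(rec))
    class(rec) <- cls
  rec
}
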