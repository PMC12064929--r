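#' Bundled example survey data
#'
#' Paths to the small plain-text datasets shipped with the package, drawn
#' from a published field survey of native lampreys in Northeastern Pacific
#' tributaries (lower Columbia River, Washington coast, Northern British
#' Columbia and the Georgia Basin):
#'
#' \describe{
#'   \item{`survey_collection_counts.tsv`}{Genetic-ID category counts for 24
#'     collections (15 sites, multiple years): *Entosphenus*, and *Lampetra*
#'     split into ecotype-unknown, WBL, Intermediate and WRL. Collection 1 is
#'     an ocean-phase WRL positive control; collections 2-24 are mixed
#'     tributary collections.}
#'   \item{`voucher_panel_calls.tsv`}{The 39 morphologically identified
#'     voucher specimens used to validate the 5-SNP ecotype panel: life
#'     stage, length, morphological ecotype and percent WRL alleles (`NA`
#'     where too few panel SNPs genotyped).}
#'   \item{`genus_id_crosstab.tsv`}{Grand cross-tabulation of genetic against
#'     morphological genus IDs for 1170 photographed specimens (long format:
#'     `genetic`, `morph`, `count`).}
#'   \item{`ecotype_id_crosstab.tsv`}{Grand cross-tabulation of genetic
#'     against morphological *Lampetra* ecotype IDs for 514 specimens (long
#'     format: `genetic`, `morph`, `count`).}
#' }
#'
#' @param file file name, or `NULL` (default) to list the available files.
#' @return a file path, or a character vector of file names.
#' @examples
#' lampid_example()
#' counts <- read.delim(lampid_example("survey_collection_counts.tsv"))
#' @export
lampid_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "lampid")))
  path <- system.file("extdata", file, package = "lampid")
  if (path == "") stop("no such example file: ", file)
  path
}
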