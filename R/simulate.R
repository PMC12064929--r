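#' Synthetic-population configuration
#'
#' Parameters of the generator that emulates the statistical structure the
#' scan and classifier assume: one panmictic population containing two
#' ecotypes that differ only at a few narrow chromosomal islands of strongly
#' divergent allele frequencies, on a near-zero-F_ST genomic background;
#' per-individual low-coverage read sampling; amplicon-panel genotypes with
#' missingness; and morphological labels with an unknown larval fraction and
#' a small error rate.
#'
#' Background loci draw a common ancestral frequency from Uniform(0.05, 0.95)
#' and then per-ecotype frequencies from a Balding-Nichols beta distribution
#' calibrated so that the mean per-locus value of the package's two-group
#' F_ST estimator equals `background_fst`. Island loci get frequency pairs
#' with `|p_wrl - p_wbl| = delta`, centred at 0.5, identical for all loci in
#' an island, with the high-frequency ecotype chosen at random per island.
#'
#' @param n_chromosomes number of chromosomes (default 20).
#' @param loci_per_chromosome SNPs per chromosome (default 2000).
#' @param chromosome_length_bp chromosome length (default 2e7).
#' @param background_fst target background differentiation in `[0, 0.05]`
#'   (default 0.01).
#' @param islands `data.frame` with columns `chromosome`, `start_bp`,
#'   `end_bp`, `delta` (frequency differential in `[0, 1]`). Default: six
#'   islands on chromosomes 2 (narrow, high delta), 5, 6, 12, 14 and 17,
#'   mirroring a multi-chromosome island architecture.
#' @param n_wbl,n_wrl voucher sample sizes (defaults 24 and 15).
#' @param mean_depth mean per-individual read depth (default 3).
#' @param panel_missing_rate amplicon dropout probability (default 0.03).
#' @param morph_unknown_rate probability a specimen is an unidentifiable
#'   larva, hence morphological ecotype `unknown` (default 0.45).
#' @param morph_error_rate probability a definitive morphological label is
#'   flipped (default 0.02).
#' @param seed integer seed.
#' @return a list of class `"sim_config"`.
#' @export
sim_config <- function(n_chromosomes = 20L, loci_per_chromosome = 2000L,
                       chromosome_length_bp = 2e7, background_fst = 0.01,
                       islands = NULL, n_wbl = 24L, n_wrl = 15L,
                       mean_depth = 3, panel_missing_rate = 0.03,
                       morph_unknown_rate = 0.45, morph_error_rate = 0.02,
                       seed = 1L) {
  if (is.null(islands)) {
    islands <- default_islands(chromosome_length_bp)
    # with few chromosomes, keep only the islands that fit
    islands <- islands[as.integer(islands$chromosome) <= n_chromosomes, ,
                       drop = FALSE]
    if (!nrow(islands))
      stop("sim_config: no default island fits n_chromosomes = ", n_chromosomes,
           "; supply islands explicitly")
  }
  islands <- as.data.frame(islands)
  stopifnot(all(c("chromosome", "start_bp", "end_bp", "delta") %in% names(islands)))
  islands$chromosome <- as.character(islands$chromosome)
  if (background_fst < 0 || background_fst > 0.05)
    stop("sim_config: background_fst must lie in [0, 0.05]")
  rates <- c(panel_missing_rate, morph_unknown_rate, morph_error_rate)
  if (any(rates < 0 | rates > 1)) stop("sim_config: rates must lie in [0, 1]")
  if (any(islands$delta < 0 | islands$delta > 1))
    stop("sim_config: island delta must lie in [0, 1]")
  if (any(islands$start_bp < 1 | islands$end_bp > chromosome_length_bp |
          islands$start_bp >= islands$end_bp))
    stop("sim_config: islands must lie within chromosome bounds")
  if (!all(islands$chromosome %in% as.character(seq_len(n_chromosomes))))
    stop("sim_config: island chromosome outside 1..n_chromosomes")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 loci_per_chromosome = as.integer(loci_per_chromosome),
                 chromosome_length_bp = chromosome_length_bp,
                 background_fst = background_fst, islands = islands,
                 n_wbl = as.integer(n_wbl), n_wrl = as.integer(n_wrl),
                 mean_depth = mean_depth,
                 panel_missing_rate = panel_missing_rate,
                 morph_unknown_rate = morph_unknown_rate,
                 morph_error_rate = morph_error_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default island architecture
#'
#' Six genomic islands of divergence: a narrow, nearly fixed island on
#' chromosome 2 and broader, less extreme islands on chromosomes 5, 6, 12,
#' 14 and 17. Coordinates scale with chromosome length.
#'
#' @param chromosome_length_bp chromosome length the islands must fit in.
#' @return an island `data.frame` (see [sim_config()]).
#' @export
default_islands <- function(chromosome_length_bp = 2e7) {
  L <- chromosome_length_bp
  data.frame(
    chromosome = c("2", "5", "6", "12", "14", "17"),
    start_bp = round(c(0.80, 0.23, 0.05, 0.30, 0.20, 0.55) * L),
    end_bp   = round(c(0.802, 0.24, 0.06, 0.315, 0.21, 0.565) * L),
    delta    = c(0.95, 0.85, 0.70, 0.85, 0.80, 0.70),
    stringsAsFactors = FALSE)
}

#' Simulate per-locus ecotype allele frequencies
#'
#' @param config a [sim_config()].
#' @return a list of class `"sim_freqs"`: `loci` (a [locus_table()], sorted by
#'   chromosome block then position), `p_wbl`, `p_wrl` (allele_b frequencies),
#'   `island` (island row index or `NA` for background loci).
#' @export
simulate_allele_frequencies <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  chroms <- as.character(seq_len(config$n_chromosomes))
  n_per <- config$loci_per_chromosome
  chromosome <- rep(chroms, each = n_per)
  position <- unlist(lapply(chroms, function(ch)
    sort(sample.int(config$chromosome_length_bp, n_per))), use.names = FALSE)
  n <- length(position)
  bases <- c("A", "C", "G", "T")
  a_idx <- sample.int(4L, n, replace = TRUE)
  b_off <- sample.int(3L, n, replace = TRUE)
  allele_a <- bases[a_idx]
  allele_b <- bases[((a_idx - 1L + b_off) %% 4L) + 1L]
  loci <- locus_table(locus_name(chromosome, position), chromosome, position,
                      allele_a, allele_b)
  # background: Balding-Nichols with per-group parameter 2*F so the two-group
  # Nei estimator averages to background_fst
  anc <- stats::runif(n, 0.05, 0.95)
  Fc <- 2 * config$background_fst
  if (Fc > 0) {
    shape1 <- anc * (1 - Fc) / Fc
    shape2 <- (1 - anc) * (1 - Fc) / Fc
    p_wbl <- stats::rbeta(n, shape1, shape2)
    p_wrl <- stats::rbeta(n, shape1, shape2)
  } else {
    p_wbl <- p_wrl <- anc
  }
  island <- rep(NA_integer_, n)
  isl <- config$islands
  for (k in seq_len(nrow(isl))) {
    hit <- chromosome == isl$chromosome[k] & position >= isl$start_bp[k] &
      position <= isl$end_bp[k]
    if (!any(hit)) next
    island[hit] <- k
    d <- isl$delta[k]
    lo <- 0.5 - d / 2; hi <- 0.5 + d / 2
    if (lo < 0 || hi > 1) {  # cannot occur with centring at 0.5 and d <= 1
      warning("island ", k, ": frequency pair clipped to [0, 1]")
      lo <- max(0, lo); hi <- min(1, hi)
    }
    if (stats::runif(1) < 0.5) { p_wbl[hit] <- lo; p_wrl[hit] <- hi }
    else { p_wbl[hit] <- hi; p_wrl[hit] <- lo }
  }
  structure(list(loci = loci, p_wbl = p_wbl, p_wrl = p_wrl, island = island),
            class = "sim_freqs")
}

#' Simulate individual genotypes under within-ecotype panmixia
#'
#' Each individual's genotype at each locus is two independent
#' Bernoulli(p_group) draws of `allele_b` (Hardy-Weinberg sampling within
#' ecotype).
#'
#' @param freqs a `"sim_freqs"` object (or any list with `loci`, `p_wbl`,
#'   `p_wrl`).
#' @param n_wbl,n_wrl individuals per ecotype (must be positive).
#' @param seed integer seed.
#' @return a list: `genotypes` (a [genotype_table()]), `labels` (ground-truth
#'   ecotype per individual).
#' @export
simulate_individuals <- function(freqs, n_wbl, n_wrl, seed = 1L) {
  if (n_wbl <= 0L || n_wrl <= 0L)
    stop("simulate_individuals: group sizes must be positive")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  loci <- freqs$loci
  n_loc <- nrow(loci)
  labels <- c(rep("WBL", n_wbl), rep("WRL", n_wrl))
  ids <- sprintf("%s_%03d", tolower(labels), c(seq_len(n_wbl), seq_len(n_wrl)))
  p <- rbind(matrix(freqs$p_wbl, n_wbl, n_loc, byrow = TRUE),
             matrix(freqs$p_wrl, n_wrl, n_loc, byrow = TRUE))
  n_tot <- n_wbl + n_wrl
  dos <- matrix(stats::rbinom(n_tot * n_loc, 2L, p), n_tot, n_loc)
  calls <- .dosage_to_calls(dos, loci)
  rownames(calls) <- ids
  list(genotypes = genotype_table(calls, loci, ids), labels = labels)
}

# internal: dosage of allele_b (0/1/2, NA) -> normalised call strings
.dosage_to_calls <- function(dos, loci) {
  n_loc <- nrow(loci)
  calls <- matrix(NA_character_, nrow(dos), n_loc)
  for (j in seq_len(n_loc)) {
    a <- loci$allele_a[j]; b <- loci$allele_b[j]
    hom_a <- paste0(a, a); hom_b <- paste0(b, b)
    het <- paste0(min(a, b), max(a, b))
    calls[, j] <- c(hom_a, het, hom_b)[dos[, j] + 1L]
  }
  calls
}

#' Simulate pooled low-coverage read counts from genotypes
#'
#' Per individual and locus, read depth is Poisson(`mean_depth`) and reads of
#' `allele_b` are Binomial(depth, dosage/2). Group counts sum over
#' individuals; `n_ind_covered` counts individuals with depth >= 1.
#'
#' @param sim output of [simulate_individuals()] (or a list with `genotypes`
#'   and `labels`).
#' @param mean_depth mean per-individual depth (> 0).
#' @param seed integer seed.
#' @return a [pool_counts()] table.
#' @export
simulate_pool_counts <- function(sim, mean_depth = 3, seed = 1L) {
  if (mean_depth <= 0) stop("simulate_pool_counts: mean_depth must be > 0")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  gt <- sim$genotypes
  labels <- sim$labels
  dos <- allele_dosage(gt, "b")
  n_ind <- nrow(dos); n_loc <- ncol(dos)
  depth <- matrix(stats::rpois(n_ind * n_loc, mean_depth), n_ind, n_loc)
  reads_b <- matrix(stats::rbinom(n_ind * n_loc, depth, dos / 2), n_ind, n_loc)
  reads_a <- depth - reads_b
  grp <- function(rows, m) colSums(m[rows, , drop = FALSE])
  w <- labels == "WBL"; r <- labels == "WRL"
  pool_counts(gt$loci$chromosome, gt$loci$position, gt$loci$allele_a,
              gt$loci$allele_b,
              grp(w, reads_a), grp(w, reads_b), grp(w, depth >= 1L),
              grp(r, reads_a), grp(r, reads_b), grp(r, depth >= 1L))
}

#' Degrade an amplicon panel with random dropout
#'
#' Sets each (individual, panel locus) call to missing independently with
#' probability `missing_rate`; loci outside `panel_loci` are untouched.
#'
#' @param gt a [genotype_table()].
#' @param panel_loci locus_ids to degrade (default: all loci).
#' @param missing_rate dropout probability in `[0, 1]`.
#' @param seed integer seed.
#' @return a [genotype_table()].
#' @export
degrade_panel <- function(gt, panel_loci = NULL, missing_rate = 0.03,
                          seed = 1L) {
  if (missing_rate < 0 || missing_rate > 1)
    stop("degrade_panel: missing_rate must lie in [0, 1]")
  if (is.null(panel_loci)) panel_loci <- gt$loci$locus_id
  j <- match(panel_loci, gt$loci$locus_id)
  if (anyNA(j)) stop("degrade_panel: unknown panel locus")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  calls <- gt$calls
  drop <- matrix(stats::runif(nrow(calls) * length(j)) < missing_rate,
                 nrow(calls), length(j))
  calls[, j][drop] <- NA_character_
  genotype_table(calls, gt$loci, gt$individuals)
}

#' Genus marker loci
#'
#' The two redundant genus-diagnostic amplicons: LampSD_478 (G/A) and
#' LampSD_700 (G/T). Positions are nominal (the markers are assayed, not
#' scanned).
#'
#' @return a [locus_table()] of the two markers.
#' @export
genus_marker_loci <- function() {
  locus_table(c("LampSD_478", "LampSD_700"), c("gmk1", "gmk2"), c(478L, 700L),
              c("G", "G"), c("A", "T"))
}

#' Simulate mixed-lamprey collections with noisy morphological labels
#'
#' Draws individuals from per-collection genus and ecotype mixtures.
#' *Entosphenus* individuals carry the *Entosphenus*-diagnostic homozygous
#' genotypes at the two genus markers and no calls at the ecotype panel;
#' *Lampetra* individuals carry *Lampetra*-diagnostic genus genotypes (the
#' genera show fixed differences) and Hardy-Weinberg panel genotypes from
#' their true ecotype's allele frequencies. Morphological ecotype labels are
#' `unknown` for larvae — a fraction `morph_unknown_rate` of each collection —
#' and otherwise flipped with probability `morph_error_rate`; morphological
#' genus labels are flipped with the same error rate.
#'
#' @param collections `data.frame` with columns `collection_id`, `n`,
#'   `p_entosphenus`, `p_lampetra` (must sum to 1 per row), `p_wbl`, `p_wrl`
#'   (ecotype mixture among *Lampetra*, must sum to 1), and optionally `rkm`.
#' @param panel_freqs a list with `loci` (a [locus_table()] of panel SNPs),
#'   `p_wbl`, `p_wrl` — e.g. a `"sim_freqs"` object subset to the panel loci.
#' @param morph_unknown_rate larval (morphologically unidentifiable) fraction.
#' @param morph_error_rate morphological misidentification probability.
#' @param panel_missing_rate amplicon dropout probability applied to all loci.
#' @param seed integer seed.
#' @return a list: `specimens` (metadata incl. morphological labels),
#'   `genotypes` (a [genotype_table()] over genus markers + panel loci),
#'   `truth` (`data.frame` with ground-truth `genus` and `ecotype`).
#' @export
simulate_collections <- function(collections, panel_freqs,
                                 morph_unknown_rate = 0.45,
                                 morph_error_rate = 0.02,
                                 panel_missing_rate = 0.03, seed = 1L) {
  collections <- as.data.frame(collections)
  need <- c("collection_id", "n", "p_entosphenus", "p_lampetra", "p_wbl", "p_wrl")
  miss <- setdiff(need, names(collections))
  if (length(miss)) stop("simulate_collections: missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(abs(collections$p_entosphenus + collections$p_lampetra - 1) > 1e-9))
    stop("simulate_collections: genus mixture must sum to 1")
  if (any(abs(collections$p_wbl + collections$p_wrl - 1) > 1e-9))
    stop("simulate_collections: ecotype mixture must sum to 1")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  gloci <- genus_marker_loci()
  ploci <- panel_freqs$loci
  loci <- locus_table(c(gloci$locus_id, ploci$locus_id),
                      c(gloci$chromosome, ploci$chromosome),
                      c(gloci$position, ploci$position),
                      c(gloci$allele_a, ploci$allele_a),
                      c(gloci$allele_b, ploci$allele_b))
  specs <- list(); truths <- list(); call_rows <- list()
  for (i in seq_len(nrow(collections))) {
    cc <- collections[i, ]
    n <- cc$n
    genus <- sample(c("Entosphenus", "Lampetra"), n, replace = TRUE,
                    prob = c(cc$p_entosphenus, cc$p_lampetra))
    eco <- rep(NA_character_, n)
    lam <- genus == "Lampetra"
    eco[lam] <- sample(c("WBL", "WRL"), sum(lam), replace = TRUE,
                       prob = c(cc$p_wbl, cc$p_wrl))
    ids <- sprintf("%s_%04d", cc$collection_id, seq_len(n))
    # genus markers: fixed differences (allele_a = G is the Entosphenus allele)
    g478 <- ifelse(genus == "Entosphenus", "GG", "AA")
    g700 <- ifelse(genus == "Entosphenus", "GG", "TT")
    pcalls <- matrix(NA_character_, n, nrow(ploci))
    if (any(lam)) {
      p <- ifelse(eco[lam] == "WBL", 1, 0)  # row selector below
      pm <- matrix(NA_real_, sum(lam), nrow(ploci))
      if (any(p == 1))
        pm[p == 1, ] <- matrix(panel_freqs$p_wbl, sum(p == 1), nrow(ploci),
                               byrow = TRUE)
      if (any(p == 0))
        pm[p == 0, ] <- matrix(panel_freqs$p_wrl, sum(p == 0), nrow(ploci),
                               byrow = TRUE)
      dos <- matrix(stats::rbinom(length(pm), 2L, pm), nrow(pm), ncol(pm))
      pcalls[lam, ] <- .dosage_to_calls(dos, ploci)
    }
    calls <- cbind(g478, g700, pcalls)
    rownames(calls) <- ids
    # morphological labels
    larva <- stats::runif(n) < morph_unknown_rate
    flip_g <- stats::runif(n) < morph_error_rate
    morph_genus <- ifelse(flip_g,
                          ifelse(genus == "Entosphenus", "Lampetra", "Entosphenus"),
                          genus)
    flip_e <- stats::runif(n) < morph_error_rate
    morph_eco <- ifelse(is.na(eco), "unknown",
                        ifelse(flip_e, ifelse(eco == "WBL", "WRL", "WBL"), eco))
    morph_eco[larva] <- "unknown"
    # a definitive ecotype label implies a Lampetra genus label
    morph_eco[morph_genus != "Lampetra"] <- "unknown"
    specs[[i]] <- data.frame(
      individual_id = ids, collection_id = cc$collection_id,
      life_stage = ifelse(larva, "larva", "adult"),
      length_mm = NA_real_,
      morph_genus = morph_genus, morph_ecotype = morph_eco,
      rkm = if ("rkm" %in% names(cc)) cc$rkm else NA_real_,
      stringsAsFactors = FALSE)
    truths[[i]] <- data.frame(individual_id = ids, genus = genus,
                              ecotype = ifelse(is.na(eco), "none", eco),
                              stringsAsFactors = FALSE)
    call_rows[[i]] <- calls
  }
  all_calls <- do.call(rbind, call_rows)
  gt <- genotype_table(all_calls, loci, rownames(all_calls))
  gt <- degrade_panel(gt, loci$locus_id, panel_missing_rate,
                      seed = seed + 1L)
  list(specimens = do.call(rbind, specs), genotypes = gt,
       truth = do.call(rbind, truths))
}
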