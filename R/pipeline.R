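#' Run the end-to-end synthetic discovery-and-survey pipeline
#'
#' Executes the full chain on generated data: simulate a two-ecotype
#' population and voucher specimens, pool their reads, run the F_ST genome
#' scan ([ecotype_scan()]), fit the diagnostic panel from voucher amplicon
#' genotypes ([ecotype_panel()]), simulate mixed survey collections, classify
#' every specimen ([classify_specimens()]), audit genetic-vs-morphological
#' concordance, and estimate per-collection compositions with bootstrap CIs
#' plus a Mantel test of river-distance against WRL-allele frequency.
#' Deterministic given the configured seed.
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognised top-level fields (all optional): `seed`; `sim` (arguments
#'   of [sim_config()]); `scan` (arguments of [scan_config()]); `collections`
#'   (rows for [simulate_collections()], incl. `rkm`); `bootstrap` (`n_boot`,
#'   `ci_level`); `mantel` (`n_perm`); `out_dir` (directory to write TSV/JSON
#'   outputs into).
#' @return (invisibly) a list of class `"lampid_pipeline"` with elements
#'   `scan`, `panel`, `records`, `specimens`, `truth`, `genus_concordance`,
#'   `ecotype_concordance`, `composition` (per collection, both bases, with
#'   CIs), `mantel`, `summary` (the machine-readable summary also written to
#'   `out_dir/summary.json` when `out_dir` is set).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("run_pipeline: config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  seed <- as.integer(config$seed %||% 1L)
  sim_args <- config$sim %||% list()
  sim_args$seed <- seed
  # survey-scale defaults keep the run light; see the methods vignette
  sim_args$n_chromosomes <- sim_args$n_chromosomes %||% 8L
  sim_args$loci_per_chromosome <- sim_args$loci_per_chromosome %||% 500L
  cfg <- do.call(sim_config, sim_args)
  scn_args <- config$scan %||% list()
  scn_args$n_candidates <- scn_args$n_candidates %||% 12L
  scn <- do.call(scan_config, scn_args)
  collections <- as.data.frame(config$collections %||% default_survey())
  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(dirname(out_dir)))
    stop("run_pipeline: parent of out_dir does not exist: ", out_dir)

  freqs <- simulate_allele_frequencies(cfg)
  vouchers <- simulate_individuals(freqs, cfg$n_wbl, cfg$n_wrl, seed + 1L)
  pools <- simulate_pool_counts(vouchers, cfg$mean_depth, seed + 2L)
  scan <- ecotype_scan(pools, scn)
  cand <- scan$candidates$candidates
  if (!nrow(cand)) stop("run_pipeline: scan produced no candidate SNPs")
  cand_ids <- locus_name(cand$chromosome, cand$position)
  keep <- match(cand_ids, freqs$loci$locus_id)
  panel_gt <- degrade_panel(vouchers$genotypes[, keep],
                            missing_rate = cfg$panel_missing_rate,
                            seed = seed + 3L)
  fit <- ecotype_panel(panel_gt, vouchers$labels, panel_size = scn$panel_size)
  pk <- match(fit$panel$locus_id, freqs$loci$locus_id)
  panel_freqs <- list(loci = freqs$loci[pk, , drop = FALSE],
                      p_wbl = freqs$p_wbl[pk], p_wrl = freqs$p_wrl[pk])
  class(panel_freqs$loci) <- c("locus_table", "data.frame")
  survey <- simulate_collections(collections, panel_freqs,
                                 morph_unknown_rate = cfg$morph_unknown_rate,
                                 morph_error_rate = cfg$morph_error_rate,
                                 panel_missing_rate = cfg$panel_missing_rate,
                                 seed = seed + 4L)
  records <- classify_specimens(survey$genotypes, fit)
  records$collection_id <- survey$specimens$collection_id

  gcon <- genus_concordance(records$genus, survey$specimens$morph_genus)
  lam <- records$genus == "Lampetra"
  econ <- ecotype_concordance(records$ecotype[lam],
                              survey$specimens$morph_ecotype[lam])

  boot <- config$bootstrap %||% list()
  n_boot <- as.integer(boot$n_boot %||% 10000L)
  ci_level <- boot$ci_level %||% 0.99
  comp <- lapply(split(records, records$collection_id), function(rc) {
    lapply(c(genus = "genus", ecotype = "ecotype"), function(b) {
      pt <- composition(rc, b)
      if (pt$n > 0) bootstrap_ci(pt, n_boot, ci_level, seed + 5L) else pt
    })
  })

  mnt <- NULL
  if ("rkm" %in% names(collections) && nrow(collections) >= 3L) {
    by_col <- split(records[lam, ], records$collection_id[lam])
    f <- vapply(by_col, function(rc) {
      tot <- sum(rc$n_alleles_typed)
      if (is.finite(tot) && tot > 0) sum(rc$n_wrl_alleles) / tot else NA_real_
    }, 0)
    rkm <- collections$rkm[match(names(f), collections$collection_id)]
    ok <- !is.na(f) & !is.na(rkm)
    if (sum(ok) >= 3L && stats::sd(f[ok]) > 0 && stats::sd(rkm[ok]) > 0) {
      dr <- abs(outer(rkm[ok], rkm[ok], "-"))
      df <- abs(outer(f[ok], f[ok], "-"))
      n_perm <- as.integer((config$mantel %||% list())$n_perm %||% 9999L)
      mnt <- mantel_test(dr, df, n_perm = n_perm, seed = seed + 6L)
    }
  }

  summary_list <- list(
    seed = seed,
    scan = list(n_snps = scan$n_retained, n_high = scan$high$n_high,
                realized_quantile = scan$high$realized_quantile,
                enriched = as.list(scan$enrichment$enriched),
                coverage = scan$enrichment$coverage,
                n_candidates = nrow(cand)),
    panel = list(loci = fit$panel$locus_id, fst = fit$panel$fst,
                 required_chromosome = fit$required_chromosome),
    classification = list(n = nrow(records),
                          genus = as.list(table(records$genus)),
                          ecotype = as.list(table(records$ecotype[lam]))),
    concordance = list(genus_overall = gcon$overall$rate,
                       ecotype_definitive = econ$definitive$rate),
    composition = lapply(comp, function(cl) lapply(cl, function(e) {
      if (inherits(e, "composition_estimate"))
        list(proportions = as.list(e$proportions),
             ci_lower = as.list(e$ci["lower", ]),
             ci_upper = as.list(e$ci["upper", ]),
             n = e$n, n_boot = e$n_boot, ci_level = e$ci_level, seed = e$seed)
      else list(proportions = as.list(e$proportions), n = e$n)
    })),
    mantel = if (!is.null(mnt)) list(r = mnt$r, p = mnt$p,
                                     n_perm = mnt$n_perm) else NULL)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_results(scan$snp_fst, file.path(out_dir, "snp_fst.tsv"))
    write_results(scan$windows, file.path(out_dir, "windows.tsv"))
    write_results(fit$panel, file.path(out_dir, "panel.tsv"))
    write_results(records, file.path(out_dir, "call_records.tsv"))
    write_results(survey$specimens, file.path(out_dir, "specimens.tsv"))
    jsonlite::write_json(summary_list, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null", na = "null")
  }
  invisible(structure(list(scan = scan, panel = fit, records = records,
                           specimens = survey$specimens, truth = survey$truth,
                           genus_concordance = gcon,
                           ecotype_concordance = econ,
                           composition = comp, mantel = mnt,
                           summary = summary_list),
                      class = "lampid_pipeline"))
}

#' Default synthetic survey design
#'
#' Four mixed collections along a river gradient: genus mixtures vary
#' strongly between sites while ecotype mixtures shift gradually with
#' distance from the river mouth.
#'
#' @return a collections `data.frame` for [simulate_collections()].
#' @export
default_survey <- function() {
  data.frame(
    collection_id = c("EST01", "MID01", "MID02", "UPP01"),
    n = c(150L, 120L, 120L, 100L),
    p_entosphenus = c(0.55, 0.40, 0.20, 0.70),
    p_lampetra = c(0.45, 0.60, 0.80, 0.30),
    p_wbl = c(0.60, 0.85, 0.90, 0.97),
    p_wrl = c(0.40, 0.15, 0.10, 0.03),
    rkm = c(15, 80, 120, 250),
    stringsAsFactors = FALSE)
}

#' @export
print.lampid_pipeline <- function(x, ...) {
  cat("lampid pipeline run\n")
  print(x$scan)
  print(x$panel)
  cat(sprintf("genus concordance: %.1f%%; ecotype concordance (definitive): %.1f%%\n",
              100 * x$genus_concordance$overall$rate,
              100 * x$ecotype_concordance$definitive$rate))
  if (!is.null(x$mantel)) print(x$mantel)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
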