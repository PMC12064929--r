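#' Scan configuration
#'
#' Bundles the tunable parameters of the pooled-sequencing F_ST genome scan.
#' Defaults follow the marker-discovery design this package implements:
#' 10 kb windows stepping 5 kb, a minimum of four covered individuals per
#' ecotype pool at a site, an absolute high-F_ST threshold of 0.500 (the
#' empirical quantile of that threshold is reported alongside), chromosomes
#' counted as enriched when they carry more than 1% of all high-F_ST SNPs,
#' 47 candidate assays, and a final panel of 5 SNPs.
#'
#' @param window window width in bp (default 10000).
#' @param step window step in bp (default 5000); must not exceed `window`.
#' @param min_ind_per_group coverage filter threshold (default 4).
#' @param high_fst_abs absolute F_ST cutoff defining "high" SNPs (default 0.5).
#' @param high_fst_quantile reference quantile reported for context
#'   (default 0.997).
#' @param enrichment_share chromosome share of high-F_ST SNPs above which a
#'   chromosome counts as enriched (default 0.01, strict inequality).
#' @param n_candidates number of candidate assays to allocate (default 47).
#' @param panel_size number of SNPs in the final panel (default 5).
#' @return a list of class `"scan_config"`.
#' @export
scan_config <- function(window = 10000L, step = 5000L, min_ind_per_group = 4L,
                        high_fst_abs = 0.5, high_fst_quantile = 0.997,
                        enrichment_share = 0.01, n_candidates = 47L,
                        panel_size = 5L) {
  if (step > window) stop("scan_config: step must be <= window")
  if (high_fst_abs <= 0 || high_fst_abs >= 1)
    stop("scan_config: high_fst_abs must lie in (0, 1)")
  if (enrichment_share <= 0 || enrichment_share >= 1)
    stop("scan_config: enrichment_share must lie in (0, 1)")
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_ind_per_group = as.integer(min_ind_per_group),
                 high_fst_abs = high_fst_abs,
                 high_fst_quantile = high_fst_quantile,
                 enrichment_share = enrichment_share,
                 n_candidates = as.integer(n_candidates),
                 panel_size = as.integer(panel_size)),
            class = "scan_config")
}

#' Sliding-window F_ST summary
#'
#' Windows are anchored at position 1 on every chromosome, with starts
#' 1, 1+s, 1+2s, ... and half-open extents `[start, start + W)`. Only windows
#' containing at least one defined-F_ST SNP are emitted; `mean_fst` is the
#' arithmetic mean over member SNPs. At defaults every interior SNP belongs to
#' exactly `ceiling(W/s)` (= 2) windows; SNPs within `W` of a chromosome start
#' belong to fewer.
#'
#' @param snp_fsts a `data.frame` with columns `chromosome`, `position`,
#'   `fst` (e.g. from [pool_allele_freqs()]), sorted by chromosome then
#'   position. Rows with `NA` F_ST are ignored.
#' @param window window width W in bp.
#' @param step step s in bp.
#' @return a `data.frame` with columns `chromosome`, `start` (1-based
#'   inclusive), `end` (exclusive, `start + window`), `n_snps`, `mean_fst`.
#' @export
sliding_windows <- function(snp_fsts, window = 10000L, step = 5000L) {
  if (step > window) stop("sliding_windows: step must be <= window")
  x <- snp_fsts[!is.na(snp_fsts$fst), , drop = FALSE]
  # chromosomes must form contiguous blocks with non-decreasing positions
  if (any(duplicated(rle(x$chromosome)$values)) ||
      any(vapply(split(x$position, x$chromosome), is.unsorted, TRUE)))
    stop("sliding_windows: input must be sorted by (chromosome, position)")
  if (!nrow(x))
    return(data.frame(chromosome = character(), start = integer(),
                      end = integer(), n_snps = integer(),
                      mean_fst = numeric(), stringsAsFactors = FALSE))
  # window start index k (start = 1 + k*step) covers pos iff
  # k in [ceil((pos - window)/step), floor((pos - 1)/step)], k >= 0
  kmax <- floor((x$position - 1) / step)
  kmin <- pmax(0L, ceiling((x$position - window) / step))
  reps <- kmax - kmin + 1L
  k <- unlist(mapply(seq.int, kmin, kmax, SIMPLIFY = FALSE), use.names = FALSE)
  chr <- rep(x$chromosome, reps)
  fst <- rep(x$fst, reps)
  key <- paste(chr, k, sep = "\r")
  n <- tapply(fst, key, length)
  mu <- tapply(fst, key, mean)
  parts <- strsplit(names(n), "\r", fixed = TRUE)
  out <- data.frame(chromosome = vapply(parts, `[`, "", 1L),
                    start = 1L + as.integer(vapply(parts, `[`, "", 2L)) * step,
                    n_snps = as.integer(n), mean_fst = as.numeric(mu),
                    stringsAsFactors = FALSE)
  out$end <- out$start + as.integer(window)
  out <- out[order(out$chromosome, out$start),
             c("chromosome", "start", "end", "n_snps", "mean_fst")]
  rownames(out) <- NULL
  out
}

#' High-F_ST SNP set
#'
#' Selects SNPs with F_ST strictly above an absolute threshold and reports the
#' threshold's empirical quantile in the defined-F_ST distribution (so the
#' 0.500 cutoff can be compared with, e.g., the 99.7th percentile).
#'
#' @param snp_fsts a `data.frame` with at least `locus_id` and `fst`.
#' @param abs_threshold absolute F_ST cutoff (default 0.5).
#' @return a list with elements `snps` (the qualifying rows), `n_high`,
#'   `realized_quantile` (fraction of defined-F_ST SNPs at or below the
#'   threshold; `NA` when there are no defined SNPs).
#' @export
high_fst_snps <- function(snp_fsts, abs_threshold = 0.5) {
  def <- snp_fsts[!is.na(snp_fsts$fst), , drop = FALSE]
  high <- def[def$fst > abs_threshold, , drop = FALSE]
  rq <- if (nrow(def)) mean(def$fst <= abs_threshold) else NA_real_
  list(snps = high, n_high = nrow(high), realized_quantile = rq)
}

#' Chromosome enrichment of high-F_ST SNPs
#'
#' A chromosome is enriched when its share of the high-F_ST SNP set strictly
#' exceeds `enrichment_share`. Also reports what fraction of all high-F_ST
#' SNPs the enriched chromosomes jointly contain.
#'
#' @param high_snps `data.frame` of high-F_ST SNPs (needs `chromosome`).
#' @param enrichment_share share threshold (default 0.01).
#' @return a list with `shares` (named share per chromosome, decreasing),
#'   `enriched` (chromosome names), `coverage` (fraction of high SNPs on
#'   enriched chromosomes; `NA` when the set is empty).
#' @export
chromosome_enrichment <- function(high_snps, enrichment_share = 0.01) {
  if (!nrow(high_snps))
    return(list(shares = numeric(), enriched = character(), coverage = NA_real_))
  tab <- table(high_snps$chromosome)
  shares <- sort(as.numeric(tab) / sum(tab), decreasing = TRUE)
  names(shares) <- names(sort(tab, decreasing = TRUE))
  enriched <- names(shares)[shares > enrichment_share]
  coverage <- sum(shares[enriched])
  list(shares = shares, enriched = enriched, coverage = coverage)
}

# internal: allocate n items across chromosomes proportionally to counts,
# with a floor of 2 per chromosome (when n allows) and largest-remainder
# rounding of the remainder; allocations are capped at availability.
.allocate_candidates <- function(counts, n) {
  k <- length(counts)
  stopifnot(k >= 1L)
  base <- if (n >= 2L * k) rep(2L, k) else rep(0L, k)
  base <- pmin(base, counts)
  left <- n - sum(base)
  room <- counts - base
  share <- counts / sum(counts)
  while (left > 0L && any(room > 0L)) {
    quota <- left * share
    add <- pmin(floor(quota), room)
    rem <- quota - floor(quota)
    rem[room - add <= 0L] <- -Inf
    left2 <- left - sum(add)
    # distribute the remainder one by one, largest remainder first,
    # ties broken by larger count then original order
    ord <- order(-rem, -counts, seq_along(counts))
    for (i in ord) {
      if (left2 <= 0L) break
      if (room[i] - add[i] > 0L) { add[i] <- add[i] + 1L; left2 <- left2 - 1L }
    }
    base <- base + add
    left <- n - sum(base)
    room <- counts - base
    if (all(add == 0L)) break
  }
  base
}

#' Select candidate assay SNPs from the high-F_ST set
#'
#' Allocates `n_candidates` across the enriched chromosomes proportionally to
#' their high-F_ST SNP counts (floor of 2 assays per included chromosome when
#' the budget allows, largest-remainder rounding), then picks the highest-F_ST
#' SNPs within each chromosome, breaking F_ST ties by smaller position.
#' Reports the mean and range of distances between neighbouring candidates on
#' the same chromosome.
#'
#' @param high_snps `data.frame` of high-F_ST SNPs with `chromosome`,
#'   `position`, `fst` (and any id columns, carried through).
#' @param enriched chromosome names to draw candidates from (see
#'   [chromosome_enrichment()]).
#' @param n_candidates total number of candidates (default 47).
#' @return a list with `candidates` (selected rows, ordered by chromosome and
#'   position), `allocation` (named integer vector), `spacing` (list with
#'   `mean`, `min`, `max` in bp; `NA`s when fewer than two candidates share a
#'   chromosome).
#' @export
select_candidates <- function(high_snps, enriched, n_candidates = 47L) {
  pool <- high_snps[high_snps$chromosome %in% enriched, , drop = FALSE]
  if (!nrow(pool)) stop("select_candidates: no high-F_ST SNPs on enriched chromosomes")
  if (n_candidates > nrow(pool)) {
    warning("select_candidates: requested ", n_candidates,
            " candidates but only ", nrow(pool), " high-F_ST SNPs available; ",
            "returning all")
    n_candidates <- nrow(pool)
  }
  counts <- table(pool$chromosome)
  # keep chromosome order by descending count for a stable allocation
  counts <- sort(counts, decreasing = TRUE)
  alloc <- .allocate_candidates(as.integer(counts), as.integer(n_candidates))
  names(alloc) <- names(counts)
  sel <- lapply(names(counts), function(ch) {
    rows <- pool[pool$chromosome == ch, , drop = FALSE]
    rows <- rows[order(-rows$fst, rows$position), , drop = FALSE]
    utils::head(rows, alloc[[ch]])
  })
  cand <- do.call(rbind, sel)
  cand <- cand[order(cand$chromosome, cand$position), , drop = FALSE]
  rownames(cand) <- NULL
  gaps <- unlist(tapply(cand$position, cand$chromosome,
                        function(p) if (length(p) > 1L) diff(sort(p)) else numeric()))
  spacing <- if (length(gaps))
    list(mean = mean(gaps), min = min(gaps), max = max(gaps))
  else list(mean = NA_real_, min = NA_real_, max = NA_real_)
  list(candidates = cand, allocation = alloc, spacing = spacing)
}

#' Top divergence peaks among sliding windows
#'
#' Sliding windows overlap by `window - step` bp, so the k highest-mean
#' windows typically stack on a single strong island. This helper reads the
#' window track the way a Manhattan plot is read: windows are taken in
#' decreasing mean-F_ST order, skipping any window whose start lies within
#' `min_separation` bp of an already accepted window on the same chromosome,
#' until `k` peaks are collected.
#'
#' @param windows a window `data.frame` from [sliding_windows()].
#' @param k number of peaks to return.
#' @param min_separation minimum start-to-start distance between accepted
#'   windows on one chromosome (default: the window width, collapsing
#'   overlapping and abutting windows).
#' @return the accepted window rows, in decreasing mean-F_ST order (fewer
#'   than `k` when the track is exhausted).
#' @export
top_divergence_windows <- function(windows, k, min_separation = NULL) {
  if (!nrow(windows)) return(windows)
  if (is.null(min_separation))
    min_separation <- windows$end[1L] - windows$start[1L]
  w <- windows[order(-windows$mean_fst), , drop = FALSE]
  take <- integer()
  for (i in seq_len(nrow(w))) {
    if (length(take)) {
      near <- w$chromosome[take] == w$chromosome[i] &
        abs(w$start[take] - w$start[i]) < min_separation
      if (any(near)) next
    }
    take <- c(take, i)
    if (length(take) == k) break
  }
  out <- w[take, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pooled-sequencing F_ST genome scan
#'
#' The full marker-discovery computation on pooled allele counts: coverage
#' filtering, per-SNP F_ST, sliding-window summaries, high-F_ST SNP
#' identification, chromosome enrichment, and proportional candidate
#' selection.
#'
#' @param pc a [pool_counts()] table.
#' @param config a [scan_config()].
#' @return an object of class `"ecotype_scan"`: a list with elements
#'   `snp_fst` (per-SNP table after coverage filtering), `windows`,
#'   `high` (see [high_fst_snps()]), `enrichment`
#'   (see [chromosome_enrichment()]), `candidates`
#'   (see [select_candidates()]), `n_input`, `n_retained`, `config`.
#' @seealso [ecotype_panel()] for refitting and final panel selection from
#'   amplicon genotypes of the candidates.
#' @export
ecotype_scan <- function(pc, config = scan_config()) {
  stopifnot(inherits(pc, "pool_counts"), inherits(config, "scan_config"))
  kept <- coverage_filter(pc, config$min_ind_per_group)
  kept <- kept[order(kept$chromosome, kept$position), , drop = FALSE]
  class(kept) <- c("pool_counts", "data.frame")
  snp <- pool_allele_freqs(kept)
  win <- sliding_windows(snp, config$window, config$step)
  high <- high_fst_snps(snp, config$high_fst_abs)
  enr <- chromosome_enrichment(high$snps, config$enrichment_share)
  cand <- if (nrow(high$snps) && length(enr$enriched))
    select_candidates(high$snps, enr$enriched, config$n_candidates)
  else list(candidates = high$snps[0, , drop = FALSE],
            allocation = integer(), spacing = list(mean = NA, min = NA, max = NA))
  structure(list(snp_fst = snp, windows = win, high = high, enrichment = enr,
                 candidates = cand, n_input = nrow(pc), n_retained = nrow(kept),
                 config = config),
            class = "ecotype_scan")
}

#' @export
print.ecotype_scan <- function(x, ...) {
  cat("Pooled F_ST genome scan\n")
  cat("  SNPs: ", x$n_input, " input, ", x$n_retained,
      " after coverage filter (>= ", x$config$min_ind_per_group,
      " individuals/group)\n", sep = "")
  cat("  high-F_ST SNPs (F_ST > ", x$config$high_fst_abs, "): ",
      x$high$n_high, sep = "")
  if (!is.na(x$high$realized_quantile))
    cat(" (threshold at empirical quantile ",
        sprintf("%.4f", x$high$realized_quantile), ")", sep = "")
  cat("\n  enriched chromosomes (> ",
      100 * x$config$enrichment_share, "% of high SNPs): ",
      if (length(x$enrichment$enriched))
        paste(x$enrichment$enriched, collapse = ", ") else "none", sep = "")
  if (!is.na(x$enrichment$coverage))
    cat(" [joint coverage ", sprintf("%.1f%%", 100 * x$enrichment$coverage),
        "]", sep = "")
  cat("\n  candidates selected: ", nrow(x$candidates$candidates), "\n", sep = "")
  invisible(x)
}

#' @export
summary.ecotype_scan <- function(object, ...) {
  print(object)
  if (nrow(object$windows)) {
    cat("\nTop windows by mean F_ST:\n")
    w <- object$windows[order(-object$windows$mean_fst), ]
    print(utils::head(w, 10), row.names = FALSE)
  }
  invisible(object)
}

#' Manhattan-style plot of window F_ST
#'
#' Plots per-window mean F_ST against cumulative genomic position, colouring
#' alternate chromosomes, with the high-F_ST threshold as a horizontal line.
#'
#' @param x an `"ecotype_scan"` object.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ecotype_scan <- function(x, ...) {
  w <- x$windows
  if (!nrow(w)) { warning("no windows to plot"); return(invisible(x)) }
  chr <- unique(w$chromosome)
  offs <- c(0, cumsum(tapply(w$end, w$chromosome, max)[chr]))
  names(offs) <- c(chr, "_end")
  xpos <- w$start + offs[w$chromosome]
  col <- c("grey35", "steelblue")[1 + (match(w$chromosome, chr) %% 2)]
  graphics::plot(xpos, w$mean_fst, pch = 16, cex = 0.5, col = col,
                 xlab = "cumulative position (bp)",
                 ylab = "window mean F_ST", ylim = c(0, 1), ...)
  graphics::abline(h = x$config$high_fst_abs, lty = 2, col = "firebrick")
  invisible(x)
}
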