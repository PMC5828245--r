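#' Per-SNP locus overlap indicator
#'
#' For every SNP in `loci` (as a locus index), `TRUE` iff any of its LD
#' proxies lies inside the interval set. Computing this once per panel
#' makes counting over thousands of background sets cheap.
#'
#' @param loci A `locus_list` from [ld_expand()].
#' @param set An [interval_set()] (merged).
#' @param panel The [snp_panel()] the loci were expanded against.
#' @return Named logical vector over the locus index SNPs.
#' @export
locus_overlap <- function(loci, set, panel) {
  stopifnot(inherits(loci, "locus_list"))
  all_prox <- unique(unlist(lapply(loci, `[[`, "proxies"), use.names = FALSE))
  idx <- .panel_index(panel, all_prox)
  ov <- stats::setNames(
    point_overlaps(set, panel$snps$chrom[idx], panel$snps$pos[idx]),
    all_prox)
  vapply(loci, function(l) any(ov[l$proxies]), logical(1))
}

#' Count loci with at least one overlapping SNP
#'
#' Locus-level counting: a locus (index SNP plus its LD proxies)
#' contributes 1 if any proxy falls inside any interval, regardless of how
#' many proxies do.
#'
#' @inheritParams locus_overlap
#' @return Integer count in `[0, length(loci)]`.
#' @export
count_overlapping_loci <- function(loci, set, panel) {
  if (!length(loci)) stop("empty locus collection")
  sum(locus_overlap(loci, set, panel))
}

#' Matched-background enrichment test
#'
#' The core resampling statistic: the observed number of index loci
#' overlapping an open-chromatin set is compared with the distribution of
#' the same count over matched background sets. The deviation is a z score
#' (sample SD, ddof 1) and the empirical P value is the fraction of
#' background sets whose count meets or exceeds the observed count,
#' floored at `1 / n_sets` — with 10,000 sets the smallest attainable
#' uncorrected P is 1e-4.
#'
#' @param index_loci `locus_list` for the index SNPs.
#' @param background A [draw_matched_sets()] result, or a precomputed
#'   integer vector of background overlap counts.
#' @param set An [interval_set()] (the annotation being tested).
#' @param panel The [snp_panel()].
#' @param h Haplotype matrix; required when `background` is a
#'   `matched_sets` object (its SNPs are LD-expanded with the same
#'   threshold/window as `index_loci` unless overridden).
#' @param r2_threshold,window_bp LD expansion parameters for background
#'   SNPs; default to those recorded in `index_loci`.
#' @param annotation_label Label stored in the result.
#' @return An object of class `enrichment_result` with fields `observed`,
#'   `bg_mean`, `bg_sd`, `z`, `z_defined`, `n_exceeding`, `p_empirical`,
#'   `n_sets`, `n_loci`, `annotation_label`, `background_counts`.
#' @export
enrichment_test <- function(index_loci, background, set, panel, h = NULL,
                            r2_threshold = NULL, window_bp = 1e6,
                            annotation_label = set$label) {
  stopifnot(inherits(index_loci, "locus_list"))
  if (!length(index_loci)) stop("empty locus collection")
  observed <- count_overlapping_loci(index_loci, set, panel)
  if (inherits(background, "matched_sets")) {
    if (is.null(h)) stop("h is required to LD-expand matched background sets")
    if (is.null(r2_threshold)) {
      r2_threshold <- index_loci[[1]]$r2_threshold
    }
    bg_counts <- background_overlap_counts(background, set, panel, h,
                                           r2_threshold = r2_threshold,
                                           window_bp = window_bp)
  } else {
    bg_counts <- as.integer(background)
  }
  n_sets <- length(bg_counts)
  if (n_sets < 100) stop("need at least 100 background sets")
  bg_mean <- mean(bg_counts)
  bg_sd <- stats::sd(bg_counts)
  z_defined <- bg_sd > 0
  z <- if (z_defined) (observed - bg_mean) / bg_sd else NA_real_
  if (!z_defined) {
    warning("background counts have zero variance; z undefined")
  }
  n_exceeding <- sum(bg_counts >= observed)
  p_empirical <- max(n_exceeding, 1L) / n_sets
  structure(list(observed = observed, bg_mean = bg_mean, bg_sd = bg_sd,
                 z = z, z_defined = z_defined, n_exceeding = n_exceeding,
                 p_empirical = p_empirical, n_sets = n_sets,
                 n_loci = length(index_loci),
                 annotation_label = annotation_label,
                 background_counts = bg_counts),
            class = "enrichment_result")
}

#' Background overlap counts for matched sets
#'
#' LD-expands every distinct background SNP once, computes its locus-level
#' overlap indicator, and sums indicators within each set.
#'
#' @param matched A [draw_matched_sets()] result.
#' @inheritParams enrichment_test
#' @return Integer vector of per-set overlap counts.
#' @export
background_overlap_counts <- function(matched, set, panel, h,
                                      r2_threshold = 0.8, window_bp = 1e6) {
  stopifnot(inherits(matched, "matched_sets"))
  snps <- unique(as.vector(matched$sets))
  loci <- ld_expand(snps, panel, h, r2_threshold = r2_threshold,
                    window_bp = window_bp)
  ov <- locus_overlap(loci, set, panel)
  counts <- matrix(ov[as.vector(matched$sets)], nrow = matched$n_sets)
  as.integer(rowSums(counts))
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> '", x$annotation_label, "'\n", sep = "")
  cat(sprintf("  observed %d / %d loci; background %.2f +/- %.2f over %d sets\n",
              x$observed, x$n_loci, x$bg_mean, x$bg_sd, x$n_sets))
  cat(sprintf("  z = %s, empirical P = %.4g (%d set(s) >= observed)\n",
              if (x$z_defined) sprintf("%.2f", x$z) else "undefined",
              x$p_empirical, x$n_exceeding))
  invisible(x)
}

#' Flag annotations with under-powered backgrounds
#'
#' An annotation is kept only if at least `min_nonzero` background sets
#' show any overlap with it; sparse annotations yield degenerate nulls and
#' are removed (e.g. fewer than 1000 of 10,000 sets non-zero).
#'
#' @param background_counts Integer vector of background overlap counts.
#' @param min_nonzero Keep threshold (inclusive), default 1000.
#' @param quiet Suppress the decision message.
#' @return `TRUE` (keep) or `FALSE` (drop), with attribute `n_nonzero`.
#' @export
filter_low_power_sets <- function(background_counts, min_nonzero = 1000,
                                  quiet = FALSE) {
  n_nonzero <- sum(background_counts >= 1)
  keep <- n_nonzero >= min_nonzero
  if (!quiet) {
    message("filter_low_power_sets: ", n_nonzero, " of ",
            length(background_counts), " background sets non-zero -> ",
            if (keep) "keep" else "drop")
  }
  structure(keep, n_nonzero = n_nonzero)
}

#' Multiple-testing correction
#'
#' Benjamini-Hochberg step-up or Bonferroni, with an explicit test count
#' `m` that may exceed the number of p-values supplied (e.g. correcting
#' each cell-type test for 37 tests performed across a study).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @param method `"BH"` or `"bonferroni"`.
#' @param m Number of tests; defaults to `length(p)`.
#' @return Adjusted p-values, capped at 1.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni"), m = NULL) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.null(m)) m <- length(p)
  if (m < length(p)) stop("m must be at least length(p)")
  stats::p.adjust(p, method = method, n = m)
}
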