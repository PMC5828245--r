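#' Read GWAS summary statistics
#'
#' Tab-separated with a header; either `SNP CHR BP Z N` (chi-square taken
#' as `Z^2`) or `SNP CHR BP CHISQ N`.
#'
#' @param path Path to the summary-statistics file.
#' @return Data frame (class `sumstats`) with columns `snp`, `chrom`,
#'   `pos`, `chi2`, `n_gwas`.
#' @export
read_sumstats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df) <- toupper(names(df))
  need <- c("SNP", "CHR", "BP", "N")
  if (!all(need %in% names(df))) {
    stop("summary statistics need columns SNP, CHR, BP, N and Z or CHISQ")
  }
  chi2 <- if ("CHISQ" %in% names(df)) df$CHISQ
          else if ("Z" %in% names(df)) df$Z^2
          else stop("need a Z or CHISQ column")
  out <- data.frame(snp = as.character(df$SNP), chrom = as.character(df$CHR),
                    pos = as.numeric(df$BP), chi2 = as.numeric(chi2),
                    n_gwas = as.numeric(df$N), stringsAsFactors = FALSE)
  if (any(out$chi2 < 0)) stop("chi-square values must be non-negative")
  if (any(out$n_gwas <= 0)) stop("GWAS sample sizes must be positive")
  class(out) <- c("sumstats", class(out))
  out
}

#' Write GWAS summary statistics
#'
#' @param stats A `sumstats` data frame (`snp`, `chrom`, `pos`, `chi2`,
#'   `n_gwas`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  df <- data.frame(SNP = stats$snp, CHR = stats$chrom, BP = stats$pos,
                   CHISQ = stats$chi2, N = stats$n_gwas)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a SNP annotation matrix from interval sets
#'
#' Binary SNP x category indicators: `a(j,c) = 1` iff SNP `j`'s position
#' lies inside category `c`'s intervals, with an all-SNPs `base` category
#' prepended. Callers extend interval sets (e.g. by +/-500 bp) before this
#' step.
#'
#' @param panel A [snp_panel()].
#' @param sets Named list of [interval_set()] objects (may be empty).
#' @return Integer matrix (SNPs x categories) with rownames the SNP ids
#'   and first column `base`; class `annotation_matrix`.
#' @export
annotate_snps <- function(panel, sets = list()) {
  if (inherits(sets, "interval_set")) {
    sets <- stats::setNames(list(sets), sets$label)
  }
  cols <- c(list(base = rep(1L, nrow(panel$snps))),
            lapply(sets, function(s) {
              as.integer(point_overlaps(s, panel$snps$chrom, panel$snps$pos))
            }))
  a <- do.call(cbind, cols)
  rownames(a) <- panel$snps$snp
  empty <- colSums(a) == 0
  if (any(empty)) {
    stop("annotation category with zero SNPs: ",
         paste(colnames(a)[empty], collapse = ", "))
  }
  structure(a, class = c("annotation_matrix", "matrix", "array"))
}

#' Stratified LD-score regression
#'
#' Fits the stratified polygenic model
#' `E[chi2_j] = 1 + n_gwas * sum_c tau_c * l(j,c)` by weighted least
#' squares (weights `1 / max(l_base, 1)`), partitions heritability across
#' the annotation categories, and attaches delete-one-block jackknife
#' standard errors over contiguous SNP blocks.
#'
#' Per-category heritability is `h2_c = sum_{j in c} sum_{c'} tau_{c'}
#' a(j,c')` (each SNP's modelled effect variance, summed over the SNPs the
#' category contains); enrichment is the category's share of total h2
#' divided by its share of SNPs, so the all-SNPs base category has
#' enrichment exactly 1. The enrichment p-value is a two-sided normal test
#' of `(enrichment - 1) / SE`. Negative category h2 estimates are allowed
#' (unconstrained WLS) and flagged.
#'
#' @param stats A `sumstats` data frame (see [read_sumstats()]); rows are
#'   matched to the score rows by SNP id.
#' @param scores LD scores from [compute_ld_scores()].
#' @param annotations The matching [annotate_snps()] matrix.
#' @param n_blocks Jackknife block count; auto-reduced to
#'   `floor(n_snps / 50)` on small panels, never below 20.
#' @param free_intercept Estimate the intercept instead of fixing it at 1.
#' @return An object of class `ldsc_fit`; see `summary()` for the
#'   per-category table (`tau`, `tau_se`, `snp_share`, `h2_share`,
#'   `enrichment`, `enrichment_se`, `p_enrichment`).
#' @export
stratified_ldsc <- function(stats, scores, annotations, n_blocks = 200,
                            free_intercept = FALSE) {
  a <- unclass(annotations)
  l <- unclass(scores)
  stopifnot(nrow(a) == nrow(l), ncol(a) == ncol(l))
  idx <- match(stats$snp, rownames(a))
  if (anyNA(idx)) {
    stop("summary statistics contain SNPs absent from the annotations: ",
         paste(utils::head(stats$snp[is.na(idx)], 5), collapse = ", "))
  }
  a <- a[idx, , drop = FALSE]
  l <- l[idx, , drop = FALSE]
  M <- nrow(a); C <- ncol(a)
  if (M < 10 * C) stop("need at least 10 SNPs per category")
  n_blocks <- max(20L, min(as.integer(n_blocks), floor(M / 50)))
  if (n_blocks > M / 10) n_blocks <- max(20L, floor(M / 10))
  N <- stats$n_gwas
  X <- l * N
  if (free_intercept) X <- cbind(intercept = 1, X)
  y <- if (free_intercept) stats$chi2 else stats$chi2 - 1
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular design; collinear categories: ",
         paste(dep, collapse = ", "))
  }
  w <- if ("base" %in% colnames(l)) 1 / pmax(l[, "base"], 1) else
    rep(1, M)  # uniform weights when no all-SNPs score column exists
  Xw <- X * w
  block_id <- ceiling(seq_len(M) / (M / n_blocks))
  block_id[block_id > n_blocks] <- n_blocks
  # per-block sufficient statistics for cheap delete-one refits
  XtWX_b <- array(0, c(ncol(X), ncol(X), n_blocks))
  XtWy_b <- matrix(0, ncol(X), n_blocks)
  for (b in seq_len(n_blocks)) {
    rows <- which(block_id == b)
    XtWX_b[, , b] <- crossprod(Xw[rows, , drop = FALSE],
                               X[rows, , drop = FALSE])
    XtWy_b[, b] <- crossprod(Xw[rows, , drop = FALSE], y[rows])
  }
  XtWX <- apply(XtWX_b, c(1, 2), sum)
  XtWy <- rowSums(XtWy_b)
  solve_tau <- function(A, bvec) {
    est <- solve(A, bvec)
    stats::setNames(as.numeric(est), colnames(X))
  }
  est_full <- solve_tau(XtWX, XtWy)
  tau_full <- est_full[colnames(a)]
  summarise <- function(tau) {
    per_snp <- as.numeric(a %*% tau)
    h2_total <- sum(per_snp)
    h2_c <- as.numeric(crossprod(a, per_snp))
    M_c <- colSums(a)
    h2_share <- h2_c / h2_total
    snp_share <- M_c / M
    list(h2_total = h2_total, h2_c = h2_c, h2_share = h2_share,
         snp_share = snp_share, enrichment = h2_share / snp_share)
  }
  full <- summarise(tau_full)
  # delete-one-block estimates
  tau_del <- matrix(0, n_blocks, C, dimnames = list(NULL, colnames(a)))
  enr_del <- matrix(0, n_blocks, C, dimnames = list(NULL, colnames(a)))
  h2_del <- numeric(n_blocks)
  for (b in seq_len(n_blocks)) {
    est_b <- solve_tau(XtWX - XtWX_b[, , b], XtWy - XtWy_b[, b])
    tau_b <- est_b[colnames(a)]
    tau_del[b, ] <- tau_b
    s <- summarise(tau_b)
    enr_del[b, ] <- s$enrichment
    h2_del[b] <- s$h2_total
  }
  jack_se <- function(theta_del) {
    sqrt((n_blocks - 1) / n_blocks *
           colSums(sweep(theta_del, 2, colMeans(theta_del))^2))
  }
  tau_se <- jack_se(tau_del)
  enr_se <- jack_se(enr_del)
  h2_se <- sqrt((n_blocks - 1) / n_blocks * sum((h2_del - mean(h2_del))^2))
  p_enr <- ifelse(enr_se > 0,
                  2 * stats::pnorm(-abs(full$enrichment - 1) / enr_se),
                  NA_real_)
  p_enr[colnames(a) == "base"] <- NA_real_
  tab <- data.frame(category = colnames(a), tau = unname(tau_full),
                    tau_se = unname(tau_se),
                    n_snps = unname(colSums(a)),
                    snp_share = unname(full$snp_share),
                    h2 = unname(full$h2_c),
                    h2_share = unname(full$h2_share),
                    enrichment = unname(full$enrichment),
                    enrichment_se = unname(enr_se),
                    p_enrichment = unname(p_enr),
                    negative_h2 = unname(full$h2_c < 0),
                    stringsAsFactors = FALSE)
  structure(list(table = tab, h2_total = full$h2_total, h2_se = h2_se,
                 n_snps = M, n_blocks = n_blocks,
                 intercept = if (free_intercept)
                   unname(est_full["intercept"]) else 1,
                 free_intercept = free_intercept,
                 tau_delete = tau_del, enrichment_delete = enr_del),
            class = "ldsc_fit")
}

#' @export
print.ldsc_fit <- function(x, ...) {
  cat("<ldsc_fit> ", x$n_snps, " SNPs, ", nrow(x$table), " categories, ",
      x$n_blocks, " jackknife blocks\n", sep = "")
  cat(sprintf("  total h2 = %.4f (SE %.4f); intercept %s\n", x$h2_total,
              x$h2_se, if (x$free_intercept)
                sprintf("%.3f (free)", x$intercept) else "fixed at 1"))
  print(x$table[, c("category", "snp_share", "h2_share", "enrichment",
                    "enrichment_se", "p_enrichment")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
summary.ldsc_fit <- function(object, ...) object$table

#' @export
coef.ldsc_fit <- function(object, ...) {
  stats::setNames(object$table$tau, object$table$category)
}

#' Fit one focal annotation at a time
#'
#' The one-at-a-time design: each focal category (e.g. one motif subset) is
#' added to the baseline annotations independently, one model per focal
#' set, and the enrichment p-values are Bonferroni-corrected across the
#' focal fits.
#'
#' @param stats A `sumstats` data frame.
#' @param panel A [snp_panel()].
#' @param h Haplotype matrix aligned to `panel`.
#' @param focal_sets Named list of [interval_set()]s, one per focal
#'   category (extend them beforehand if desired).
#' @param baseline_sets Optional named list of interval sets always
#'   included alongside the all-SNPs base category.
#' @param window_bp LD-score window (bp).
#' @param n_blocks,free_intercept Passed to [stratified_ldsc()].
#' @param adjusted Passed to [compute_ld_scores()].
#' @param m Bonferroni test count; defaults to the number of focal fits.
#' @return Data frame (class `h2_partition`) with one row per focal
#'   category: enrichment, SE, `p_enrichment`, `p_corrected`, plus the
#'   underlying fits as attribute `fits`.
#' @export
run_single_annotation_models <- function(stats, panel, h, focal_sets,
                                         baseline_sets = list(),
                                         window_bp = 1e6, n_blocks = 200,
                                         free_intercept = FALSE,
                                         adjusted = FALSE, m = NULL) {
  stopifnot(length(focal_sets) >= 1)
  if (is.null(names(focal_sets)) || any(!nzchar(names(focal_sets)))) {
    stop("focal_sets must be a named list")
  }
  if (any(names(focal_sets) %in% c("base", names(baseline_sets)))) {
    stop("focal annotation labels must not collide with the baseline")
  }
  fits <- list()
  rows <- list()
  for (nm in names(focal_sets)) {
    sets <- c(baseline_sets, focal_sets[nm])
    ann <- annotate_snps(panel, sets)
    sc <- compute_ld_scores(panel, h, ann, window_bp = window_bp,
                            adjusted = adjusted)
    fit <- stratified_ldsc(stats, sc, ann, n_blocks = n_blocks,
                           free_intercept = free_intercept)
    fits[[nm]] <- fit
    r <- fit$table[fit$table$category == nm, ]
    rows[[nm]] <- data.frame(category = nm, n_snps = r$n_snps,
                             snp_share = r$snp_share,
                             h2_share = r$h2_share,
                             enrichment = r$enrichment,
                             enrichment_se = r$enrichment_se,
                             p_enrichment = r$p_enrichment,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (is.null(m)) m <- nrow(out)
  out$p_corrected <- adjust_pvalues(out$p_enrichment, "bonferroni", m = m)
  attr(out, "fits") <- fits
  attr(out, "m") <- m
  class(out) <- c("h2_partition", class(out))
  out
}
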