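#' Pairwise r-squared between two panel SNPs
#'
#' Squared Pearson correlation of the 0/1 allele indicators across
#' haplotypes — the standard haplotype-based LD estimate, unadjusted.
#'
#' @param h Haplotype matrix (haplotypes x SNPs), columns named by SNP id.
#' @param i,j SNP ids or column indices.
#' @return r-squared in `[0, 1]`.
#' @export
compute_r2 <- function(h, i, j) {
  if (is.character(i)) i <- match(i, colnames(h))
  if (is.character(j)) j <- match(j, colnames(h))
  if (anyNA(c(i, j))) stop("SNP not present in haplotype matrix")
  x <- h[, i]; y <- h[, j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("LD undefined for monomorphic SNP")
  }
  stats::cor(x, y)^2
}

# Signed correlation matrix for the panel SNPs on one chromosome, with
# entries beyond the bp window zeroed. Diagonal is exactly 1.
.chrom_cor <- function(h, idx, pos, window_bp = NULL) {
  r <- stats::cor(h[, idx, drop = FALSE])
  diag(r) <- 1
  if (!is.null(window_bp) && is.finite(window_bp)) {
    far <- abs(outer(pos, pos, "-")) > window_bp
    r[far] <- 0
  }
  r
}

# Split panel row indices by chromosome, preserving panel order.
.by_chrom <- function(panel) split(seq_len(nrow(panel$snps)), panel$snps$chrom)

#' Expand SNPs to LD loci
#'
#' For each input SNP, finds all panel SNPs within `window_bp` on the same
#' chromosome whose r-squared with it strictly exceeds `r2_threshold`, and
#' returns the index SNP together with these proxies as a locus — the unit
#' at which open-chromatin overlap is counted.
#'
#' @param snps Character vector of SNP ids (must be in the panel).
#' @param panel A [snp_panel()].
#' @param h Haplotype matrix aligned to `panel`.
#' @param r2_threshold Proxy threshold; proxies require `r2 > r2_threshold`
#'   (strict). Default 0.8.
#' @param window_bp Search window around the index SNP. Default 1 Mb.
#' @return A `locus_list`: named list (one element per input SNP) of locus
#'   objects with fields `index`, `proxies` (ids, index included) and
#'   `r2_threshold`.
#' @export
ld_expand <- function(snps, panel, h, r2_threshold = 0.8,
                      window_bp = 1e6) {
  idx <- .panel_index(panel, snps)
  chrom <- panel$snps$chrom
  pos <- panel$snps$pos
  out <- vector("list", length(snps))
  names(out) <- snps
  for (ch in unique(chrom[idx])) {
    on_ch <- which(chrom == ch)
    qs <- idx[chrom[idx] == ch]
    # one correlation matrix per chromosome serves all queries on it
    r2 <- .chrom_cor(h, on_ch, pos[on_ch])^2
    for (q in qs) {
      k <- match(q, on_ch)
      inwin <- abs(pos[on_ch] - pos[q]) <= window_bp
      prox <- on_ch[inwin & r2[k, ] > r2_threshold]
      prox <- union(q, prox)
      out[[panel$snps$snp[q]]] <- structure(
        list(index = panel$snps$snp[q],
             proxies = panel$snps$snp[sort(prox)],
             r2_threshold = r2_threshold),
        class = "locus")
    }
  }
  structure(out, class = "locus_list")
}

#' @export
print.locus_list <- function(x, ...) {
  sizes <- lengths(lapply(x, `[[`, "proxies"))
  cat("<locus_list> ", length(x), " loci; proxies per locus ",
      min(sizes), "-", max(sizes), "\n", sep = "")
  invisible(x)
}

#' Count LD buddies for panel SNPs
#'
#' Number of other SNPs within the window whose r-squared with the query
#' meets `buddy_r2` (inclusive). A matching covariate in the
#' SNPsnap-style background sampler.
#'
#' @param snp SNP id(s); default all panel SNPs.
#' @inheritParams ld_expand
#' @param buddy_r2 Inclusive buddy threshold, default 0.5.
#' @return Named integer vector of buddy counts.
#' @export
ld_buddy_count <- function(panel, h, snp = panel$snps$snp,
                           buddy_r2 = 0.5, window_bp = 1e6) {
  idx <- .panel_index(panel, snp)
  chrom <- panel$snps$chrom
  pos <- panel$snps$pos
  out <- stats::setNames(integer(length(idx)), snp)
  for (ch in unique(chrom[idx])) {
    on_ch <- which(chrom == ch)
    r2 <- .chrom_cor(h, on_ch, pos[on_ch])^2
    qs <- idx[chrom[idx] == ch]
    for (q in qs) {
      k <- match(q, on_ch)
      inwin <- abs(pos[on_ch] - pos[q]) <= window_bp
      out[panel$snps$snp[q]] <-
        sum(inwin & r2[k, ] >= buddy_r2) - 1L  # exclude self
    }
  }
  out
}

#' Annotation-specific LD scores
#'
#' For SNP `j` and annotation category `c`, the LD score is
#' `l(j,c) = sum_k r2(j,k) * a(k,c)` over panel SNPs `k` within the window
#' on the same chromosome, including `k = j` with `r2 = 1`. These are the
#' regressors of stratified LD-score regression.
#'
#' @inheritParams ld_expand
#' @param annotations Annotation matrix from [annotate_snps()] (SNPs x
#'   categories, 0/1, rows aligned to the panel).
#' @param adjusted Use the finite-panel bias adjustment
#'   `r2_adj = r2 - (1 - r2) / (n_hap - 2)` in place of raw r-squared.
#' @return Matrix of LD scores (SNPs x categories), class `ld_scores`,
#'   rows named by SNP id.
#' @export
compute_ld_scores <- function(panel, h, annotations, window_bp = 1e6,
                              adjusted = FALSE) {
  a <- unclass(annotations)
  if (nrow(a) != nrow(panel$snps)) {
    stop("annotations must have one row per panel SNP")
  }
  n_hap <- nrow(h)
  scores <- matrix(0, nrow = nrow(a), ncol = ncol(a),
                   dimnames = list(panel$snps$snp, colnames(a)))
  for (on_ch in .by_chrom(panel)) {
    r2 <- .chrom_cor(h, on_ch, panel$snps$pos[on_ch], window_bp)^2
    if (adjusted) {
      nz <- r2 > 0
      r2[nz] <- r2[nz] - (1 - r2[nz]) / (n_hap - 2)
      diag(r2) <- 1
    }
    scores[on_ch, ] <- r2 %*% a[on_ch, , drop = FALSE]
  }
  structure(scores, class = c("ld_scores", "matrix", "array"))
}
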