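# Brute-force reference implementations, deliberately independent of the
# package internals: plain loops and first-principles formulas only.

# Scanline sweep over sorted endpoints; bookended intervals coalesce.
oracle_merge <- function(df) {
  out <- NULL
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, , drop = FALSE]
    d <- d[order(d$start, d$end), , drop = FALSE]
    cur_s <- d$start[1]; cur_e <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur_e) {          # overlap or bookended
        cur_e <- max(cur_e, d$end[i])
      } else {
        out <- rbind(out, data.frame(chrom = ch, start = cur_s,
                                     end = cur_e))
        cur_s <- d$start[i]; cur_e <- d$end[i]
      }
    }
    out <- rbind(out, data.frame(chrom = ch, start = cur_s, end = cur_e))
  }
  out[order(out$chrom, out$start), , drop = FALSE]
}

# Linear scan: 1-based pos against 0-based half-open intervals.
oracle_point_overlap <- function(df, chrom, pos) {
  hit <- FALSE
  for (i in seq_len(nrow(df))) {
    if (df$chrom[i] == chrom && (pos - 1) >= df$start[i] &&
        (pos - 1) < df$end[i]) hit <- TRUE
  }
  hit
}

# r^2 from the covariance formula written out by hand.
oracle_r2 <- function(x, y) {
  n <- length(x)
  cxy <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  vx <- sum((x - mean(x))^2) / (n - 1)
  vy <- sum((y - mean(y))^2) / (n - 1)
  (cxy / sqrt(vx * vy))^2
}

# All-pairs proxy filter (strict threshold) within the bp window.
oracle_ld_expand <- function(q, snps, chrom, pos, h, r2_threshold,
                             window_bp) {
  keep <- snps[q]
  for (k in seq_along(snps)) {
    if (k == q) next
    if (chrom[k] != chrom[q]) next
    if (abs(pos[k] - pos[q]) > window_bp) next
    if (oracle_r2(h[, q], h[, k]) > r2_threshold) keep <- c(keep, snps[k])
  }
  sort(keep)
}

oracle_buddy_count <- function(q, chrom, pos, h, buddy_r2, window_bp) {
  n <- 0L
  for (k in seq_along(chrom)) {
    if (k == q) next
    if (chrom[k] != chrom[q]) next
    if (abs(pos[k] - pos[q]) > window_bp) next
    if (oracle_r2(h[, q], h[, k]) >= buddy_r2) n <- n + 1L
  }
  n
}

# O(M^2) double loop for annotation-specific LD scores.
oracle_ld_scores <- function(chrom, pos, h, a, window_bp) {
  M <- length(chrom)
  out <- matrix(0, M, ncol(a))
  for (j in seq_len(M)) {
    for (k in seq_len(M)) {
      if (chrom[k] != chrom[j]) next
      if (abs(pos[k] - pos[j]) > window_bp) next
      r2 <- if (k == j) 1 else oracle_r2(h[, j], h[, k])
      for (cc in seq_len(ncol(a))) {
        out[j, cc] <- out[j, cc] + r2 * a[k, cc]
      }
    }
  }
  out
}

# Exhaustive double loop over (locus, interval): a locus counts once if
# any proxy position falls in any interval.
oracle_count_loci <- function(loci_proxies, snp_chrom, snp_pos, ivl_df) {
  count <- 0L
  for (prox in loci_proxies) {
    hit <- FALSE
    for (s in prox) {
      if (oracle_point_overlap(ivl_df, snp_chrom[[s]], snp_pos[[s]])) {
        hit <- TRUE
      }
    }
    if (hit) count <- count + 1L
  }
  count
}

# Minimum distance from a 1-based SNP position to any gene edge
# (0 inside a gene), brute force over all gene intervals.
oracle_dist_gene <- function(chrom, pos, gdf) {
  p0 <- pos - 1
  best <- Inf
  for (i in seq_len(nrow(gdf))) {
    if (gdf$chrom[i] != chrom) next
    if (p0 >= gdf$start[i] && p0 < gdf$end[i]) return(0)
    best <- min(best, abs(p0 - gdf$start[i]), abs(p0 - (gdf$end[i] - 1)))
  }
  best
}
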