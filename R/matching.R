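#' Per-SNP matching covariates
#'
#' Computes the four covariates used to draw matched background SNPs:
#' minor-allele frequency, LD-buddy count, distance to the nearest gene
#' (bp; 0 inside a gene) and gene density (gene intervals overlapping a
#' +/-500 kb window centred on the SNP).
#'
#' @param panel A [snp_panel()].
#' @param h Haplotype matrix aligned to `panel`.
#' @param genes An [interval_set()] of gene bodies.
#' @param buddy_r2,window_bp Passed to [ld_buddy_count()].
#' @param density_window_bp Half-width of the gene-density window (bp).
#' @return A data frame (class `match_covariates`) with columns `snp`,
#'   `maf`, `ld_buddies`, `dist_nearest_gene`, `gene_density`.
#' @export
compute_match_covariates <- function(panel, h, genes, buddy_r2 = 0.5,
                                     window_bp = 1e6,
                                     density_window_bp = 5e5) {
  stopifnot(inherits(genes, "interval_set"))
  if (!length(genes$gr)) stop("genes must be non-empty")
  df <- panel$snps
  buddies <- ld_buddy_count(panel, h, buddy_r2 = buddy_r2,
                            window_bp = window_bp)
  gdf <- as.data.frame(merge_intervals(genes, label = genes$label))
  dist <- numeric(nrow(df))
  for (ch in unique(df$chrom)) {
    si <- which(df$chrom == ch)
    g <- gdf[gdf$chrom == ch, , drop = FALSE]
    if (!nrow(g)) {
      message("compute_match_covariates: no genes on ", ch,
              "; using chromosome length as distance")
      dist[si] <- unname(panel$layout$lengths[ch])
      next
    }
    p0 <- df$pos[si] - 1  # 0-based point
    k <- findInterval(p0, g$start)
    inside <- k >= 1 & p0 < ifelse(k >= 1, g$end[pmax(k, 1)], Inf)
    left <- ifelse(k >= 1, p0 - (g$end[pmax(k, 1)] - 1), Inf)
    right <- ifelse(k < nrow(g), g$start[pmin(k + 1, nrow(g))] - p0, Inf)
    d <- pmin(pmax(left, 0), pmax(right, 0))
    d[inside] <- 0
    dist[si] <- d
  }
  win_lo <- pmax(1, df$pos - density_window_bp)
  win_hi <- pmin(unname(panel$layout$lengths[df$chrom]),
                 df$pos + density_window_bp)
  win <- GenomicRanges::GRanges(
    seqnames = factor(df$chrom, levels = panel$layout$chrom),
    ranges = IRanges::IRanges(start = as.integer(win_lo),
                              end = as.integer(win_hi)),
    seqinfo = .layout_seqinfo(panel$layout))
  density <- GenomicRanges::countOverlaps(win, genes$gr)
  out <- data.frame(snp = df$snp, maf = df$maf,
                    ld_buddies = unname(buddies[df$snp]),
                    dist_nearest_gene = dist,
                    gene_density = as.integer(density),
                    stringsAsFactors = FALSE)
  class(out) <- c("match_covariates", class(out))
  out
}

# Candidate pool for one index SNP under the current tolerance set.
.match_pool <- function(cov, i, candidates, tol_maf, tol_frac) {
  rel_ok <- function(x, x0) {
    lo <- x0 * (1 - tol_frac); hi <- x0 * (1 + tol_frac)
    x >= lo & x <= hi
  }
  ok <- abs(cov$maf[candidates] - cov$maf[i]) <= tol_maf &
    rel_ok(cov$ld_buddies[candidates], cov$ld_buddies[i]) &
    rel_ok(cov$dist_nearest_gene[candidates], cov$dist_nearest_gene[i]) &
    rel_ok(cov$gene_density[candidates], cov$gene_density[i])
  candidates[ok]
}

#' Draw matched background SNP sets
#'
#' SNPsnap-style resampling null: for each index SNP, a candidate pool of
#' panel SNPs matched on MAF (absolute window), LD buddies, gene distance
#' and gene density (relative windows) is built — excluding all index SNPs
#' and SNPs inside the exclusion regions — and `n_sets` background sets are
#' drawn, one candidate per index SNP, uniformly, without replacement
#' within a set and with replacement across sets.
#'
#' If a pool is empty, all four tolerances for that SNP are widened by 25%
#' up to `max_relax` times before erroring (deterministic relaxation
#' ladder); the effective tolerances are recorded in the result.
#'
#' @param index Character vector of index SNP ids.
#' @param cov Covariates from [compute_match_covariates()].
#' @param n_sets Number of background sets (default 10,000).
#' @param tol_maf Absolute MAF tolerance (default 0.05).
#' @param tol_frac Relative tolerance for the other three covariates
#'   (default 0.5, i.e. +/-50%).
#' @param seed Integer seed; draws are reproducible given the seed.
#' @param exclude Optional [interval_set()]; panel SNPs inside it are
#'   removed from every pool. Requires `panel`.
#' @param panel Optional [snp_panel()], needed only with `exclude`.
#' @param relax Enable the relaxation ladder (default `TRUE`).
#' @param max_relax Maximum relaxation steps (default 4).
#' @return An object of class `matched_sets`: list with `sets` (character
#'   matrix, `n_sets` x `length(index)`), `index`, `tolerances` (effective,
#'   per index SNP), `pool_sizes`, `seed`.
#' @export
draw_matched_sets <- function(index, cov, n_sets = 10000,
                              tol_maf = 0.05, tol_frac = 0.5,
                              seed = 1L, exclude = NULL, panel = NULL,
                              relax = TRUE, max_relax = 4L) {
  stopifnot(inherits(cov, "match_covariates"))
  i_idx <- match(index, cov$snp)
  if (anyNA(i_idx)) {
    stop("index SNP(s) missing from covariates: ",
         paste(index[is.na(i_idx)], collapse = ", "))
  }
  candidates <- setdiff(seq_len(nrow(cov)), i_idx)
  if (!is.null(exclude)) {
    if (is.null(panel)) stop("panel is required when exclude is given")
    inside <- point_overlaps(exclude, panel$snps$chrom, panel$snps$pos)
    candidates <- setdiff(candidates, which(inside[match(cov$snp,
                                                         panel$snps$snp)]))
  }
  pools <- vector("list", length(index))
  eff <- data.frame(snp = index, tol_maf = tol_maf, tol_frac = tol_frac,
                    relax_steps = 0L, pool_size = 0L)
  for (s in seq_along(index)) {
    tm <- tol_maf; tf <- tol_frac; steps <- 0L
    pool <- .match_pool(cov, i_idx[s], candidates, tm, tf)
    while (!length(pool) && relax && steps < max_relax) {
      tm <- tm * 1.25; tf <- tf * 1.25; steps <- steps + 1L
      pool <- .match_pool(cov, i_idx[s], candidates, tm, tf)
    }
    if (!length(pool)) {
      stop("insufficient candidates for index SNP '", index[s],
           "' (pool size 0 after ", steps, " relaxation step(s))")
    }
    pools[[s]] <- pool
    eff$tol_maf[s] <- tm; eff$tol_frac[s] <- tf
    eff$relax_steps[s] <- steps; eff$pool_size[s] <- length(pool)
  }
  sets <- with_seed(seed, .draw_sets(pools, n_sets))
  sets_id <- matrix(cov$snp[sets], nrow = n_sets,
                    dimnames = list(NULL, index))
  structure(list(sets = sets_id, index = index, tolerances = eff,
                 pool_sizes = eff$pool_size, n_sets = n_sets, seed = seed),
            class = "matched_sets")
}

# Vectorised drawing: per-slot draws for all sets at once, then resolve
# within-set duplicates by redrawing the offending entries.
.draw_sets <- function(pools, n_sets) {
  k <- length(pools)
  m <- matrix(0L, nrow = n_sets, ncol = k)
  for (s in seq_len(k)) {
    m[, s] <- pools[[s]][sample.int(length(pools[[s]]), n_sets,
                                    replace = TRUE)]
  }
  if (k > 1) {
    dup <- which(apply(m, 1, anyDuplicated) > 0)
    # greedy per-row refill, scarcest pool first, keeps tiny shared
    # pools feasible whenever a distinct assignment exists
    ord <- order(lengths(pools))
    for (r in dup) {
      done <- FALSE
      for (attempt in 1:50) {
        row <- integer(k)
        ok <- TRUE
        for (s in ord) {
          avail <- setdiff(pools[[s]], row)
          if (!length(avail)) { ok <- FALSE; break }
          row[s] <- if (length(avail) == 1L) avail else sample(avail, 1L)
        }
        if (ok) { m[r, ] <- row; done <- TRUE; break }
      }
      if (!done) {
        stop("cannot draw a within-set distinct background set: ",
             "candidate pools too small for ", k, " distinct SNPs")
      }
    }
  }
  m
}

#' @export
print.matched_sets <- function(x, ...) {
  cat("<matched_sets> ", x$n_sets, " sets x ", length(x$index),
      " slots; pool sizes ", min(x$pool_sizes), "-", max(x$pool_sizes),
      "; seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write matched sets as a tab-separated table
#'
#' Long format: `set_id`, `slot_index`, `index_snp`, `matched_snp`.
#'
#' @param x A [draw_matched_sets()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matched_sets <- function(x, path) {
  stopifnot(inherits(x, "matched_sets"))
  k <- length(x$index)
  df <- data.frame(set_id = rep(seq_len(x$n_sets), each = k),
                   slot_index = rep(seq_len(k), x$n_sets),
                   index_snp = rep(x$index, x$n_sets),
                   matched_snp = as.vector(t(x$sets)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs the expression, and restores the caller's RNG
#' state, so seeded package functions do not disturb user simulations.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
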