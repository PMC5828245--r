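#' Shared machinery for repeated enrichment simulations
#'
#' Builds, once, everything repeated enrichment simulations need against a
#' fixed reference panel and landscape: match covariates, LD loci for every
#' panel SNP, and the per-SNP locus-level overlap indicator. Mirrors real
#' practice, where one reference panel serves many analyses.
#'
#' @param config A [sim_config()].
#' @param r2_threshold,window_bp LD expansion parameters.
#' @return List with `sim`, `landscape`, `cov`, `loci` (all panel SNPs)
#'   and `ov` (named per-SNP locus overlap indicator).
#' @export
enrichment_study_fixture <- function(config, r2_threshold = 0.8,
                                     window_bp = 1e6) {
  sim <- simulate_panel(config)
  land <- simulate_regulatory_landscape(config, sim)
  cov <- compute_match_covariates(sim$panel, sim$haplotypes, land$genes,
                                  window_bp = window_bp)
  loci <- ld_expand(sim$panel$snps$snp, sim$panel, sim$haplotypes,
                    r2_threshold = r2_threshold, window_bp = window_bp)
  ov <- locus_overlap(loci, land$ocrs, sim$panel)
  list(config = config, sim = sim, landscape = land, cov = cov,
       loci = loci, ov = ov)
}

# Spread n_sims enrichment simulations across n_panels independent
# panel/landscape fixtures. An index draw whose matched pools come up
# empty even after relaxation is skipped and replaced (the matched-SNP
# tool likewise refuses index SNPs without candidates); skips are rare
# and logged.
.run_enrichment_sims <- function(config, n_sims, n_sets, n_panels, null,
                                 stream) {
  p <- numeric(0)
  per <- ceiling(n_sims / n_panels)
  skipped <- 0L
  for (k in seq_len(n_panels)) {
    cfg <- config
    cfg$seed <- as.integer((config$seed + stream * k) %%
                             .Machine$integer.max)
    fx <- enrichment_study_fixture(cfg)
    want <- min(per, n_sims - length(p))
    got <- 0L
    i <- 0L
    while (got < want && i < 10L * want) {
      i <- i + 1L
      res <- tryCatch(
        .one_enrichment_sim(fx, seed = cfg$seed + i, n_sets = n_sets,
                            null = null),
        error = function(e) {
          if (grepl("insufficient candidates|distinct background",
                    conditionMessage(e))) NULL else stop(e)
        })
      if (is.null(res)) { skipped <- skipped + 1L; next }
      p <- c(p, res$p_empirical)
      got <- got + 1L
    }
    if (length(p) >= n_sims) break
  }
  if (skipped) {
    message("enrichment study: replaced ", skipped,
            " index draw(s) without matched candidates")
  }
  p
}

# One simulated enrichment test against a prebuilt fixture: draw an index
# set (uniform when null), draw matched backgrounds, and compute the
# empirical P through enrichment_test() on locus-level counts.
.one_enrichment_sim <- function(fx, seed, n_sets, null = TRUE) {
  cfg <- fx$config
  cfg$seed <- as.integer(seed)
  if (null) cfg$index_overlap_prob <- NA
  idx <- simulate_index_snps(cfg, fx$sim, fx$landscape$ocrs)
  matched <- draw_matched_sets(idx$index, fx$cov, n_sets = n_sets,
                               seed = seed)
  bg <- as.integer(rowSums(matrix(fx$ov[as.vector(matched$sets)],
                                  nrow = n_sets)))
  index_loci <- structure(fx$loci[idx$index], class = "locus_list")
  enrichment_test(index_loci, bg, fx$landscape$ocrs, fx$sim$panel)
}

#' Type-I error calibration of the matched-background enrichment test
#'
#' Repeatedly draws null index sets (uniform panel draws, no planted
#' overlap excess) with matched backgrounds against a fixed panel and
#' landscape, and reports the fraction of simulations with empirical P at
#' or below `alpha`.
#'
#' @param n_sims Number of simulated index sets.
#' @param n_sets Matched background sets per simulation.
#' @param config Generator configuration; `n_panels` independent
#'   panel/landscape fixtures are built from its seed, with simulations
#'   divided evenly among them.
#' @param alpha Nominal level (default 0.05).
#' @param n_panels Independent reference panels to spread simulations
#'   over (default 5; averages over panel-specific count quantisation).
#' @return List with `rejection_rate`, `p_values`, `alpha`.
#' @export
enrichment_null_calibration <- function(n_sims = 500, n_sets = 1000,
                                        config = sim_config(),
                                        alpha = 0.05, n_panels = 5) {
  p <- .run_enrichment_sims(config, n_sims, n_sets, n_panels,
                            null = TRUE, stream = 1e4)
  list(rejection_rate = mean(p <= alpha), p_values = p, alpha = alpha)
}

#' Power of the enrichment test under a planted overlap excess
#'
#' Index SNPs are drawn from inside open chromatin with the configured
#' probability (default 0.7) against the landscape's background rate
#' (default about 0.2); power is the fraction of simulations detecting
#' the excess at level `alpha`.
#'
#' @inheritParams enrichment_null_calibration
#' @return List with `power`, `p_values`, `alpha`.
#' @export
enrichment_power_study <- function(n_sims = 200, n_sets = 1000,
                                   config = sim_config(), alpha = 0.05,
                                   n_panels = 2) {
  p <- .run_enrichment_sims(config, n_sims, n_sets, n_panels,
                            null = FALSE, stream = 2e4)
  list(power = mean(p <= alpha), p_values = p, alpha = alpha)
}

#' Fixture for repeated heritability-partitioning simulations
#'
#' One panel with a block-aligned focal annotation covering roughly
#' `share` of SNPs, plus its LD scores — the inputs reused by every
#' replicate of a recovery or calibration study.
#'
#' @param config A [sim_config()].
#' @param share Target SNP share of the focal category.
#' @param adjusted Use finite-panel-adjusted r-squared for the LD scores
#'   (default `TRUE`: at a few hundred haplotypes the raw scores carry an
#'   upward noise bias of roughly one unit per `n_hap` window SNPs, which
#'   visibly biases enrichment estimates).
#' @return List with `sim`, `ann`, `scores`, `share_realised`.
#' @export
h2_study_fixture <- function(config, share = 0.1, adjusted = TRUE) {
  sim <- simulate_panel(config)
  df <- sim$panel$snps
  block <- paste0(df$chrom, ":", (df$pos - 1) %/% config$block_size_bp)
  chosen <- with_seed(config$seed + 1,
                      sample(unique(block),
                             round(share * length(unique(block)))))
  keep <- block %in% chosen
  focal <- merge_intervals(interval_set(df$chrom[keep],
                                        pmax(df$pos[keep] - 51, 0),
                                        df$pos[keep] + 50, sim$layout,
                                        label = "focal"))
  ann <- annotate_snps(sim$panel, list(focal = focal))
  scores <- compute_ld_scores(sim$panel, sim$haplotypes, ann,
                              adjusted = adjusted)
  list(config = config, sim = sim, ann = ann, scores = scores,
       share_realised = mean(ann[, "focal"]))
}

#' Recovery and calibration study for stratified LD-score regression
#'
#' Simulates GWAS summary statistics with a planted focal-category
#' enrichment (or the uniform-tau null with `target = 1`) and refits each
#' replicate, reporting jackknife 95% CI coverage of the truth and the
#' fraction of replicates with enrichment P at or below `alpha`.
#'
#' @param n_reps Number of GWAS replicates.
#' @param config Generator configuration (panel is built once from it).
#' @param share Focal SNP share.
#' @param target Planted true enrichment (1 = null).
#' @param alpha Level for the rejection count.
#' @param n_blocks Jackknife blocks; default 50, so each block spans many
#'   independent LD units (mirroring the genome-wide convention of few
#'   large blocks).
#' @return List with `coverage`, `rejection_rate`, `estimates`,
#'   `true_enrichment`.
#' @export
h2_recovery_study <- function(n_reps = 100, config = sim_config(),
                              share = 0.1, target = 5, alpha = 0.05,
                              n_blocks = 50) {
  fx <- h2_study_fixture(config, share = share)
  ld <- precompute_ld(fx$sim, window_bp = config$block_size_bp)
  est <- se <- pval <- truth <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- as.integer(config$seed + 31L * i)
    g <- simulate_gwas(cfg, fx$sim, fx$ann, tau_plan = c(focal = target),
                       ld = ld)
    fit <- stratified_ldsc(g$stats, fx$scores, fx$ann,
                           n_blocks = n_blocks)
    r <- fit$table[fit$table$category == "focal", ]
    est[i] <- r$enrichment; se[i] <- r$enrichment_se
    pval[i] <- r$p_enrichment
    truth[i] <- unname(g$truth$true_enrichment["focal"])
  }
  covered <- abs(est - truth) <= 1.96 * se
  list(coverage = mean(covered), rejection_rate = mean(pval <= alpha),
       estimates = est, se = se, p_values = pval,
       true_enrichment = mean(truth))
}
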