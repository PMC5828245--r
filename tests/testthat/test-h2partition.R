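# Shared fixture: block-LD panel with a block-aligned focal annotation
# covering about 10% of SNPs.
h2_fixture <- function(seed = 5, n_snps = 2000, share = 0.1) {
  cfg <- sim_config(seed = seed, n_snps = n_snps, n_haplotypes = 200)
  sim <- simulate_panel(cfg)
  df <- sim$panel$snps
  block <- paste0(df$chrom, ":", (df$pos - 1) %/% cfg$block_size_bp)
  chosen <- with_seed(seed + 1,
                      sample(unique(block),
                             round(share * length(unique(block)))))
  keep <- block %in% chosen
  focal <- merge_intervals(interval_set(df$chrom[keep],
                                        pmax(df$pos[keep] - 51, 0),
                                        df$pos[keep] + 50, sim$layout,
                                        label = "focal"))
  ann <- annotate_snps(sim$panel, list(focal = focal))
  # adjusted scores: raw r2 from 200 haplotypes carries enough upward
  # noise bias to visibly distort enrichment on a desk-scale panel
  scores <- compute_ld_scores(sim$panel, sim$haplotypes, ann,
                              adjusted = TRUE)
  list(cfg = cfg, sim = sim, focal = focal, ann = ann, scores = scores)
}

test_that("summary statistics read both Z and CHISQ dialects", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tCHR\tBP\tZ\tN", "rs1\tchr1\t100\t2\t5000",
               "rs2\tchr1\t200\t-1.5\t5000"), p)
  st <- read_sumstats(p)
  expect_equal(st$chi2, c(4, 2.25))
  writeLines(c("SNP\tCHR\tBP\tCHISQ\tN", "rs1\tchr1\t100\t3.1\t5000"), p)
  expect_equal(read_sumstats(p)$chi2, 3.1)
  writeLines(c("SNP\tCHR\tBP\tCHISQ\tN", "rs1\tchr1\t100\t-1\t5000"), p)
  expect_error(read_sumstats(p), "non-negative")
  writeLines(c("SNP\tCHR\tBP\tN", "rs1\tchr1\t100\t5000"), p)
  expect_error(read_sumstats(p), "Z or CHISQ")
  # round trip
  writeLines(c("SNP\tCHR\tBP\tCHISQ\tN", "rs1\tchr1\t100\t3.1\t5000"), p)
  st <- read_sumstats(p)
  q <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(st, q)
  expect_equal(read_sumstats(q), st)
})

test_that("annotation matrix matches a brute-force membership loop", {
  fx <- h2_fixture(seed = 11, n_snps = 500)
  df <- fx$sim$panel$snps
  a <- fx$ann
  expect_true(all(a[, "base"] == 1))
  fdf <- as.data.frame(fx$focal)
  want <- vapply(seq_len(nrow(df)), function(i) {
    oracle_point_overlap(fdf, df$chrom[i], df$pos[i])
  }, logical(1))
  expect_equal(unname(a[, "focal"]), as.integer(want))
  # zero-membership category refuses to build
  empty <- interval_set("chr1", 1, 2, fx$sim$layout, label = "empty")
  expect_error(annotate_snps(fx$sim$panel, list(empty = empty)),
               "zero SNPs")
})

test_that("base-only model has enrichment exactly 1", {
  fx <- h2_fixture(seed = 7, n_snps = 1500)
  ann <- annotate_snps(fx$sim$panel)
  sc <- compute_ld_scores(fx$sim$panel, fx$sim$haplotypes, ann)
  g <- simulate_gwas(fx$cfg, fx$sim, ann)
  fit <- stratified_ldsc(g$stats, sc, ann)
  expect_equal(fit$table$enrichment, 1)
  expect_true(is.na(fit$table$p_enrichment))
})

test_that("null GWAS gives mean chi-square near 1 and tau near 0", {
  cfg <- sim_config(seed = 19, n_snps = 5000, n_haplotypes = 200,
                    h2_total = 0)
  sim <- simulate_panel(cfg)
  ann <- annotate_snps(sim$panel)
  g <- simulate_gwas(cfg, sim, ann)
  expect_equal(mean(g$stats$chi2), 1, tolerance = 0.05)
  sc <- compute_ld_scores(sim$panel, sim$haplotypes, ann)
  fit <- stratified_ldsc(g$stats, sc, ann)
  expect_lt(abs(fit$h2_total), 0.05)
})

test_that("planted enrichment is recovered within a few jackknife SEs", {
  fx <- h2_fixture(seed = 3, n_snps = 2000)
  g <- simulate_gwas(fx$cfg, fx$sim, fx$ann, tau_plan = c(focal = 5))
  expect_equal(unname(g$truth$true_enrichment["focal"]), 5,
               tolerance = 1e-6)
  fit <- stratified_ldsc(g$stats, fx$scores, fx$ann)
  r <- fit$table[fit$table$category == "focal", ]
  expect_lt(abs(r$enrichment - 5) / r$enrichment_se, 4)
  expect_lt(r$p_enrichment, 0.05)
})

test_that("heritability is additive over a disjoint SNP partition", {
  fx <- h2_fixture(seed = 13, n_snps = 1500)
  df <- fx$sim$panel$snps
  a <- cbind(base = rep(1L, nrow(df)),
             inA = fx$ann[, "focal"],
             inB = 1L - fx$ann[, "focal"])
  rownames(a) <- df$snp
  class(a) <- c("annotation_matrix", "matrix", "array")
  sc <- compute_ld_scores(fx$sim$panel, fx$sim$haplotypes, a)
  g <- simulate_gwas(fx$cfg, fx$sim, a, tau_plan = c(inA = 3))
  # base = inA + inB exactly: the joint design is singular
  expect_error(stratified_ldsc(g$stats, sc, a), "singular")
  # fit the disjoint two-category partition alone: shares sum to one
  keep <- c("inA", "inB")
  a2 <- structure(a[, keep], class = class(a))
  sc2 <- structure(unclass(sc)[, keep],
                   class = c("ld_scores", "matrix", "array"))
  fit <- stratified_ldsc(g$stats, sc2, a2)
  expect_equal(sum(fit$table$h2), fit$h2_total, tolerance = 1e-10)
  expect_equal(sum(fit$table$h2_share), 1, tolerance = 1e-10)
})

test_that("excluding MHC/APOE-style regions only removes SNPs", {
  fx <- h2_fixture(seed = 17, n_snps = 400)
  excl <- interval_set("chr1", 0, 5e4, fx$sim$layout, label = "excl")
  panel_x <- exclude_regions(fx$sim$panel, excl, quiet = TRUE)
  expect_lte(nrow(panel_x$snps), nrow(fx$sim$panel$snps))
  expect_gt(attr(panel_x, "n_dropped"), 0)
})

test_that("one-focal-at-a-time models report Bonferroni-corrected rows", {
  fx <- h2_fixture(seed = 23, n_snps = 2000)
  df <- fx$sim$panel$snps
  block <- paste0(df$chrom, ":", (df$pos - 1) %/% fx$cfg$block_size_bp)
  ub <- unique(block)
  mk_set <- function(blocks, lab) {
    keep <- block %in% blocks
    merge_intervals(interval_set(df$chrom[keep],
                                 pmax(df$pos[keep] - 51, 0),
                                 df$pos[keep] + 50, fx$sim$layout,
                                 label = lab))
  }
  sets <- with_seed(99, {
    picks <- split(sample(ub, 40), rep(1:4, each = 10))
    lapply(seq_along(picks), function(i) mk_set(picks[[i]],
                                                paste0("m", i)))
  })
  names(sets) <- paste0("m", 1:4)
  g <- simulate_gwas(fx$cfg, fx$sim, fx$ann, tau_plan = c(focal = 3))
  part <- run_single_annotation_models(g$stats, fx$sim$panel,
                                       fx$sim$haplotypes, sets,
                                       n_blocks = 40)
  expect_equal(nrow(part), 4)
  expect_equal(part$p_corrected,
               pmin(1, part$p_enrichment * 4))
  one <- run_single_annotation_models(g$stats, fx$sim$panel,
                                      fx$sim$haplotypes, sets[1],
                                      n_blocks = 40)
  expect_equal(one$p_corrected, one$p_enrichment)
  # explicit m overrides the default
  m37 <- run_single_annotation_models(g$stats, fx$sim$panel,
                                      fx$sim$haplotypes, sets[1],
                                      n_blocks = 40, m = 37)
  expect_equal(m37$p_corrected, min(1, m37$p_enrichment * 37))
  expect_error(run_single_annotation_models(g$stats, fx$sim$panel,
                                            fx$sim$haplotypes,
                                            list(base = sets[[1]])),
               "collide")
})
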