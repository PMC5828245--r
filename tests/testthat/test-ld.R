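test_that("pairwise r2 matches the hand covariance formula", {
  h <- cbind(a = c(0L, 0L, 1L, 1L), b = c(0L, 1L, 0L, 1L),
             c = c(0L, 0L, 1L, 1L), d = c(1L, 1L, 0L, 0L))
  expect_equal(compute_r2(h, "a", "c"), 1)      # identical columns
  expect_equal(compute_r2(h, "a", "d"), 1)      # complement: r = -1
  expect_equal(compute_r2(h, "a", "b"), 0)      # orthogonal by hand
  expect_equal(compute_r2(h, "a", "b"), oracle_r2(h[, "a"], h[, "b"]))
  expect_equal(compute_r2(h, "a", "a"), 1)
  expect_equal(compute_r2(h, "a", "c"), compute_r2(h, "c", "a"))
  h2 <- cbind(h, e = c(1L, 1L, 1L, 1L))
  expect_error(compute_r2(h2, "a", "e"), "monomorphic")
})

test_that("r2 agrees with the oracle on random haplotype fixtures", {
  set.seed(21)
  for (rep in 1:50) {
    fx <- block_haplotypes(n_snps = 6, n_hap = 30, block = 3)
    i <- sample.int(6, 1); j <- sample.int(6, 1)
    if (i == j) next
    expect_equal(compute_r2(fx$h, i, j), oracle_r2(fx$h[, i], fx$h[, j]),
                 tolerance = 1e-12)
  }
})

test_that("ld_expand returns the index alone when nothing is linked", {
  set.seed(5)
  fx <- block_haplotypes(n_snps = 6, n_hap = 60, block = 1, noise = 0.5)
  panel <- fixture_panel(fx)
  loci <- ld_expand("s3", panel, fx$h, r2_threshold = 0.99)
  expect_s3_class(loci, "locus_list")
  expect_equal(loci[["s3"]]$proxies, "s3")
})

test_that("threshold 0 pulls in every window SNP and expansion matches the oracle", {
  set.seed(31)
  fx <- block_haplotypes(n_snps = 10, n_hap = 50, block = 5)
  panel <- fixture_panel(fx)
  all_loci <- ld_expand("s4", panel, fx$h, r2_threshold = 0)
  expect_setequal(all_loci[["s4"]]$proxies, fx$snp)

  for (rep in 1:30) {
    fx <- block_haplotypes(n_snps = 10, n_hap = 40, block = 5,
                           noise = runif(1, 0.02, 0.3))
    panel <- fixture_panel(fx)
    q <- sample.int(10, 1)
    thr <- runif(1, 0.2, 0.95)
    loci <- ld_expand(fx$snp[q], panel, fx$h, r2_threshold = thr)
    expect_equal(sort(loci[[1]]$proxies),
                 oracle_ld_expand(q, fx$snp, fx$chrom, fx$pos, fx$h,
                                  thr, 1e6))
  }
  expect_error(ld_expand("nope", panel, fx$h), "not in panel")
})

test_that("raising the proxy threshold never adds proxies", {
  set.seed(8)
  fx <- block_haplotypes(n_snps = 12, n_hap = 40, block = 4, noise = 0.15)
  panel <- fixture_panel(fx)
  thresholds <- c(0.2, 0.5, 0.8, 0.95)
  prev <- NULL
  for (thr in thresholds) {
    cur <- ld_expand("s5", panel, fx$h, r2_threshold = thr)[[1]]$proxies
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("buddy counts match the exhaustive all-pairs scan", {
  set.seed(13)
  fx <- block_haplotypes(n_snps = 10, n_hap = 40, block = 5, noise = 0.1)
  panel <- fixture_panel(fx)
  counts <- ld_buddy_count(panel, fx$h, buddy_r2 = 0.5)
  for (q in seq_along(fx$snp)) {
    expect_equal(unname(counts[fx$snp[q]]),
                 oracle_buddy_count(q, fx$chrom, fx$pos, fx$h, 0.5, 1e6))
  }
  # isolated SNP: fully noisy block of its own
  fx2 <- block_haplotypes(n_snps = 5, n_hap = 200, block = 1, noise = 0.5)
  panel2 <- fixture_panel(fx2)
  expect_equal(unname(ld_buddy_count(panel2, fx2$h, snp = "s1",
                                     buddy_r2 = 0.9)), 0L)
})

test_that("LD scores match the O(M^2) oracle and add over disjoint annotations", {
  set.seed(17)
  fx <- block_haplotypes(n_snps = 20, n_hap = 50, block = 5, noise = 0.1)
  panel <- fixture_panel(fx)
  a <- cbind(base = rep(1L, 20),
             c1 = as.integer(seq_len(20) <= 10),
             c2 = as.integer(seq_len(20) > 10))
  rownames(a) <- fx$snp
  sc <- compute_ld_scores(panel, fx$h, a, window_bp = 600)
  want <- oracle_ld_scores(fx$chrom, fx$pos, fx$h, a, window_bp = 600)
  expect_equal(unclass(sc), want, ignore_attr = TRUE, tolerance = 1e-10)
  # additivity of disjoint categories and the self-score lower bound
  expect_equal(sc[, "c1"] + sc[, "c2"], sc[, "base"])
  expect_true(all(sc[, "base"] >= 1))
  # single SNP in a category scores at least its own membership
  expect_true(all(sc[1:10, "c1"] >= 1))
  # empty annotation column gives zero scores
  a0 <- cbind(a, none = 0L)
  sc0 <- compute_ld_scores(panel, fx$h, a0, window_bp = 600)
  expect_true(all(sc0[, "none"] == 0))
})

test_that("single-SNP panel has unit LD score for its own annotation", {
  layout <- tiny_layout()
  h <- cbind(s1 = c(0L, 1L, 0L, 1L, 1L, 0L))
  panel <- snp_panel("s1", "chr1", 500, 0.5, layout)
  sc <- compute_ld_scores(panel, h, cbind(base = 1L))
  expect_equal(unname(sc[1, 1]), 1)
})

test_that("cross-block r2 vanishes with many haplotypes", {
  set.seed(99)
  n_hap <- 2000
  z1 <- rbinom(n_hap, 1, 0.4); z2 <- rbinom(n_hap, 1, 0.3)
  h <- cbind(a = z1, b = as.integer(xor(z1, rbinom(n_hap, 1, 0.05))),
             c = z2, d = as.integer(xor(z2, rbinom(n_hap, 1, 0.05))))
  cross <- c(compute_r2(h, "a", "c"), compute_r2(h, "a", "d"),
             compute_r2(h, "b", "c"), compute_r2(h, "b", "d"))
  expect_lt(max(cross), 0.02)
  expect_gt(compute_r2(h, "a", "b"), 0.7)
})

test_that("haplotype files round-trip and monomorphic columns are dropped", {
  layout <- tiny_layout()
  set.seed(3)
  fx <- block_haplotypes(n_snps = 8, n_hap = 20, block = 4)
  panel <- fixture_panel(fx)
  p <- withr::local_tempfile(fileext = ".hap")
  write_hap(panel, fx$h, p)
  back <- read_hap(p, layout)
  expect_equal(back$haplotypes[, panel$snps$snp],
               fx$h[, panel$snps$snp], ignore_attr = TRUE)
  expect_equal(back$panel$snps$pos, panel$snps$pos)
  # panel MAF is recomputed from the haplotypes
  expect_equal(back$panel$snps$maf,
               pmin(colMeans(fx$h), 1 - colMeans(fx$h))[panel$snps$snp],
               ignore_attr = TRUE)

  lines <- c(readLines(p),
             paste("sMono chr1 9999 A B",
                   paste(rep("1", 20), collapse = "")))
  writeLines(lines, p)
  expect_message(again <- read_hap(p, layout), "monomorphic")
  expect_false("sMono" %in% again$panel$snps$snp)
})

test_that("minimal phased VCF converts to the haplotype format", {
  vcf <- withr::local_tempfile(fileext = ".vcf")
  hap <- withr::local_tempfile(fileext = ".hap")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
               "chr1\t100\trsA\tA\tG\t.\t.\t.\tGT\t0|1\t1|1",
               "chr1\t200\t.\tC\tT\t.\t.\t.\tGT\t0|0\t0|1"), vcf)
  vcf_to_hap(vcf, hap)
  got <- read_hap(hap, tiny_layout())
  expect_equal(got$panel$snps$snp, c("rsA", "chr1:200"))
  expect_equal(unname(got$haplotypes[, "rsA"]), c(0L, 1L, 1L, 1L))
  expect_equal(unname(got$haplotypes[, "chr1:200"]), c(0L, 0L, 0L, 1L))

  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t100\trsA\tA\tG,T\t.\t.\t.\tGT\t0|1"), vcf)
  expect_error(vcf_to_hap(vcf, hap), "multi-allelic")
  writeLines(c("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t100\trsA\tA\tG\t.\t.\t.\tGT\t0/1"), vcf)
  expect_error(vcf_to_hap(vcf, hap), "phased")
})
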