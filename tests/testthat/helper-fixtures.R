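# Small programmatic fixtures shared across test files.

tiny_layout <- function(len = c(chr1 = 1e5, chr2 = 1e5)) genome_layout(len)

# Random interval data frame on a tiny layout.
random_intervals <- function(n, layout = tiny_layout(), max_width = 500) {
  chrom <- sample(layout$chrom, n, replace = TRUE)
  start <- floor(runif(n, 0, unname(layout$lengths[chrom]) - max_width))
  width <- sample.int(max_width, n, replace = TRUE)
  data.frame(chrom = chrom, start = start, end = start + width,
             stringsAsFactors = FALSE)
}

# Hand-sized haplotype fixture: n_hap haplotypes over SNPs laid out in
# LD blocks of `block` consecutive SNPs copied from a latent column with
# flip probability `noise` (high correlation within a block).
block_haplotypes <- function(n_snps = 10, n_hap = 40, block = 5,
                             spacing = 100, noise = 0.05,
                             chrom = "chr1") {
  h <- matrix(0L, n_hap, n_snps)
  for (b in seq_len(ceiling(n_snps / block))) {
    z <- rbinom(n_hap, 1, 0.5)
    for (k in seq((b - 1) * block + 1, min(b * block, n_snps))) {
      flip <- rbinom(n_hap, 1, noise)
      col <- ifelse(flip == 1, 1L - z, z)
      if (var(col) == 0) col[1] <- 1L - col[1]
      h[, k] <- col
    }
  }
  snp <- paste0("s", seq_len(n_snps))
  colnames(h) <- snp
  list(snp = snp, chrom = rep(chrom, n_snps),
       pos = seq(1000, by = spacing, length.out = n_snps), h = h)
}

# Assemble a snp_panel from a block_haplotypes fixture.
fixture_panel <- function(fx, layout = tiny_layout()) {
  f <- colMeans(fx$h)
  f <- pmin(pmax(f, 1e-3), 1 - 1e-3)
  snp_panel(fx$snp, fx$chrom, fx$pos, pmin(f, 1 - f), layout)
}

# Panel plus hand-built loci (no LD machinery) for overlap counting.
make_loci_fixture <- function(n_loci = 18, seed = 1) {
  set.seed(seed)
  layout <- tiny_layout()
  n <- 200
  chrom <- sort(sample(layout$chrom, n, replace = TRUE))
  pos <- unlist(lapply(split(seq_len(n), chrom), function(i) {
    sort(sample.int(9e4, length(i)))
  }))
  snp <- paste0("s", seq_len(n))
  panel <- snp_panel(snp, chrom, pos, rep(0.2, n), layout)
  loci <- lapply(seq_len(n_loci), function(i) {
    idx <- sample(panel$snps$snp, 1)
    prox <- unique(c(idx, sample(panel$snps$snp, sample.int(6, 1))))
    structure(list(index = idx, proxies = prox, r2_threshold = 0.8),
              class = "locus")
  })
  names(loci) <- vapply(loci, `[[`, character(1), "index")
  class(loci) <- "locus_list"
  list(panel = panel, loci = loci, layout = layout)
}

# A deterministic point-mass PWM on the given consensus.
consensus_pwm <- function(name, consensus, threshold = NULL,
                          p_major = 0.97) {
  L <- nchar(consensus)
  probs <- matrix((1 - p_major) / 3, L, 4)
  hit <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  probs[cbind(seq_len(L), hit)] <- p_major
  pm <- pwm(name, probs, threshold = 0, consensus = consensus)
  if (is.null(threshold)) {
    pm$threshold <- sum(apply(pm$lodds, 1, max)) - 1
  } else pm$threshold <- threshold
  pm
}
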