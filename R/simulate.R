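#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator with defaults that
#' emulate the study conditions the pipeline targets: 18 GWAS index SNPs,
#' 10,000 matched background sets, index SNPs placed inside open chromatin
#' with probability 0.7 against a background SNP-in-OCR rate of about 0.2,
#' and a stratified polygenic GWAS with planted per-annotation effects.
#'
#' @param seed Root seed; named substreams (panel / landscape / index /
#'   gwas) are derived from it so stages can be regenerated independently.
#' @param n_snps,n_haplotypes,n_chromosomes Panel dimensions.
#' @param snp_spacing_bp Mean SNP spacing; chromosome lengths follow.
#' @param block_size_bp LD block size (bp).
#' @param rho Within-block LD strength in `[0, 1)`: expected within-block
#'   r-squared is about `rho^2`.
#' @param maf_beta Beta-distribution shape parameters of the MAF spectrum
#'   (drawn, then folded into `[maf_min, 0.5]`).
#' @param maf_min Lower MAF truncation (keeps SNPs reliably polymorphic at
#'   small haplotype counts).
#' @param n_genes,gene_width_bp Gene annotation.
#' @param n_ocrs Number of open-chromatin regions; when `NULL` it is set
#'   so that about `background_overlap_rate` of SNPs fall inside an OCR.
#' @param ocr_width_bp OCR width.
#' @param motif_plant_plan Named numeric vector: fraction of OCRs that get
#'   an exact consensus site planted, per motif.
#' @param n_index_snps Size of the index SNP set.
#' @param index_overlap_prob Probability an index SNP is drawn from inside
#'   an OCR (0.7 plants an excess over the ~0.2 background rate; set equal
#'   to the background rate, or to `NA` for uniform panel draws, for a
#'   null scenario).
#' @param background_overlap_rate Target fraction of panel SNPs inside
#'   OCRs.
#' @param n_gwas GWAS sample size for simulated summary statistics.
#' @param h2_total Total SNP heritability in `[0, 1)`; 0 gives the pure
#'   null (`chi2 ~ chi-square(1)`).
#' @param tau_plan Named list or vector of per-category enrichment factors
#'   used by [simulate_gwas()] (`1` everywhere is the null).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_snps = 2000L, n_haplotypes = 200L,
                       n_chromosomes = 2L, snp_spacing_bp = 500,
                       block_size_bp = 10000, rho = 0.9,
                       maf_beta = c(0.8, 1.6), maf_min = 0.05,
                       n_genes = 60L, gene_width_bp = 2000,
                       n_ocrs = NULL, ocr_width_bp = 300,
                       motif_plant_plan = c(SPI1 = 0.3),
                       n_index_snps = 18L, index_overlap_prob = 0.7,
                       background_overlap_rate = 0.2,
                       n_gwas = 50000, h2_total = 0.5,
                       tau_plan = c(focal = 5)) {
  cfg <- list(seed = as.integer(seed), n_snps = as.integer(n_snps),
              n_haplotypes = as.integer(n_haplotypes),
              n_chromosomes = as.integer(n_chromosomes),
              snp_spacing_bp = snp_spacing_bp,
              block_size_bp = block_size_bp, rho = rho,
              maf_beta = maf_beta, maf_min = maf_min,
              n_genes = as.integer(n_genes),
              gene_width_bp = gene_width_bp, n_ocrs = n_ocrs,
              ocr_width_bp = ocr_width_bp,
              motif_plant_plan = motif_plant_plan,
              n_index_snps = as.integer(n_index_snps),
              index_overlap_prob = index_overlap_prob,
              background_overlap_rate = background_overlap_rate,
              n_gwas = n_gwas, h2_total = h2_total, tau_plan = tau_plan)
  stopifnot(cfg$n_snps > 0, cfg$n_haplotypes > 1, cfg$n_chromosomes > 0,
            cfg$rho >= 0, cfg$rho < 1,
            is.na(cfg$index_overlap_prob) ||
              (cfg$index_overlap_prob >= 0 && cfg$index_overlap_prob <= 1),
            cfg$background_overlap_rate > 0,
            cfg$background_overlap_rate < 1,
            cfg$h2_total >= 0, cfg$h2_total < 1)
  if (cfg$n_haplotypes < 50) {
    warning("fewer than 50 haplotypes: LD estimates will be unstable")
  }
  class(cfg) <- "sim_config"
  cfg
}

# Derived seeds stay below 2^31.
.substream <- function(cfg, name) {
  offs <- c(panel = 11L, landscape = 23L, index = 37L, gwas = 51L,
            matching = 67L)
  (cfg$seed * 1000L + offs[[name]]) %% .Machine$integer.max
}

#' Simulate a SNP panel with block LD
#'
#' Haplotypes are generated blockwise: each LD block has a latent binary
#' haplotype; every SNP in the block copies the latent allele with
#' probability `sqrt(rho)` (independently per haplotype) and otherwise
#' draws a fresh allele at the block frequency. Pairs of SNPs within a
#' block then correlate at about `rho` (r-squared about `rho^2`) while
#' cross-block r-squared vanishes as the haplotype count grows. MAF is
#' recomputed from the realised haplotypes; monomorphic draws are redrawn.
#'
#' @param config A [sim_config()].
#' @return List with `panel` (a [snp_panel()]), `haplotypes`, and
#'   `layout`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(.substream(config, "panel"), {
    n_chr <- config$n_chromosomes
    per_chr <- diff(round(seq(0, config$n_snps, length.out = n_chr + 1)))
    chrom_len <- pmax(per_chr * config$snp_spacing_bp + 1e4, 1e5)
    layout <- genome_layout(stats::setNames(chrom_len,
                                            paste0("chr", seq_len(n_chr))))
    copy_p <- sqrt(config$rho)
    snp <- character(0); chrom <- character(0); pos <- numeric(0)
    hap_cols <- list()
    counter <- 0L
    for (ci in seq_len(n_chr)) {
      m <- per_chr[ci]
      if (!m) next
      p <- sort(sample.int(chrom_len[ci] - 1000L, m))
      block <- (p - 1) %/% config$block_size_bp
      for (bl in unique(block)) {
        in_bl <- which(block == bl)
        f <- config$maf_min +
          (0.5 - config$maf_min) * stats::rbeta(1, config$maf_beta[1],
                                                config$maf_beta[2])
        z <- stats::rbinom(config$n_haplotypes, 1L, f)
        for (k in in_bl) {
          for (try in 1:50) {
            keep <- stats::rbinom(config$n_haplotypes, 1L, copy_p) == 1L
            u <- stats::rbinom(config$n_haplotypes, 1L, f)
            col <- ifelse(keep, z, u)
            if (stats::var(col) > 0) break
          }
          counter <- counter + 1L
          hap_cols[[counter]] <- col
        }
      }
      snp <- c(snp, sprintf("rs%d_%d", ci, seq_len(m)))
      chrom <- c(chrom, rep(paste0("chr", ci), m))
      pos <- c(pos, p)
    }
    h <- do.call(cbind, hap_cols)
    colnames(h) <- snp
    freq <- colMeans(h)
    panel <- snp_panel(snp, chrom, pos, pmin(freq, 1 - freq), layout)
    h <- h[, panel$snps$snp, drop = FALSE]
    class(h) <- c("haplotype_matrix", class(h))
    list(panel = panel, haplotypes = h, layout = layout)
  })
}

.random_dna <- function(n) {
  paste0(sample(BASES, n, replace = TRUE), collapse = "")
}

#' Simulate genes, open-chromatin regions and genome sequence
#'
#' Places gene intervals uniformly, anchors OCRs on randomly chosen SNPs
#' so that about `background_overlap_rate` of panel SNPs fall inside an
#' OCR, generates i.i.d. uniform background sequence, and plants exact
#' motif consensus sites into an exact count of OCRs per motif (recorded
#' as ground truth).
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_panel()].
#' @param pwms Named list of [pwm()]s to plant (defaults to a built-in
#'   SPI1-like and MEF2-like pair, subset to the names in
#'   `config$motif_plant_plan`).
#' @param genes_avoid_ocrs Re-place genes that touch OCRs (for tests that
#'   need them disjoint).
#' @return List with `genes`, `ocrs` (interval sets), `genome_seq`
#'   (named `DNAStringSet`), `pwms`, and `truth` (per-OCR planted motif
#'   membership matrix).
#' @export
simulate_regulatory_landscape <- function(config, sim, pwms = NULL,
                                          genes_avoid_ocrs = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  panel <- sim$panel; layout <- sim$layout
  if (is.null(pwms)) {
    pwms <- builtin_pwms()[names(config$motif_plant_plan)]
    if (anyNA(names(pwms))) {
      stop("no built-in PWM for: ",
           paste(setdiff(names(config$motif_plant_plan),
                         names(builtin_pwms())), collapse = ", "))
    }
  }
  with_seed(.substream(config, "landscape"), {
    df <- panel$snps
    w <- config$ocr_width_bp
    anchors <- integer(0)
    if (is.null(config$n_ocrs)) {
      # Open chromatin clusters with respect to LD structure: whole LD
      # blocks are selected until the target fraction of panel SNPs is
      # covered, and every SNP of a selected block is covered by an OCR.
      # Both the SNP-level and the locus-level background overlap rates
      # then track config$background_overlap_rate (scattering OCRs
      # independently of blocks would saturate locus-level overlap, since
      # a locus overlaps if any of its ~block-sized proxy set does).
      block <- paste0(df$chrom, ":", (df$pos - 1) %/% config$block_size_bp)
      target <- round(config$background_overlap_rate * nrow(df))
      covered <- 0L
      for (bl in sample(unique(block))) {
        if (covered >= target) break
        in_bl <- which(block == bl)
        anchors <- c(anchors, in_bl)
        covered <- covered + length(in_bl)
      }
    } else {
      anchors <- sample.int(nrow(df), min(config$n_ocrs, nrow(df)))
    }
    centre <- df$pos[anchors] - 1
    start <- pmax(0, centre - sample.int(w - 2L, length(anchors),
                                         replace = TRUE))
    end <- pmin(unname(layout$lengths[df$chrom[anchors]]), start + w)
    ocrs <- merge_intervals(interval_set(df$chrom[anchors], start, end,
                                         layout, label = "ocrs"),
                            label = "ocrs")
    place_genes <- function() {
      gchr <- sample(layout$chrom, config$n_genes, replace = TRUE,
                     prob = layout$lengths / sum(layout$lengths))
      gstart <- floor(stats::runif(config$n_genes) *
                        (layout$lengths[gchr] - config$gene_width_bp))
      interval_set(gchr, gstart, gstart + config$gene_width_bp, layout,
                   label = "genes")
    }
    genes <- place_genes()
    if (genes_avoid_ocrs) {
      for (try in 1:200) {
        hit <- IRanges::overlapsAny(genes$gr, ocrs$gr)
        if (!any(hit)) break
        gdf <- as.data.frame(genes)
        redo <- which(hit)
        gchr <- sample(layout$chrom, length(redo), replace = TRUE,
                       prob = layout$lengths / sum(layout$lengths))
        gdf$chrom[redo] <- gchr
        gdf$start[redo] <- floor(stats::runif(length(redo)) *
                                   (layout$lengths[gchr] -
                                      config$gene_width_bp))
        gdf$end[redo] <- gdf$start[redo] + config$gene_width_bp
        genes <- interval_set(gdf$chrom, gdf$start, gdf$end, layout,
                              label = "genes")
      }
    }
    seqs <- lapply(layout$lengths, .random_dna)
    odf <- as.data.frame(ocrs)
    truth <- matrix(FALSE, nrow = nrow(odf), ncol = length(pwms),
                    dimnames = list(NULL, names(pwms)))
    occupied <- vector("list", nrow(odf))  # planted ranges, per OCR
    for (m in names(pwms)) {
      cons <- pwms[[m]]$consensus
      L <- nchar(cons)
      frac <- config$motif_plant_plan[[m]]
      k <- round(frac * nrow(odf))
      if (!k) next
      chosen <- sample.int(nrow(odf), k)
      for (i in chosen) {
        width_i <- odf$end[i] - odf$start[i]
        if (width_i < L) next
        for (try in 1:50) {
          off <- sample.int(width_i - L + 1L, 1L)
          span <- off:(off + L - 1L)
          if (!length(occupied[[i]]) ||
              !any(span %in% unlist(occupied[[i]]))) break
        }
        occupied[[i]] <- c(occupied[[i]], list(span))
        at <- odf$start[i] + off  # 1-based start in chromosome string
        substr(seqs[[odf$chrom[i]]], at, at + L - 1L) <- cons
        truth[i, m] <- TRUE
      }
    }
    genome_seq <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome_seq) <- layout$chrom
    list(genes = genes, ocrs = ocrs, genome_seq = genome_seq, pwms = pwms,
         truth = truth)
  })
}

#' Precompute per-chromosome LD correlation matrices
#'
#' Signed allelic correlation matrices, one per chromosome, for reuse
#' across repeated GWAS simulations on the same panel. `window_bp`
#' truncates correlations to a bp window; for simulating GWAS statistics
#' this should match the generator's true LD support (the block size):
#' marginal z-statistics of a large study are correlated only through
#' population LD, and the small panel's cross-block sampling noise must
#' not be baked into them.
#'
#' @param sim Output of [simulate_panel()].
#' @param window_bp Optional truncation window (bp); `NULL` keeps the
#'   full empirical correlation.
#' @return Named list of matrices keyed by chromosome.
#' @export
precompute_ld <- function(sim, window_bp = NULL) {
  panel <- sim$panel
  out <- list()
  for (ch in unique(panel$snps$chrom)) {
    on_ch <- which(panel$snps$chrom == ch)
    out[[ch]] <- .chrom_cor(sim$haplotypes, on_ch, panel$snps$pos[on_ch],
                            window_bp = window_bp)
  }
  out
}

#' Built-in demonstration PWMs
#'
#' A small library of near-deterministic PWMs with distinct consensus
#' sequences (an SPI1-like purine-rich core, a MEF2-like AT-rich core, a
#' CEBP-like palindrome and an EGR1-like GC-rich core), with thresholds
#' set one bit below the consensus score so only exact or near-exact sites
#' are detected.
#'
#' @return Named list of [pwm()] objects.
#' @export
builtin_pwms <- function() {
  mk <- function(name, consensus, p_major = 0.97) {
    L <- nchar(consensus)
    probs <- matrix((1 - p_major) / 3, nrow = L, ncol = 4,
                    dimnames = list(NULL, BASES))
    hit <- match(strsplit(consensus, "")[[1]], BASES)
    probs[cbind(seq_len(L), hit)] <- p_major
    pm <- pwm(name, probs, threshold = 0, consensus = consensus)
    max_score <- sum(apply(pm$lodds, 1, max))
    pm$threshold <- max_score - 1
    pm
  }
  # 12-bp consensus: long enough that chance exact hits in uniform
  # background are negligible across a whole synthetic landscape
  list(SPI1 = mk("SPI1", "AAAGAGGAAGTG"),
       MEF2 = mk("MEF2", "GCTATTTATAGC"),
       CEBP = mk("CEBP", "TATTGCGCAATA"),
       EGR1 = mk("EGR1", "ACGCCCACGCAC"))
}

#' Simulate index SNPs with a planted open-chromatin excess
#'
#' Each index SNP is drawn (without replacement) from the SNPs inside an
#' OCR with probability `index_overlap_prob`, otherwise from the SNPs
#' outside, so the index set carries a controlled excess of OCR overlap
#' over the background rate. With `index_overlap_prob = NA` the index
#' SNPs are drawn uniformly from the whole panel (the exact null).
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_panel()].
#' @param ocrs The OCR [interval_set()].
#' @return List with `index` (SNP ids) and `truth` (logical: drawn from
#'   inside an OCR).
#' @export
simulate_index_snps <- function(config, sim, ocrs) {
  stopifnot(inherits(config, "sim_config"))
  df <- sim$panel$snps
  inside_all <- which(point_overlaps(ocrs, df$chrom, df$pos))
  outside_all <- setdiff(seq_len(nrow(df)), inside_all)
  if (is.na(config$index_overlap_prob)) {
    return(with_seed(.substream(config, "index"), {
      picks <- sample.int(nrow(df), config$n_index_snps)
      list(index = df$snp[picks], truth = picks %in% inside_all)
    }))
  }
  if (length(inside_all) < config$n_index_snps ||
      length(outside_all) < config$n_index_snps) {
    stop("not enough SNPs inside/outside OCRs to draw ",
         config$n_index_snps, " index SNPs")
  }
  with_seed(.substream(config, "index"), {
    want_in <- stats::rbinom(config$n_index_snps, 1L,
                             config$index_overlap_prob) == 1L
    inside <- sample(inside_all)
    outside <- sample(outside_all)
    picks <- integer(config$n_index_snps)
    ni <- 0L; no <- 0L
    for (s in seq_len(config$n_index_snps)) {
      if (want_in[s]) { ni <- ni + 1L; picks[s] <- inside[ni] }
      else { no <- no + 1L; picks[s] <- outside[no] }
    }
    list(index = df$snp[picks], truth = want_in)
  })
}

#' Simulate GWAS summary statistics under the stratified polygenic model
#'
#' Per-SNP effects are drawn as `beta_j ~ Normal(0, sigma2_j)` where
#' `sigma2_j` depends on annotation membership; marginal z-statistics are
#' `z_j ~ Normal(sqrt(N) * sum_k r_jk beta_k, 1)` using the panel's
#' per-chromosome LD, and `chi2_j = z_j^2`, so that
#' `E[chi2_j] = 1 + N * sum_c tau_c * l(j,c)` — exactly the model the
#' stratified regression fits.
#'
#' Per-SNP variances are scaled so the total equals `h2_total`. The
#' `tau_plan` entries are per-category enrichment factors on the per-SNP
#' variance: a category with factor 5 gives its SNPs five times the
#' per-SNP effect variance of the remainder (factor 1 everywhere is the
#' null). Categories are taken from `annotations` columns (excluding
#' `base`); a plan entry with no matching column is an error.
#'
#' @param config A [sim_config()].
#' @param sim Output of [simulate_panel()].
#' @param annotations An [annotate_snps()] matrix (may be base-only).
#' @param tau_plan Named per-category variance enrichment factors;
#'   defaults to `config$tau_plan` matched by name, with 1 for categories
#'   not named.
#' @param ld Optional precomputed per-chromosome signed correlation
#'   matrices (as from [precompute_ld()]); avoids recomputation across
#'   replicates in simulation studies.
#' @return List with `stats` (a `sumstats` data frame) and `truth`
#'   (per-category true tau, per-SNP variances, true enrichment).
#' @export
simulate_gwas <- function(config, sim, annotations, tau_plan = NULL,
                          ld = NULL) {
  stopifnot(inherits(config, "sim_config"))
  a <- unclass(annotations)
  panel <- sim$panel
  M <- nrow(a)
  stopifnot(M == nrow(panel$snps))
  cats <- setdiff(colnames(a), "base")
  if (is.null(tau_plan)) {
    tau_plan <- stats::setNames(rep(1, length(cats)), cats)
    hit <- intersect(names(config$tau_plan), cats)
    tau_plan[hit] <- config$tau_plan[hit]
  }
  if (!all(names(tau_plan) %in% cats)) {
    stop("tau_plan names must match annotation categories: ",
         paste(setdiff(names(tau_plan), cats), collapse = ", "))
  }
  # Per-SNP relative variance chosen so each planned category's realised
  # heritability enrichment (h2 share / SNP share) equals its plan factor:
  # for one category with SNP share s and target E, members get
  # f = E(1-s) / (1-sE) times the variance of the rest. With several
  # planned categories the correction is iterated to a fixed point.
  rel <- rep(1, M)
  planted <- names(tau_plan)[unlist(tau_plan) != 1]
  for (ct in planted) {
    if (mean(a[, ct] == 1) * tau_plan[[ct]] >= 1) {
      stop("tau_plan enrichment ", tau_plan[[ct]], " for '", ct,
           "' infeasible at SNP share ", round(mean(a[, ct] == 1), 3))
    }
  }
  for (iter in seq_len(50 * max(1, length(planted)))) {
    moved <- FALSE
    for (ct in planted) {
      mem <- a[, ct] == 1
      cur <- mean(rel[mem]) / mean(rel)
      if (abs(cur - tau_plan[[ct]]) > 1e-10) {
        rel[mem] <- rel[mem] * tau_plan[[ct]] / cur
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  sigma2 <- rel * (config$h2_total / sum(rel))
  if (sum(sigma2) > 1) stop("implied heritability exceeds 1")
  if (is.null(ld)) ld <- precompute_ld(sim, window_bp =
                                         config$block_size_bp)
  with_seed(.substream(config, "gwas"), {
    beta <- stats::rnorm(M, 0, sqrt(sigma2))
    z <- numeric(M)
    for (ch in names(ld)) {
      on_ch <- which(panel$snps$chrom == ch)
      mu <- sqrt(config$n_gwas) * as.numeric(ld[[ch]] %*% beta[on_ch])
      z[on_ch] <- stats::rnorm(length(on_ch), mu, 1)
    }
    stats <- data.frame(snp = panel$snps$snp, chrom = panel$snps$chrom,
                        pos = panel$snps$pos, chi2 = z^2,
                        n_gwas = config$n_gwas, stringsAsFactors = FALSE)
    class(stats) <- c("sumstats", class(stats))
    true_tau <- vapply(colnames(a), function(ct) {
      mean(sigma2[a[, ct] == 1])
    }, numeric(1))
    h2_c <- vapply(colnames(a), function(ct) sum(sigma2[a[, ct] == 1]),
                   numeric(1))
    true_enr <- (h2_c / sum(sigma2)) / (colSums(a) / M)
    list(stats = stats,
         truth = list(sigma2 = sigma2, beta = beta,
                      true_tau = true_tau, true_enrichment = true_enr,
                      h2_total = sum(sigma2)))
  })
}

#' Generate and write a complete synthetic input bundle
#'
#' Runs the full generator and writes every file the pipeline consumes:
#' `panel.hap`, `genes.bed`, `ocrs.bed`, `genome.fa`, `motifs.motif`,
#' `index_snps.tsv`, `sumstats.tsv` and `truth.json`.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if absent).
#' @param gwas_focal Optional name of a motif whose planted OCR subset
#'   (extended by `flank`) becomes the focal heritability annotation;
#'   defaults to the first motif in the plant plan.
#' @param flank Flank (bp) applied to the focal subset before annotation.
#' @return Invisibly, a list with the in-memory objects and file paths.
#' @export
simulate_bundle <- function(config, dir, gwas_focal = NULL, flank = 500) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulate_panel(config)
  land <- simulate_regulatory_landscape(config, sim)
  idx <- simulate_index_snps(config, sim, land$ocrs)
  if (is.null(gwas_focal)) gwas_focal <- names(config$motif_plant_plan)[1]
  odf <- as.data.frame(land$ocrs)
  keep <- land$truth[, gwas_focal]
  focal <- if (any(keep)) {
    extend_intervals(interval_set(odf$chrom[keep], odf$start[keep],
                                  odf$end[keep], sim$layout,
                                  label = gwas_focal), flank)
  } else NULL
  sets <- if (is.null(focal)) list() else stats::setNames(list(focal),
                                                          gwas_focal)
  ann <- annotate_snps(sim$panel, sets)
  plan <- if (is.null(focal)) NULL else
    stats::setNames(config$tau_plan[[1]], gwas_focal)
  gwas <- simulate_gwas(config, sim, ann, tau_plan = plan)
  paths <- list(
    hap = file.path(dir, "panel.hap"),
    genes = file.path(dir, "genes.bed"),
    ocrs = file.path(dir, "ocrs.bed"),
    genome = file.path(dir, "genome.fa"),
    motifs = file.path(dir, "motifs.motif"),
    index = file.path(dir, "index_snps.tsv"),
    sumstats = file.path(dir, "sumstats.tsv"),
    truth = file.path(dir, "truth.json"))
  write_hap(sim$panel, sim$haplotypes, paths$hap)
  write_bed(land$genes, paths$genes)
  write_bed(land$ocrs, paths$ocrs)
  Biostrings::writeXStringSet(land$genome_seq, paths$genome)
  write_pwm(land$pwms, paths$motifs)
  utils::write.table(
    data.frame(id = idx$index,
               chrom = sim$panel$snps$chrom[match(idx$index,
                                                  sim$panel$snps$snp)],
               pos = sim$panel$snps$pos[match(idx$index,
                                              sim$panel$snps$snp)]),
    paths$index, sep = "\t", quote = FALSE, row.names = FALSE)
  write_sumstats(gwas$stats, paths$sumstats)
  truth <- list(
    seed = config$seed,
    chrom_lengths = as.list(sim$layout$lengths),
    motif_membership = lapply(seq_len(ncol(land$truth)), function(j) {
      which(land$truth[, j]) }),
    index_inside_ocr = idx$truth,
    true_tau = gwas$truth$true_tau,
    true_enrichment = gwas$truth$true_enrichment,
    h2_total = gwas$truth$h2_total)
  names(truth$motif_membership) <- colnames(land$truth)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(config = config, sim = sim, landscape = land,
                 index = idx, annotations = ann, gwas = gwas,
                 paths = paths))
}
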