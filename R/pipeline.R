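#' Assemble a pipeline run configuration
#'
#' @param inputs Named list of input paths: `hap` (haplotype panel),
#'   `index` (index SNP TSV: id, chrom, 1-based pos), `genes` (BED),
#'   `peaks` (BED of open-chromatin regions), and optionally `motifs`
#'   (HOMER-style PWMs), `genome` (FASTA) and `sumstats` (TSV) for the
#'   motif-partition and heritability stages.
#' @param stages Stages to run, in order, from `"enrich"`,
#'   `"motif-partition"`, `"partition-h2"`.
#' @param out_dir Output directory for tables and the JSON report.
#' @param n_sets,seed Matched-set sampling.
#' @param r2_threshold,window_bp LD expansion.
#' @param tol_maf,tol_frac Matching tolerances.
#' @param correction `"BH"` or `"bonferroni"`; `m` the optional test count.
#' @param flank Flank (bp) applied to annotations in the heritability
#'   stage.
#' @param min_nonzero Low-power filter threshold for motif subsets.
#' @param exclude `"default"` (packaged MHC/APOE regions), `"none"`, or a
#'   BED path.
#' @param n_blocks Jackknife blocks for the heritability stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(inputs, stages = c("enrich", "motif-partition",
                                          "partition-h2"),
                       out_dir = tempfile("ocrenrich_run"),
                       n_sets = 10000, seed = 1L, r2_threshold = 0.8,
                       window_bp = 1e6, tol_maf = 0.05, tol_frac = 0.5,
                       correction = c("BH", "bonferroni"), m = NULL,
                       flank = 500, min_nonzero = 1000,
                       exclude = "default", n_blocks = 200) {
  stages <- match.arg(stages, c("enrich", "motif-partition",
                                "partition-h2"), several.ok = TRUE)
  correction <- match.arg(correction)
  structure(list(inputs = inputs, stages = stages, out_dir = out_dir,
                 n_sets = n_sets, seed = as.integer(seed),
                 r2_threshold = r2_threshold, window_bp = window_bp,
                 tol_maf = tol_maf, tol_frac = tol_frac,
                 correction = correction, m = m, flank = flank,
                 min_nonzero = min_nonzero, exclude = exclude,
                 n_blocks = n_blocks),
            class = "run_config")
}

#' Read a YAML run configuration
#'
#' The YAML mirrors the arguments of [run_config()]: an `inputs:` block
#' of paths plus top-level parameters.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), "inputs")]
  do.call(run_config, c(list(inputs = y$inputs), args))
}

.stage_fail <- function(stage, msg) {
  stop("pipeline stage '", stage, "': ", msg, call. = FALSE)
}

.need_input <- function(config, what, stage) {
  p <- config$inputs[[what]]
  if (is.null(p)) .stage_fail(stage, paste0("missing input '", what, "'"))
  if (!file.exists(p)) {
    .stage_fail(stage, paste0("input file not found: ", p))
  }
  p
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order — exclusion filtering, LD
#' expansion, matched-background sampling, open-chromatin enrichment
#' (whole peak set, then per-motif subsets with the low-power filter),
#' and heritability partitioning — writing tab-separated result tables
#' and a JSON run report to `config$out_dir`. Re-running with the same
#' configuration and seed reproduces every output.
#'
#' @param config A [run_config()] or path to a YAML file.
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  if (!dir.exists(config$out_dir)) dir.create(config$out_dir,
                                              recursive = TRUE)
  report <- list(package_version =
                   as.character(utils::packageVersion("ocrenrich")),
                 seed = config$seed,
                 parameters = config[setdiff(names(config),
                                             c("inputs", "out_dir"))],
                 stages = list())
  # shared inputs
  hap_path <- .need_input(config, "hap", "setup")
  genes_path <- .need_input(config, "genes", "setup")
  # layout is inferred from the haplotype panel with generous tail room
  hp_lines <- readLines(hap_path)
  fields <- strsplit(trimws(hp_lines[-1]), "[ \t]+")
  chrom_all <- vapply(fields, `[[`, character(1), 2L)
  pos_all <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  lens <- tapply(pos_all, chrom_all, max) * 1.1 + 1e4
  layout <- genome_layout(lens[unique(chrom_all)])
  hp <- read_hap(hap_path, layout)
  panel <- hp$panel; h <- hp$haplotypes
  excl <- if (identical(config$exclude, "none")) {
    interval_set(character(), integer(), integer(), layout,
                 label = "exclusions")
  } else if (identical(config$exclude, "default")) {
    default_exclusions(layout)
  } else read_bed(config$exclude, layout, label = "exclusions",
                  unknown_chrom = "skip")
  genes <- read_bed(genes_path, layout, label = "genes")
  peaks <- NULL; assignment <- NULL
  if ("enrich" %in% config$stages || "partition-h2" %in% config$stages) {
    peaks_path <- .need_input(config, "peaks", "enrichment")
    peaks <- merge_intervals(read_bed(peaks_path, layout, label = "peaks"))
  }
  if ("motif-partition" %in% config$stages) {
    motifs_path <- .need_input(config, "motifs", "motif-partition")
    genome_path <- .need_input(config, "genome", "motif-partition")
    pwms <- read_pwm(motifs_path)
    genome_seq <- Biostrings::readDNAStringSet(genome_path)
    names(genome_seq) <- sub("\\s.*", "", names(genome_seq))
    assignment <- partition_by_motif(peaks, genome_seq, pwms)
    write_motif_subsets(assignment, file.path(config$out_dir,
                                              "motif_subsets"))
    report$stages$motif_partition <- list(
      n_ocrs = nrow(assignment$membership),
      per_motif = as.list(colSums(assignment$membership)),
      n_no_motif = sum(rowSums(assignment$membership) == 0))
  }
  if ("enrich" %in% config$stages) {
    index_path <- .need_input(config, "index", "enrichment")
    idx_df <- utils::read.table(index_path, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
    names(idx_df) <- tolower(names(idx_df))
    if (!all(c("id") %in% names(idx_df))) {
      .stage_fail("enrichment", "index SNP file needs an 'id' column")
    }
    index_ids <- as.character(idx_df$id)
    keep <- !point_overlaps(excl, panel$snps$chrom[
      .panel_index(panel, index_ids)], panel$snps$pos[
        .panel_index(panel, index_ids)])
    n_excluded <- sum(!keep)
    index_ids <- index_ids[keep]
    if (!length(index_ids)) .stage_fail("enrichment",
                                        "no index SNPs after exclusions")
    index_loci <- ld_expand(index_ids, panel, h,
                            r2_threshold = config$r2_threshold,
                            window_bp = config$window_bp)
    cov <- compute_match_covariates(panel, h, genes,
                                    window_bp = config$window_bp)
    matched <- draw_matched_sets(index_ids, cov, n_sets = config$n_sets,
                                 tol_maf = config$tol_maf,
                                 tol_frac = config$tol_frac,
                                 seed = config$seed, exclude = excl,
                                 panel = panel)
    test_sets <- list(peaks = peaks)
    if (!is.null(assignment)) test_sets <- c(test_sets, assignment$subsets)
    rows <- list()
    for (nm in names(test_sets)) {
      if (!length(test_sets[[nm]]$gr)) next
      res <- enrichment_test(index_loci, matched, test_sets[[nm]], panel,
                             h, r2_threshold = config$r2_threshold,
                             window_bp = config$window_bp,
                             annotation_label = nm)
      kept <- filter_low_power_sets(res$background_counts,
                                    min_nonzero = config$min_nonzero,
                                    quiet = TRUE)
      rows[[nm]] <- data.frame(
        annotation_label = nm, n_loci = res$n_loci,
        observed = res$observed, bg_mean = res$bg_mean,
        bg_sd = res$bg_sd, z = res$z, p_empirical = res$p_empirical,
        kept_after_power_filter = as.logical(kept),
        stringsAsFactors = FALSE)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    keep_rows <- tab$kept_after_power_filter
    tab$p_corrected <- NA_real_
    tab$p_corrected[keep_rows] <- adjust_pvalues(
      tab$p_empirical[keep_rows], method = config$correction,
      m = if (is.null(config$m)) sum(keep_rows) else config$m)
    utils::write.table(tab, file.path(config$out_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$enrichment <- list(
      n_index_snps = length(index_ids),
      n_index_excluded = n_excluded,
      n_sets = config$n_sets,
      correction = config$correction,
      m = if (is.null(config$m)) sum(keep_rows) else config$m,
      results = tab)
  }
  if ("partition-h2" %in% config$stages) {
    sum_path <- .need_input(config, "sumstats", "partition-h2")
    stats <- read_sumstats(sum_path)
    panel_x <- exclude_regions(panel, excl, quiet = TRUE)
    h_x <- h[, panel_x$snps$snp, drop = FALSE]
    stats <- stats[stats$snp %in% panel_x$snps$snp, , drop = FALSE]
    focal <- if (!is.null(assignment)) {
      assignment$subsets[vapply(assignment$subsets,
                                function(s) length(s$gr) > 0, logical(1))]
    } else stats::setNames(list(peaks), "peaks")
    focal <- lapply(focal, extend_intervals, flank = config$flank)
    part <- run_single_annotation_models(stats, panel_x, h_x, focal,
                                         window_bp = config$window_bp,
                                         n_blocks = config$n_blocks,
                                         m = config$m)
    utils::write.table(as.data.frame(part),
                       file.path(config$out_dir, "h2_partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$stages$h2_partition <- list(
      baseline = "simplified baseline (all-SNPs category)",
      flank = config$flank, n_snps = nrow(panel_x$snps),
      results = as.data.frame(part))
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
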