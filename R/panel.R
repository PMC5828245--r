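#' Construct a SNP panel
#'
#' The SNP universe: identifiers, 1-based positions and minor-allele
#' frequencies. Positions must be strictly increasing within each
#' chromosome; ids must be unique; MAF lies in (0, 0.5].
#'
#' @param snp Character vector of SNP ids.
#' @param chrom Chromosome label per SNP.
#' @param pos 1-based position per SNP.
#' @param maf Minor-allele frequency per SNP.
#' @param layout A [genome_layout()].
#' @return An object of class `snp_panel` with a `snps` data frame.
#' @export
snp_panel <- function(snp, chrom, pos, maf, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  snp <- as.character(snp)
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  maf <- as.numeric(maf)
  n <- length(snp)
  if (length(chrom) != n || length(pos) != n || length(maf) != n) {
    stop("snp, chrom, pos, maf must have equal length")
  }
  if (anyDuplicated(snp)) stop("SNP ids must be unique")
  unknown <- setdiff(unique(chrom), layout$chrom)
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  if (any(pos < 1 | pos > layout$lengths[chrom])) {
    stop("SNP positions must lie in [1, chromosome length]")
  }
  if (any(!is.finite(maf)) || any(maf <= 0 | maf > 0.5)) {
    stop("maf must lie in (0, 0.5]")
  }
  ord <- order(match(chrom, layout$chrom), pos)
  snp <- snp[ord]; chrom <- chrom[ord]; pos <- pos[ord]; maf <- maf[ord]
  same <- chrom[-1] == chrom[-n]
  if (n > 1 && any(same & diff(pos) <= 0)) {
    stop("positions must be strictly increasing within a chromosome")
  }
  structure(list(snps = data.frame(snp = snp, chrom = chrom, pos = pos,
                                   maf = maf, stringsAsFactors = FALSE),
                 layout = layout),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat("<snp_panel> ", nrow(x$snps), " SNPs on ",
      length(unique(x$snps$chrom)), " chromosome(s); MAF ",
      sprintf("%.3f-%.3f", min(x$snps$maf), max(x$snps$maf)), "\n", sep = "")
  invisible(x)
}

#' @export
length.snp_panel <- function(x) nrow(x$snps)

.panel_index <- function(panel, snps) {
  idx <- match(snps, panel$snps$snp)
  if (anyNA(idx)) {
    stop("SNP(s) not in panel: ",
         paste(utils::head(snps[is.na(idx)], 5), collapse = ", "))
  }
  idx
}

#' Read a haplotype panel
#'
#' Reads the simple text haplotype format: a header line `#HAP n_hap=<N>`
#' followed by one row per SNP, `snp_id chrom pos a1 a2 <N binary chars>`
#' (whitespace-separated; the allele string is `N` characters of 0/1, with
#' 1 meaning the a2 allele). Monomorphic SNPs are dropped with a message;
#' MAF in the returned panel is computed from the haplotypes.
#'
#' @param path Path to a `.hap` file.
#' @param layout A [genome_layout()].
#' @return A list with `panel` (a [snp_panel()]) and `haplotypes`
#'   (a `haplotype_matrix`: haplotypes in rows, SNPs in columns, entries
#'   0/1, columns named by SNP id).
#' @export
read_hap <- function(path, layout) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#HAP")) {
    stop("not a haplotype file: missing '#HAP' header")
  }
  n_hap <- as.integer(sub(".*n_hap=([0-9]+).*", "\\1", lines[1]))
  if (is.na(n_hap) || n_hap < 2) stop("invalid n_hap in header")
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  fields <- strsplit(trimws(body), "[ \t]+")
  if (any(lengths(fields) != 6L)) {
    stop("haplotype line ", which(lengths(fields) != 6L)[1] + 1L,
         ": expected 6 fields")
  }
  snp <- vapply(fields, `[[`, character(1), 1L)
  chrom <- vapply(fields, `[[`, character(1), 2L)
  pos <- as.numeric(vapply(fields, `[[`, character(1), 3L))
  alle <- vapply(fields, `[[`, character(1), 6L)
  if (any(nchar(alle) != n_hap)) {
    stop("haplotype line ", which(nchar(alle) != n_hap)[1] + 1L,
         ": allele string length != n_hap")
  }
  if (any(grepl("[^01]", alle))) {
    stop("allele strings must contain only 0/1")
  }
  h <- matrix(0L, nrow = n_hap, ncol = length(snp))
  for (j in seq_along(alle)) {
    h[, j] <- as.integer(charToRaw(alle[j]) == charToRaw("1"))
  }
  colnames(h) <- snp
  freq <- colMeans(h)
  mono <- freq == 0 | freq == 1
  if (any(mono)) {
    message("read_hap: excluding ", sum(mono), " monomorphic SNP(s)")
    h <- h[, !mono, drop = FALSE]
    snp <- snp[!mono]; chrom <- chrom[!mono]; pos <- pos[!mono]
    freq <- freq[!mono]
  }
  panel <- snp_panel(snp, chrom, pos, pmin(freq, 1 - freq), layout)
  h <- h[, panel$snps$snp, drop = FALSE]
  class(h) <- c("haplotype_matrix", class(h))
  list(panel = panel, haplotypes = h)
}

#' Write a haplotype panel
#'
#' Inverse of [read_hap()]. Reference/alternate allele labels are written
#' as `A`/`B` placeholders (the analyses only use the 0/1 indicators).
#'
#' @param panel A [snp_panel()].
#' @param h Haplotype matrix aligned to `panel` (haplotypes x SNPs).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hap <- function(panel, h, path) {
  stopifnot(inherits(panel, "snp_panel"),
            ncol(h) == nrow(panel$snps))
  alle <- apply(h, 2, paste0, collapse = "")
  lines <- c(sprintf("#HAP n_hap=%d", nrow(h)),
             paste(panel$snps$snp, panel$snps$chrom, panel$snps$pos,
                   "A", "B", alle))
  writeLines(lines, path)
  invisible(path)
}

#' Convert a minimal VCF to the haplotype format
#'
#' Accepts an uncompressed, biallelic, fully phased VCF (GT fields like
#' `0|1`) and writes the equivalent `.hap` file. Multi-allelic or unphased
#' records are rejected.
#'
#' @param vcf_path Input VCF path.
#' @param hap_path Output `.hap` path.
#' @return `hap_path`, invisibly.
#' @export
vcf_to_hap <- function(vcf_path, hap_path) {
  lines <- readLines(vcf_path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) stop("VCF has no variant records")
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) < 10L)) stop("VCF records must carry genotypes")
  chrom <- vapply(fields, `[[`, character(1), 1L)
  pos <- vapply(fields, `[[`, character(1), 2L)
  id <- vapply(fields, `[[`, character(1), 3L)
  ref <- vapply(fields, `[[`, character(1), 4L)
  alt <- vapply(fields, `[[`, character(1), 5L)
  if (any(grepl(",", alt, fixed = TRUE))) {
    stop("multi-allelic records are not supported")
  }
  miss <- id == "."
  id[miss] <- paste0(chrom[miss], ":", pos[miss])
  alle <- vapply(seq_along(fields), function(i) {
    gt <- sub(":.*", "", fields[[i]][-(1:9)])
    if (any(!grepl("^[01]\\|[01]$", gt))) {
      stop("record ", i, ": genotypes must be phased biallelic (e.g. 0|1)")
    }
    paste0(unlist(strsplit(gt, "|", fixed = TRUE)), collapse = "")
  }, character(1))
  n_hap <- nchar(alle[1])
  writeLines(c(sprintf("#HAP n_hap=%d", n_hap),
               paste(id, chrom, pos, ref, alt, alle)),
             hap_path)
  invisible(hap_path)
}
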