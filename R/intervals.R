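#' Define a genome layout
#'
#' A genome layout names the chromosomes and fixes their lengths in base
#' pairs. Every interval set and SNP panel in the package is validated
#' against a layout, so out-of-bounds coordinates are caught at construction
#' rather than deep inside an analysis.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#'   Names are the chromosome labels; lengths must be positive.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 1e6, chr2 = 5e5))
#' @export
genome_layout <- function(chrom_lengths) {
  nm <- names(chrom_lengths)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("chrom_lengths must be a named vector of chromosome lengths")
  }
  if (anyDuplicated(nm)) stop("chromosome names must be unique")
  len <- as.numeric(chrom_lengths)
  if (any(!is.finite(len)) || any(len <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  structure(list(chrom = nm, lengths = stats::setNames(len, nm)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("<genome_layout> ", length(x$chrom), " chromosome(s), ",
      format(sum(x$lengths), big.mark = ","), " bp total\n", sep = "")
  invisible(x)
}

# Seqinfo for building GRanges tied to a layout.
.layout_seqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = layout$chrom,
                        seqlengths = as.integer(layout$lengths))
}

#' Construct an interval set
#'
#' An interval set is a named collection of genomic intervals with BED
#' semantics: 0-based, half-open `[start, end)` coordinates. Internally the
#' intervals are held as a `GRanges`, which supplies the interval arithmetic
#' (merging, overlap queries) used throughout the package.
#'
#' @param chrom Character vector of chromosome labels.
#' @param start Integer vector, 0-based inclusive start coordinates.
#' @param end Integer vector, 0-based exclusive end coordinates.
#' @param layout A [genome_layout()] the coordinates are validated against.
#' @param label Set name, e.g. `"macrophage_consolidated"`.
#' @param name Optional per-interval labels.
#' @param merged Logical; whether merge semantics already hold (sorted,
#'   non-overlapping, non-bookended per chromosome). Set by
#'   [merge_intervals()]; rarely supplied by hand.
#' @return An object of class `interval_set`.
#' @seealso [read_bed()], [merge_intervals()], [extend_intervals()]
#' @export
interval_set <- function(chrom, start, end, layout, label = "intervals",
                         name = NULL, merged = FALSE) {
  stopifnot(inherits(layout, "genome_layout"))
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) == 1L && length(start) > 1L) {
    chrom <- rep(chrom, length(start))
  }
  if (length(chrom) != length(start) || length(start) != length(end)) {
    stop("chrom, start and end must have equal length")
  }
  unknown <- setdiff(unique(chrom), layout$chrom)
  if (length(unknown)) {
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  }
  if (length(start)) {
    bad <- which(!(start >= 0 & start < end & end <= layout$lengths[chrom]))
    if (length(bad)) {
      stop("invalid interval at record ", bad[1], ": ",
           chrom[bad[1]], ":", start[bad[1]], "-", end[bad[1]],
           " (need 0 <= start < end <= chromosome length)")
    }
  }
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = layout$chrom),
    ranges = IRanges::IRanges(start = as.integer(start) + 1L,
                              end = as.integer(end)),
    seqinfo = .layout_seqinfo(layout))
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- as.character(name)
  structure(list(gr = gr, layout = layout, label = label,
                 merged = isTRUE(merged)),
            class = "interval_set")
}

#' @export
print.interval_set <- function(x, ...) {
  cat("<interval_set> '", x$label, "': ", length(x$gr), " interval(s)",
      if (x$merged) " (merged)", "\n", sep = "")
  invisible(x)
}

#' @export
length.interval_set <- function(x) length(x$gr)

#' @describeIn interval_set Coerce to a data frame with 0-based half-open
#'   `chrom`/`start`/`end` columns (BED semantics).
#' @param x An `interval_set`.
#' @param ... Unused.
#' @export
as.data.frame.interval_set <- function(x, ...) {
  gr <- x$gr
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1L,
                    end = GenomicRanges::end(gr),
                    stringsAsFactors = FALSE)
  nm <- S4Vectors::mcols(gr)$name
  if (!is.null(nm)) out$name <- nm
  out
}

.interval_set_from_gr <- function(gr, layout, label, merged = FALSE) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  interval_set(df$chrom, df$start, df$end, layout, label = label,
               merged = merged)
}

#' Read a BED file into an interval set
#'
#' Reads 3+ column BED (tab-separated, no header). `track`, `browser` and
#' `#` comment lines are skipped. Column 4, when present, is kept as the
#' interval name.
#'
#' @param path Path to a BED file.
#' @param layout A [genome_layout()].
#' @param label Set label; defaults to the file name.
#' @param unknown_chrom `"error"` (default) rejects records on chromosomes
#'   absent from `layout`; `"skip"` drops them with a message.
#' @param normalize_chrom Add a `"chr"` prefix to bare chromosome labels
#'   (e.g. `"1"` becomes `"chr1"`) when the layout uses prefixed names.
#' @return An [interval_set()].
#' @export
read_bed <- function(path, layout, label = basename(path),
                     unknown_chrom = c("error", "skip"),
                     normalize_chrom = TRUE) {
  unknown_chrom <- match.arg(unknown_chrom)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    return(interval_set(character(), integer(), integer(), layout,
                        label = label))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop("malformed BED line ", lineno[which(nf < 3)[1]],
         ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[[`, character(1), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3L)))
  bad <- which(is.na(start) | is.na(end) | start != floor(start) |
                 end != floor(end))
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]],
         ": non-integer coordinates")
  }
  if (normalize_chrom) {
    bare <- !startsWith(chrom, "chr") & paste0("chr", chrom) %in% layout$chrom
    chrom[bare] <- paste0("chr", chrom[bare])
  }
  unk <- !(chrom %in% layout$chrom)
  if (any(unk)) {
    if (unknown_chrom == "error") {
      stop("BED line ", lineno[which(unk)[1]], ": unknown chromosome '",
           chrom[which(unk)[1]], "'")
    }
    message("read_bed: skipping ", sum(unk),
            " record(s) on chromosomes absent from the layout")
    chrom <- chrom[!unk]; start <- start[!unk]; end <- end[!unk]
    fields <- fields[!unk]; nf <- nf[!unk]; lineno <- lineno[!unk]
  }
  bad <- which(end <= start)
  if (length(bad)) {
    stop("BED line ", lineno[bad[1]], ": end <= start (",
         chrom[bad[1]], ":", start[bad[1]], "-", end[bad[1]], ")")
  }
  name <- if (length(nf) && any(nf >= 4)) {
    vapply(fields, function(f) if (length(f) >= 4) f[[4]] else ".",
           character(1))
  } else NULL
  interval_set(chrom, start, end, layout, label = label, name = name)
}

#' Write an interval set as BED
#'
#' @param x An [interval_set()].
#' @param path Output path. BED3 unless interval names are present (BED4).
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "interval_set"))
  df <- as.data.frame(x)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Merge interval sets into a consolidated set
#'
#' Takes the union of one or more interval sets and coalesces overlapping
#' and bookended intervals, the same semantics as BEDTools `merge` with
#' default parameters. This is how per-donor peak files are combined into a
#' consolidated open-chromatin set.
#'
#' @param ... One or more [interval_set()] objects sharing a layout.
#' @param label Label for the merged set.
#' @return A merged [interval_set()].
#' @export
merge_intervals <- function(..., label = NULL) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) &&
      !inherits(sets[[1]], "interval_set")) {
    sets <- sets[[1]]
  }
  if (!length(sets)) stop("merge_intervals: no interval sets supplied")
  if (!all(vapply(sets, inherits, logical(1), "interval_set"))) {
    stop("all inputs must be interval_set objects")
  }
  layout <- sets[[1]]$layout
  same <- vapply(sets, function(s) identical(s$layout$chrom, layout$chrom) &&
                   identical(s$layout$lengths, layout$lengths), logical(1))
  if (!all(same)) stop("all interval sets must share one genome layout")
  if (is.null(label)) {
    label <- if (length(sets) == 1L) sets[[1]]$label else "merged"
  }
  gr <- do.call(c, lapply(sets, function(s) {
    g <- s$gr
    S4Vectors::mcols(g) <- NULL
    g
  }))
  # IRanges::reduce with default min.gapwidth = 1 coalesces overlapping and
  # bookended (distance-0) ranges, i.e. BEDTools-default merge.
  merged <- GenomicRanges::reduce(GenomicRanges::sort(gr))
  .interval_set_from_gr(merged, layout, label, merged = TRUE)
}

#' Extend intervals symmetrically and re-merge
#'
#' Widens every interval by `flank` bp on each side, clips to chromosome
#' bounds, and re-merges. Used to extend open-chromatin sites by +/-500 bp
#' before building heritability annotations.
#'
#' @param x An [interval_set()].
#' @param flank Non-negative flank size in bp.
#' @return A merged [interval_set()].
#' @export
extend_intervals <- function(x, flank) {
  stopifnot(inherits(x, "interval_set"), flank >= 0)
  df <- as.data.frame(x)
  df$start <- pmax(0, df$start - flank)
  df$end <- pmin(unname(x$layout$lengths[df$chrom]), df$end + flank)
  merge_intervals(interval_set(df$chrom, df$start, df$end, x$layout,
                               label = x$label),
                  label = x$label)
}

#' Default exclusion regions (MHC and APOE, hg19)
#'
#' The extended MHC region (chr6:26,000,000-34,000,000) and the APOE region
#' (chr19:44,400,000-46,500,000): high-LD, large-effect regions
#' conventionally removed from Alzheimer's enrichment and heritability
#' analyses. Shipped as a packaged BED file.
#'
#' @param layout A [genome_layout()] containing `chr6` and/or `chr19`.
#'   Regions on chromosomes absent from the layout are skipped.
#' @return An [interval_set()] (possibly empty for synthetic layouts).
#' @export
default_exclusions <- function(layout) {
  path <- system.file("extdata", "exclusions_hg19.bed",
                      package = "ocrenrich", mustWork = TRUE)
  read_bed(path, layout, label = "exclusions",
           unknown_chrom = "skip", normalize_chrom = FALSE)
}

#' Drop records intersecting exclusion regions
#'
#' Removes every interval (or SNP) that intersects any exclusion region.
#' Works on an [interval_set()] or a SNP-like data frame with `chrom` and
#' 1-based `pos` columns (including a [snp_panel()]).
#'
#' @param x An `interval_set`, `snp_panel`, or data frame with
#'   `chrom`/`pos` columns.
#' @param exclusions An [interval_set()] of regions to remove.
#' @param quiet Suppress the dropped-record message.
#' @return Object of the same type as `x`, with an attribute `n_dropped`.
#' @export
exclude_regions <- function(x, exclusions, quiet = FALSE) {
  stopifnot(inherits(exclusions, "interval_set"))
  if (inherits(x, "interval_set")) {
    if (!length(exclusions$gr) || !length(x$gr)) {
      attr(x, "n_dropped") <- 0L
      return(x)
    }
    hit <- IRanges::overlapsAny(x$gr, exclusions$gr)
    out <- x
    out$gr <- x$gr[!hit]
    attr(out, "n_dropped") <- sum(hit)
    if (!quiet && sum(hit)) {
      message("exclude_regions: dropped ", sum(hit), " interval(s)")
    }
    return(out)
  }
  if (inherits(x, "snp_panel") || (is.data.frame(x) &&
      all(c("chrom", "pos") %in% names(x)))) {
    df <- if (inherits(x, "snp_panel")) x$snps else x
    if (!length(exclusions$gr) || !nrow(df)) {
      attr(x, "n_dropped") <- 0L
      return(x)
    }
    hit <- point_overlaps(exclusions, df$chrom, df$pos)
    out <- x
    if (inherits(x, "snp_panel")) out$snps <- df[!hit, , drop = FALSE]
    else out <- x[!hit, , drop = FALSE]
    attr(out, "n_dropped") <- sum(hit)
    if (!quiet && sum(hit)) {
      message("exclude_regions: dropped ", sum(hit), " SNP(s)")
    }
    return(out)
  }
  stop("x must be an interval_set, snp_panel, or chrom/pos data frame")
}

#' Test whether 1-based positions fall inside an interval set
#'
#' The single place where 1-based SNP coordinates (VCF convention) meet
#' 0-based half-open intervals (BED convention): position `pos` overlaps an
#' interval `[start, end)` iff `pos - 1` lies in it.
#'
#' @param set An [interval_set()].
#' @param chrom Chromosome label(s), recycled against `pos`.
#' @param pos 1-based position(s).
#' @return Logical vector. Positions on chromosomes unknown to the set's
#'   layout return `FALSE` (with a message), not an error.
#' @export
point_overlaps <- function(set, chrom, pos) {
  stopifnot(inherits(set, "interval_set"))
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(as.numeric(pos), n)
  out <- logical(n)
  known <- chrom %in% set$layout$chrom
  if (any(!known)) {
    message("point_overlaps: ", sum(!known),
            " position(s) on unknown chromosome(s) treated as non-overlapping")
  }
  if (!any(known) || !length(set$gr)) return(out)
  # 1-based point pos maps to the width-1 range [pos, pos] in the internal
  # 1-based closed coordinates, equivalent to pos-1 in [start, end).
  q <- GenomicRanges::GRanges(
    seqnames = factor(chrom[known], levels = set$layout$chrom),
    ranges = IRanges::IRanges(start = as.integer(pos[known]), width = 1L),
    seqinfo = .layout_seqinfo(set$layout))
  out[known] <- IRanges::overlapsAny(q, set$gr)
  out
}

#' Total bases covered by an interval set
#'
#' @param x An [interval_set()].
#' @return Numeric total of covered bases (after implicit merging overlaps
#'   are counted once only if `x` is merged; raw sum of widths otherwise).
#' @export
covered_bases <- function(x) {
  stopifnot(inherits(x, "interval_set"))
  sum(as.numeric(GenomicRanges::width(x$gr)))
}
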