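BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param name Motif name (e.g. `"SPI1"`).
#' @param probs Numeric matrix, positions x 4 (columns A, C, G, T), each
#'   row a probability distribution.
#' @param threshold Log-odds detection threshold (HOMER semantics: a hit
#'   is any window scoring at or above it).
#' @param background Background base composition (default uniform).
#' @param consensus Optional consensus string for display.
#' @param pseudocount Added to every probability before renormalisation so
#'   log-odds are finite (default 1e-3).
#' @return An object of class `pwm`.
#' @export
pwm <- function(name, probs, threshold, background = rep(0.25, 4),
                consensus = NULL, pseudocount = 1e-3) {
  probs <- as.matrix(probs)
  if (ncol(probs) != 4) stop("probs must have 4 columns (A, C, G, T)")
  if (nrow(probs) < 4) stop("motif length must be at least 4")
  if (any(abs(rowSums(probs) - 1) > 1e-6)) {
    stop("PWM row ", which(abs(rowSums(probs) - 1) > 1e-6)[1],
         " does not sum to 1")
  }
  probs <- probs + pseudocount
  probs <- probs / rowSums(probs)
  colnames(probs) <- BASES
  background <- background / sum(background)
  if (is.null(consensus)) {
    consensus <- paste0(BASES[max.col(probs)], collapse = "")
  }
  structure(list(name = name, probs = probs, threshold = threshold,
                 background = stats::setNames(background, BASES),
                 consensus = consensus,
                 lodds = log(sweep(probs, 2, background, "/"))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm> ", x$name, ": L=", nrow(x$probs), " consensus=", x$consensus,
      " threshold=", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Read HOMER-style motif files
#'
#' Each motif starts with a header `>CONSENSUS<TAB>NAME<TAB>THRESHOLD`
#' followed by one whitespace-separated A C G T probability row per
#' position. Rows must sum to 1 (tolerance 0.01); a pseudocount is applied
#' and rows renormalised on load.
#'
#' @param path Path to a `.motif` file (may contain several motifs).
#' @param pseudocount Passed to [pwm()].
#' @return Named list of [pwm()] objects.
#' @export
read_pwm <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- which(startsWith(lines, ">"))
  if (!length(heads)) stop("no motif headers ('>') found")
  bounds <- c(heads, length(lines) + 1L)
  out <- list()
  for (i in seq_along(heads)) {
    hd <- strsplit(sub("^>", "", lines[heads[i]]), "[ \t]+")[[1]]
    if (length(hd) < 3) {
      stop("motif header at line ", heads[i],
           " needs consensus, name and threshold")
    }
    name <- hd[2]
    threshold <- suppressWarnings(as.numeric(hd[3]))
    if (is.na(threshold)) stop("motif '", name, "': invalid threshold")
    body <- lines[(heads[i] + 1L):(bounds[i + 1L] - 1L)]
    rows <- lapply(strsplit(trimws(body), "[ \t]+"), as.numeric)
    if (any(lengths(rows) != 4L) || anyNA(unlist(rows))) {
      stop("motif '", name, "': malformed probability row")
    }
    mat <- do.call(rbind, rows)
    bad <- which(abs(rowSums(mat) - 1) > 0.01)
    if (length(bad)) {
      stop("motif '", name, "', position ", bad[1],
           ": probabilities sum to ", sprintf("%.3f", rowSums(mat)[bad[1]]),
           ", not 1")
    }
    mat <- mat / rowSums(mat)
    out[[name]] <- pwm(name, mat, threshold, consensus = hd[1],
                       pseudocount = pseudocount)
  }
  out
}

#' Write motifs in HOMER style
#'
#' @param pwms A [pwm()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pwm <- function(pwms, path) {
  if (inherits(pwms, "pwm")) pwms <- list(pwms)
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    # write the pre-pseudocount shape as close as stored
    probs <- p$probs / rowSums(p$probs)
    writeLines(sprintf(">%s\t%s\t%.4f", p$consensus, p$name, p$threshold),
               con)
    writeLines(apply(probs, 1, function(r) paste(sprintf("%.6f", r),
                                                 collapse = "\t")), con)
  }
  invisible(path)
}

.seq_to_int <- function(seq) {
  match(strsplit(toupper(seq), "")[[1]], BASES)  # N and others -> NA
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Log-odds score at every offset of an integer-coded sequence; windows
# containing non-ACGT codes score NA.
.scan_scores <- function(si, lodds) {
  L <- nrow(lodds)
  n <- length(si) - L + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (i in seq_len(L)) {
    v <- lodds[i, ][si[i:(i + n - 1L)]]
    sc <- sc + v
  }
  sc
}

#' Scan a sequence with a PWM
#'
#' Scores every offset on both strands with the motif's log-odds matrix
#' (`sum_i log(p_i(base) / bg(base))`) and reports windows whose score
#' meets the motif's threshold. Windows containing `N` are skipped.
#'
#' @param seq A DNA string over `A`,`C`,`G`,`T`,`N`.
#' @param pwm A [pwm()].
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return Data frame with `pos` (1-based start of the window on the
#'   forward strand), `strand` and `score`, one row per hit.
#' @export
scan_pwm <- function(seq, pwm, both_strands = TRUE) {
  stopifnot(inherits(pwm, "pwm"))
  L <- nrow(pwm$probs)
  n <- nchar(seq)
  empty <- data.frame(pos = integer(), strand = character(),
                      score = numeric())
  if (n < L) return(empty)
  fwd <- .scan_scores(.seq_to_int(seq), pwm$lodds)
  hits <- which(!is.na(fwd) & fwd >= pwm$threshold)
  out <- data.frame(pos = hits, strand = rep("+", length(hits)),
                    score = fwd[hits])
  if (both_strands) {
    rev <- .scan_scores(.seq_to_int(.revcomp(seq)), pwm$lodds)
    rhits <- which(!is.na(rev) & rev >= pwm$threshold)
    # offset j on the reverse strand starts at n - (j + L - 1) + 1 forward
    out <- rbind(out, data.frame(pos = n - (rhits + L - 1L) + 1L,
                                 strand = rep("-", length(rhits)),
                                 score = rev[rhits]))
  }
  out[order(out$pos, out$strand), , drop = FALSE]
}

#' Partition open-chromatin regions by motif content
#'
#' Scans the sequence under every OCR with each PWM and groups the OCRs:
#' one subset per motif (OCRs with at least one hit; an OCR may belong to
#' several) plus a `no_motif` subset of OCRs with no hit for any motif.
#'
#' @param ocrs An [interval_set()] of open-chromatin regions.
#' @param genome_seq Named `DNAStringSet` (or named character vector) of
#'   chromosome sequences covering every OCR.
#' @param pwms Named list of [pwm()] objects.
#' @return An object of class `motif_assignment`: `membership` (logical
#'   matrix, OCRs x motifs), `subsets` (named list of [interval_set()]s,
#'   one per motif plus `no_motif`), and `ocrs`.
#' @export
partition_by_motif <- function(ocrs, genome_seq, pwms) {
  stopifnot(inherits(ocrs, "interval_set"))
  if (inherits(pwms, "pwm")) pwms <- stats::setNames(list(pwms), pwms$name)
  if (is.character(genome_seq)) {
    genome_seq <- Biostrings::DNAStringSet(genome_seq)
  }
  df <- as.data.frame(ocrs)
  miss <- setdiff(unique(df$chrom), names(genome_seq))
  if (length(miss)) {
    stop("no sequence for chromosome(s): ", paste(miss, collapse = ", "))
  }
  over <- df$end > Biostrings::width(genome_seq)[match(df$chrom,
                                                       names(genome_seq))]
  if (any(over)) {
    stop("interval beyond sequence bounds: ", df$chrom[which(over)[1]], ":",
         df$start[which(over)[1]], "-", df$end[which(over)[1]])
  }
  membership <- matrix(FALSE, nrow = nrow(df), ncol = length(pwms),
                       dimnames = list(NULL, names(pwms)))
  for (i in seq_len(nrow(df))) {
    s <- as.character(Biostrings::subseq(genome_seq[[df$chrom[i]]],
                                         start = df$start[i] + 1L,
                                         end = df$end[i]))
    for (m in names(pwms)) {
      membership[i, m] <- nrow(scan_pwm(s, pwms[[m]])) > 0
    }
  }
  subset_of <- function(keep, lab) {
    interval_set(df$chrom[keep], df$start[keep], df$end[keep], ocrs$layout,
                 label = lab, merged = ocrs$merged)
  }
  subsets <- lapply(names(pwms), function(m) {
    subset_of(membership[, m], paste0(ocrs$label, ".", m))
  })
  names(subsets) <- names(pwms)
  subsets$no_motif <- subset_of(rowSums(membership) == 0,
                                paste0(ocrs$label, ".no_motif"))
  structure(list(membership = membership, subsets = subsets, ocrs = ocrs),
            class = "motif_assignment")
}

#' @export
print.motif_assignment <- function(x, ...) {
  cat("<motif_assignment> ", nrow(x$membership), " OCRs x ",
      ncol(x$membership), " motifs; no_motif: ",
      sum(rowSums(x$membership) == 0), "\n", sep = "")
  invisible(x)
}

#' Write motif-partitioned subsets as BED files
#'
#' One file per subset, `<label>.<motif>.bed` plus `<label>.no_motif.bed`.
#'
#' @param x A [partition_by_motif()] result.
#' @param dir Output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_motif_subsets <- function(x, dir) {
  stopifnot(inherits(x, "motif_assignment"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- vapply(names(x$subsets), function(nm) {
    p <- file.path(dir, paste0(x$subsets[[nm]]$label, ".bed"))
    write_bed(x$subsets[[nm]], p)
    p
  }, character(1))
  invisible(paths)
}
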