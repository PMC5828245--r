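test_that("HOMER-style motif files parse, validate and round-trip", {
  p <- withr::local_tempfile(fileext = ".motif")
  writeLines(c(">NNNN\tSPI1\t6.5",
               "0.97\t0.01\t0.01\t0.01",
               "0.01\t0.01\t0.97\t0.01",
               "0.01\t0.01\t0.01\t0.97",
               "0.01\t0.97\t0.01\t0.01"), p)
  pwms <- read_pwm(p)
  expect_equal(names(pwms), "SPI1")
  expect_equal(nrow(pwms$SPI1$probs), 4)
  expect_equal(pwms$SPI1$threshold, 6.5)

  writeLines(c(">NNNN\tBAD\t1.0", "0.5\t0.5\t0.5\t0.5"), p)
  expect_error(read_pwm(p), "position 1")

  many <- builtin_pwms()
  stopifnot(length(many) >= 2)
  # a 15-motif library reads back with 15 records
  lib <- many[rep(1:4, length.out = 15)]
  names(lib) <- paste0("m", 1:15)
  for (i in seq_along(lib)) lib[[i]]$name <- names(lib)[i]
  write_pwm(lib, p)
  back <- read_pwm(p)
  expect_length(back, 15)
  expect_equal(back$m3$consensus, lib$m3$consensus)
  expect_equal(back$m7$threshold, lib$m7$threshold, tolerance = 1e-3)
})

test_that("pwm constructor enforces distribution rows", {
  expect_error(pwm("x", matrix(0.5, 4, 4), 0), "sum to 1")
  expect_error(pwm("x", matrix(0.25, 3, 4), 0), "at least 4")
  ok <- pwm("x", matrix(0.25, 5, 4), 0)
  expect_equal(rowSums(ok$probs), rep(1, 5))
})

test_that("consensus scanning finds exact sites on both strands", {
  pm <- consensus_pwm("t", "ACGT", threshold = NULL)
  #            123456789012345
  seq <-      "TTACGTTTTTTTTTT"
  hits <- scan_pwm(seq, pm)
  expect_equal(hits$pos[hits$strand == "+"], 3L)
  # ACGT is its own reverse complement: the site is hit on both strands
  expect_equal(hits$pos[hits$strand == "-"], 3L)
  # non-palindromic consensus on the minus strand only
  pm2 <- consensus_pwm("t2", "AAAGG")
  seq2 <- "TTTTTCCTTTTT"  # forward 6..10 = CCTTT, revcomp AAAGG
  hits2 <- scan_pwm(seq2, pm2)
  expect_true(all(hits2$strand == "-"))
  expect_equal(hits2$pos, 6L)
})

test_that("uniform PWM at threshold 0 hits every clean offset, N windows skipped", {
  pm <- pwm("u", matrix(0.25, 4, 4), threshold = 0)
  hits <- scan_pwm("ACGTACGT", pm, both_strands = FALSE)
  expect_equal(hits$pos, 1:5)
  expect_true(all(abs(hits$score) < 1e-9))
  hits_n <- scan_pwm("ACGNACGT", pm, both_strands = FALSE)
  expect_equal(hits_n$pos, 5L)  # windows touching the N are skipped
  expect_equal(nrow(scan_pwm("ACG", pm)), 0)  # shorter than the motif
})

test_that("planted consensus sites are recovered exactly at strict thresholds", {
  set.seed(12)
  pm <- consensus_pwm("SPI1", "AGAGGAAGTG")
  bg <- paste0(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
               collapse = "")
  plant_at <- c(20, 90, 150)
  s <- bg
  for (at in plant_at) {
    substr(s, at, at + 9) <- "AGAGGAAGTG"
  }
  hits <- scan_pwm(s, pm)
  expect_setequal(hits$pos[hits$strand == "+"], plant_at)
})

test_that("motif partition assigns planted OCRs and respects invariants", {
  layout <- tiny_layout(c(chr1 = 5000))
  set.seed(33)
  genome <- paste0(sample(c("A", "C", "G", "T"), 5000, replace = TRUE),
                   collapse = "")
  ocr_starts <- seq(100, 4500, by = 450)
  ocrs <- interval_set(rep("chr1", length(ocr_starts)), ocr_starts,
                       ocr_starts + 200, layout, label = "ocrs")
  pmA <- consensus_pwm("A_motif", "AGAGGAAGTG")
  pmB <- consensus_pwm("B_motif", "CTATTTATAG")
  # plant A into OCRs 1-3 and B into OCRs 4-5; wipe chance hits by
  # re-checking against ground truth below
  for (i in 1:3) {
    substr(genome, ocr_starts[i] + 50, ocr_starts[i] + 59) <- "AGAGGAAGTG"
  }
  for (i in 4:5) {
    substr(genome, ocr_starts[i] + 50, ocr_starts[i] + 59) <- "CTATTTATAG"
  }
  asg <- partition_by_motif(ocrs, c(chr1 = genome), list(A_motif = pmA,
                                                         B_motif = pmB))
  expect_true(all(asg$membership[1:3, "A_motif"]))
  expect_true(all(asg$membership[4:5, "B_motif"]))
  # partition invariant: no_motif plus any-motif covers all OCRs exactly
  n_any <- sum(rowSums(asg$membership) > 0)
  expect_equal(n_any + length(asg$subsets$no_motif), length(ocrs))
  # no_motif disjoint from every motif subset
  no_df <- as.data.frame(asg$subsets$no_motif)
  for (m in c("A_motif", "B_motif")) {
    mdf <- as.data.frame(asg$subsets[[m]])
    expect_equal(nrow(merge(no_df, mdf)), 0)
  }
})

test_that("scanning is strand-symmetric under genome reverse complement", {
  layout <- tiny_layout(c(chr1 = 1000))
  set.seed(44)
  genome <- paste0(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                   collapse = "")
  substr(genome, 200, 209) <- "AGAGGAAGTG"
  pm <- consensus_pwm("m", "AGAGGAAGTG")
  ocrs <- interval_set("chr1", c(100, 500), c(400, 900), layout)
  fwd <- partition_by_motif(ocrs, c(chr1 = genome), list(m = pm))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(genome)))
  # mirror the OCRs onto the reverse-complemented coordinates
  ocrs_rc <- interval_set("chr1", 1000 - c(400, 900), 1000 - c(100, 500),
                          layout)
  bwd <- partition_by_motif(ocrs_rc, c(chr1 = rc), list(m = pm))
  expect_equal(sum(fwd$membership), sum(bwd$membership))
})

test_that("raising a threshold never rescues an OCR from no_motif", {
  layout <- tiny_layout(c(chr1 = 2000))
  set.seed(55)
  genome <- paste0(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                   collapse = "")
  ocrs <- interval_set("chr1", seq(0, 1800, by = 200),
                       seq(150, 1950, by = 200), layout)
  pm <- consensus_pwm("m", "AGAGGAAG", p_major = 0.9)
  lo <- pm; lo$threshold <- 2
  hi <- pm; hi$threshold <- 8
  a_lo <- partition_by_motif(ocrs, c(chr1 = genome), list(m = lo))
  a_hi <- partition_by_motif(ocrs, c(chr1 = genome), list(m = hi))
  expect_true(all(a_hi$membership[, "m"] <= a_lo$membership[, "m"]))
})

test_that("partition errors on OCRs outside the supplied sequence", {
  layout <- tiny_layout(c(chr1 = 1000))
  ocrs <- interval_set("chr1", 900, 1000, layout)
  pm <- consensus_pwm("m", "ACGTACGT")
  short <- c(chr1 = paste0(rep("A", 500), collapse = ""))
  expect_error(partition_by_motif(ocrs, short, list(m = pm)),
               "beyond sequence bounds")
  expect_error(partition_by_motif(ocrs, c(chr2 = short[[1]]),
                                  list(m = pm)), "no sequence")
})

test_that("motif subsets write one BED per subset", {
  layout <- tiny_layout(c(chr1 = 2000))
  genome <- c(chr1 = paste0(rep("ACGT", 500), collapse = ""))
  ocrs <- interval_set("chr1", c(0, 1000), c(200, 1200), layout,
                       label = "peaks")
  pm <- consensus_pwm("m", "AAAAAAAA")  # absent from the ACGT repeat
  asg <- partition_by_motif(ocrs, genome, list(m = pm))
  d <- withr::local_tempdir()
  paths <- write_motif_subsets(asg, d)
  expect_true(all(file.exists(paths)))
  nm <- read_bed(file.path(d, "peaks.no_motif.bed"), layout)
  expect_equal(length(nm), 2)
})
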