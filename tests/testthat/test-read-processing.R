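test_that("adapter trimming removes the longest qualifying suffix", {
  ad <- "AGATCGGAAGAGC"
  expect_identical(trim_adapter("ACGTACGTAGATCGGAAG", ad, 5), "ACGTACGT")
  expect_identical(trim_adapter("ACGTACGT", ad, 5), "ACGTACGT")
  expect_identical(trim_adapter("AGATCGGAAGAGC", ad, 5), "")
})

test_that("adapter trimming matches the exhaustive suffix-prefix oracle", {
  set.seed(101)
  ad <- default_adapter()
  for (i in 1:60) {
    ins_len <- sample(0:30, 1)
    ad_len <- sample(0:20, 1)
    read <- paste0(
      paste(sample(c("A", "C", "G", "T"), ins_len, replace = TRUE), collapse = ""),
      substr(ad, 1, ad_len))
    if (!nzchar(read)) next
    expect_identical(trim_adapter(read, ad), brute_force_trim(read, ad),
                     label = paste("read", read))
  }
})

test_that("handle demultiplexing assigns channels and strips the handle", {
  dm <- demux_by_handle(c("GGACTTTT", "TTCATTTT", "NNNNTTTT"),
                        plus_handle = "RRRY", minus_handle = "YYYR")
  expect_equal(as.character(dm$channel), c("plus", "minus", "unassigned"))
  expect_equal(dm$read1, c("TTTT", "TTTT", "NNNNTTTT"))
  expect_equal(attr(dm, "n_ambiguous"), 0L)
})

test_that("overlapping handle patterns yield ambiguous reads, tallied", {
  dm <- demux_by_handle("GGGGAAAA", plus_handle = "RRRR", minus_handle = "GGGG")
  expect_equal(as.character(dm$channel), "unassigned")
  expect_equal(attr(dm, "n_ambiguous"), 1L)
})

test_that("demux recovers simulated channel labels exactly with disjoint handles", {
  tg <- synthetic_target()
  tr <- simulation_truth(tg, depth_plus = 500, depth_minus = 500, seed = 3)
  reads <- simulate_reads(simulate_stop_counts(tr), tg, seed = 4)
  dm <- demux_by_handle(reads$read1)
  expect_identical(as.character(dm$channel), reads$channel)
})

test_that("stop-site inference follows the halt-one-before convention", {
  tg <- synthetic_target(n = 60)
  dna <- target_dna(tg)
  aln <- align_and_infer_stop(c(substr(dna, 8, 38), substr(dna, 1, 31)), tg)
  expect_equal(aln$stop_site, c(7L, 0L))  # 0 = full length
  expect_equal(aln$target, rep("synthRNA", 2))
})

test_that("reads matching two targets equally are discarded as no-hits", {
  tg1 <- synthetic_target(name = "a")
  tg2 <- synthetic_target(name = "b")  # identical sequence, different name
  aln <- align_and_infer_stop(substr(target_dna(tg1), 5, 35), list(tg1, tg2))
  expect_true(is.na(aln$target))
  expect_true(is.na(aln$stop_site))
})

test_that("empty reads are no-hits", {
  tg <- synthetic_target()
  aln <- align_and_infer_stop("", tg)
  expect_true(is.na(aln$stop_site))
})

test_that("aligner agrees with a brute-force all-offsets Hamming scan", {
  tg <- synthetic_target(n = 40, seed = 7)
  set.seed(77)
  dna <- target_dna(tg)
  reads <- character(0)
  for (i in 1:120) {
    p <- sample(1:41, 1)
    ln <- sample(12:31, 1)
    r <- substr(dna, p, min(p + ln - 1, nchar(dna)))
    if (runif(1) < 0.4) {  # plant 1-2 substitutions
      pos <- sample(nchar(r), min(sample(1:2, 1), nchar(r)))
      for (q in pos) substr(r, q, q) <- sample(c("A", "C", "G", "T"), 1)
    }
    reads <- c(reads, r)
  }
  reads <- c(reads, replicate(80, paste(
    sample(c("A", "C", "G", "T"), sample(10:31, 1), replace = TRUE),
    collapse = "")))
  aln <- align_and_infer_stop(reads, tg)
  for (i in seq_along(reads)) {
    oracle <- brute_force_stop(reads[i], list(tg))
    expect_identical(aln$target[i], oracle$target, label = paste("read", i))
    expect_identical(aln$stop_site[i], oracle$stop, label = paste("read", i))
  }
})

test_that("stop tabulation counts sites and full-length reads", {
  tg <- synthetic_target(n = 4, primer_length = 10, seed = 2)
  out <- tabulate_stops(c(3L, 3L, 0L, 1L), tg)
  expect_equal(out$X, c(1L, 0L, 2L, 0L))
  expect_equal(out$X_full, 1L)

  empty <- tabulate_stops(integer(0), synthetic_target(n = 5, primer_length = 10))
  expect_equal(empty$X, rep(0L, 5))
  expect_equal(empty$X_full, 0L)

  expect_error(tabulate_stops(c(1L, 5L), tg), "aligner/coordinate bug")
})

test_that("tabulation conserves the number of observations", {
  tg <- synthetic_target(n = 30, seed = 5)
  set.seed(9)
  stops <- sample(0:30, 1000, replace = TRUE)
  out <- tabulate_stops(stops, tg)
  expect_equal(sum(out$X) + out$X_full, 1000L)
})

test_that("ligation dimers are classified and quantified", {
  tg <- synthetic_target()
  primer <- rt_primer_region_dna(tg)
  tr <- simulation_truth(tg, depth_plus = 5, depth_minus = 5, seed = 21)
  cts <- simulate_stop_counts(tr)
  clean <- simulate_reads(cts, tg, dimer_rate = 0, seed = 22)
  expect_equal(ligation_dimer_fraction(clean$read1, primer), 0)

  mixed <- simulate_reads(cts, tg, dimer_rate = 0.9, seed = 23)
  expect_equal(ligation_dimer_fraction(mixed$read1, primer),
               sum(mixed$is_dimer) / nrow(mixed))
  expect_equal(sum(mixed$is_dimer) / nrow(mixed), 0.9)

  pure <- mixed$read1[mixed$is_dimer]
  expect_equal(ligation_dimer_fraction(pure, primer), 1)
  expect_error(ligation_dimer_fraction(character(0), primer), "empty")
})

test_that("pipeline round trip reproduces simulator counts at zero noise", {
  tg <- synthetic_target()
  tr <- simulation_truth(tg, depth_plus = 1500, depth_minus = 1500, seed = 31)
  cts <- simulate_stop_counts(tr)
  reads <- simulate_reads(cts, tg, seed = 32)
  res <- process_reads(reads$read1, tg)
  expect_identical(res$counts[["synthRNA.plus"]]$X, cts$plus$X)
  expect_identical(res$counts[["synthRNA.plus"]]$X_full, cts$plus$X_full)
  expect_identical(res$counts[["synthRNA.minus"]]$X, cts$minus$X)
  expect_identical(res$counts[["synthRNA.minus"]]$X_full, cts$minus$X_full)
  expect_equal(res$qc$n_no_hit, 0)
})

test_that("fragment counts conserve uniquely aligned reads under contamination", {
  tg <- synthetic_target()
  tr <- simulation_truth(tg, depth_plus = 800, depth_minus = 800, seed = 41)
  reads <- simulate_reads(simulate_stop_counts(tr), tg, dimer_rate = 0.2, seed = 42)
  res <- process_reads(reads$read1, tg)
  aligned <- sum(vapply(res$counts, function(x) sum(x$X) + x$X_full, integer(1)))
  expect_equal(aligned, sum(!reads$is_dimer))
  expect_equal(res$qc$dimer_fraction, mean(reads$is_dimer))
})

test_that("stop-count tables round-trip through the TSV format", {
  tg <- synthetic_target(n = 6, primer_length = 10, seed = 3)
  cts <- list(a.plus = fragment_counts("a", "plus", c(1, 0, 4, 0, 2, 7), 11),
              a.minus = fragment_counts("a", "minus", c(0, 0, 1, 0, 0, 2), 30))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_stop_counts(cts, path)
  back <- read_stop_counts(path)
  expect_equal(back$a.plus$X, cts$a.plus$X)
  expect_equal(back$a.minus$X_full, cts$a.minus$X_full)
})

test_that("FASTQ written by the simulator reads back identically", {
  tg <- synthetic_target()
  tr <- simulation_truth(tg, depth_plus = 50, depth_minus = 50, seed = 51)
  reads <- simulate_reads(simulate_stop_counts(tr), tg, seed = 52)
  r1 <- withr::local_tempfile(fileext = ".fq")
  r2 <- withr::local_tempfile(fileext = ".fq")
  write_fastq_pairs(reads, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  expect_identical(back$read1, reads$read1)
  expect_identical(back$read2, reads$read2)
})
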