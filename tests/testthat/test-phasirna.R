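test_that("consolidation maps both strands into one register system", {
  aln <- alignment_frame(
    read_seq = c(strrep("A", 21), strrep("C", 21), strrep("G", 24)),
    target_id = "t", start = c(100L, 102L, 300L),
    strand = c("+", "-", "+"), count = c(2, 3, 1))
  cons <- consolidate(aln, i = 21)
  expect_equal(nrow(cons), 2)           # the 24-nt read is dropped
  expect_equal(cons$pos, c(100L, 100L)) # minus read at 102 -> 100
  expect_equal(sum(cons$count), 5)

  # mixed set with all reads in the same register mod i
  aln2 <- alignment_frame(
    read_seq = strrep("A", 21), target_id = "t",
    start = c(100L, 121L, 142L, 165L), strand = "+", count = 1)
  cons2 <- consolidate(aln2, 21)
  expect_equal(length(unique(cons2$pos %% 21)), 2)  # 165 off register
})

test_that("binomial phasing p matches the printed formula exactly", {
  # j = 0, n = 1, i = 21 -> p = 1/21
  expect_equal(phasing_pvalue(0, 1, 21), 1 / 21, tolerance = 1e-12)
  # j = n -> 0 (the full sum equals 1)
  expect_equal(phasing_pvalue(10, 10, 21), 0)
  expect_equal(phasing_pvalue(0, 0, 21), 0)

  # brute-force summation oracle over the whole (j, n) range
  oracle <- function(j, n, i) {
    q <- 1 / i
    k <- j:n
    if (j == n) return(0)
    sum(exp(lchoose(n, (j + 1):n) + ((j + 1):n) * log(q) +
              (n - (j + 1):n) * log1p(-q)))
  }
  for (i in c(21, 24)) {
    for (n in c(1, 5, 17, 40, 60)) {
      for (j in 0:n) {
        expect_equal(phasing_pvalue(j, n, i), oracle(j, n, i),
                     tolerance = 1e-12)
      }
    }
  }
  # strictly decreasing in j at fixed n, i
  p_seq <- vapply(0:40, phasing_pvalue, numeric(1), n = 40, i = 21)
  expect_true(all(diff(p_seq) < 0))
  expect_true(all(p_seq >= 0 & p_seq <= 1))

  # the inclusive variant is P(X >= j)
  expect_equal(phasing_pvalue(3, 10, 21, inclusive = TRUE),
               phasing_pvalue(2, 10, 21))
  # numerically stable at large n
  expect_gt(phasing_pvalue(4900, 1e5, 21), 0)
})

test_that("legacy phase score follows P = (n-2) ln(1 + sum k)", {
  expect_equal(phase_score(c(1, 1, 1, 1, 1, 1, 1, 0)), 5 * log(8))
  expect_equal(phase_score(c(3, 4, 0, 0, 0, 0, 0, 0)), 0 * log(8))
  p <- phase_score(c(2, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(as.numeric(p), 0)
  expect_true(attr(p, "degenerate"))
  # monotone in occupied positions and in total reads
  expect_lt(phase_score(c(5, 5, 0, 0, 0, 0, 0, 0)),
            phase_score(c(5, 5, 1, 0, 0, 0, 0, 0)))
  expect_lt(phase_score(c(1, 1, 1, 1, 1, 1, 1, 1)),
            phase_score(c(9, 1, 1, 1, 1, 1, 1, 1)))
})

test_that("planted phased loci are called; filters kill noisy windows", {
  # 30 phased 21-nt positions, both strands, no background
  ts <- gen_phased_testset(n_loci = 30, reads_per_pos = 1, i = 21,
                           background_reads = 0, seed = 5)
  res <- scan_windows(ts$alignments, phase_params(21))
  expect_gte(sum(res$windows$called), 1)
  expect_equal(nrow(res$phasirna), 30)
  # every planted read is reported
  expect_setequal(res$phasirna$seq, ts$alignments$read_seq)

  # heavy uniform background *inside* the locus window: p may stay tiny but
  # the phased fraction drops below 50% and the window is vetoed
  ts2 <- gen_phased_testset(n_loci = 10, reads_per_pos = 1, i = 21,
                            background_reads = 0, seed = 6)
  with_seed(99, {
    bpos <- sample(setdiff(1001:1900, ts2$truth$positions), 40)
    bg <- alignment_frame(
      read_seq = vapply(bpos, function(p) substr(ts2$genome[[1]], p, p + 20),
                        character(1)),
      target_id = "pchr1", start = bpos, strand = "+", count = 1)
  })
  noisy <- rbind(as.data.frame(ts2$alignments), as.data.frame(bg))
  res2 <- scan_windows(noisy, phase_params(21))
  expect_false(any(res2$windows$called))
  expect_true(any(res2$windows$p_pass & !res2$windows$frac_pass))
})

test_that("sensitivity is unaffected by out-of-window background", {
  for (bg in c(0, 500, 1000)) {
    ts <- gen_phased_testset(n_loci = 10, reads_per_pos = 10, i = 21,
                             background_reads = bg, seed = 7)
    res <- scan_windows(ts$alignments, phase_params(21))
    called <- res$windows[res$windows$called, ]
    covers <- any(called$start <= min(ts$truth$positions) &
                    called$end >= max(ts$truth$positions))
    expect_true(covers)
  }
})

test_that("null maps yield no Bonferroni-passing calls in most replicates", {
  fp <- 0L
  n_sim <- 60L
  for (s in seq_len(n_sim)) {
    ts <- gen_phased_testset(n_loci = 0, reads_per_pos = 1, i = 21,
                             background_reads = 500, seed = 2000 + s,
                             target_len = 20000L)
    res <- scan_windows(ts$alignments, phase_params(21))
    if (any(res$windows$called)) fp <- fp + 1L
  }
  expect_gte((n_sim - fp) / n_sim, 0.95)
})

test_that("windows and calls are invariant under input record order", {
  ts <- gen_phased_testset(n_loci = 12, reads_per_pos = 2, i = 21,
                           background_reads = 100, seed = 9)
  res1 <- scan_windows(ts$alignments, phase_params(21))
  perm <- as.data.frame(ts$alignments)[rev(seq_len(nrow(ts$alignments))), ]
  res2 <- scan_windows(perm, phase_params(21))
  expect_equal(res1$windows, res2$windows, ignore_attr = TRUE)
  expect_equal(res1$phasirna, res2$phasirna, ignore_attr = TRUE)
})

test_that("strand-bias and minimum-loci filters are enforced", {
  # all phased reads on one strand: strand filter vetoes the call
  i <- 21L
  pos <- 1001L + (0:9) * i
  one_sided <- alignment_frame(
    read_seq = strrep("A", 21), target_id = "t", start = pos,
    strand = "+", count = 5)
  res <- scan_windows(one_sided, phase_params(21))
  expect_false(any(res$windows$called))
  expect_true(any(res$windows$p_pass & !res$windows$strand_pass))

  # fewer than 5 distinct loci
  few <- alignment_frame(
    read_seq = strrep("A", 21), target_id = "t",
    start = c(1001L, 1022L, 1043L, 1064L), strand = c("+", "+", "-", "-"),
    count = 50)
  few$start[3:4] <- few$start[3:4] + 2L  # minus-strand duplex partners
  res2 <- scan_windows(few, phase_params(21))
  expect_false(any(res2$windows$called))
  expect_true(any(!res2$windows$loci_pass))
})
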