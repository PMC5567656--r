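test_that("best hits define h by the equally-well (minimal mismatch) rule", {
  set.seed(12)
  rrna <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                collapse = "")
  read <- substr(rrna, 40, 60)
  # snoRNA carries the same region with one substitution
  sno <- rrna
  substr(sno, 50, 50) <- setdiff(c("A", "C", "G", "T"),
                                 substr(sno, 50, 50))[1]
  # snRNA carries it exactly
  refs <- list(ncrna = data.frame(
    class = c("rRNA", "snoRNA", "snRNA"),
    id = c("r1", "sno1", "sn1"),
    seq = c(rrna, sno, substr(rrna, 30, 90))))

  ann <- annotate_ncrna(read_set(read), refs)
  tab <- ann$table
  # 0-mm hits on rRNA and snRNA beat the 1-mm snoRNA hit
  expect_setequal(tab$class, c("rRNA", "snRNA"))
  expect_equal(unique(tab$h), 2L)

  # single-class read: a probe spelling the snoRNA-private substitution
  probe <- paste0(substr(rrna, 40, 49),
                  substr(sno, 50, 50), substr(rrna, 51, 60))
  ann2 <- annotate_ncrna(read_set(probe), refs,
                         ncrna_params(max_mismatch = 0))
  expect_equal(ann2$table$class, "snoRNA")
  expect_equal(ann2$table$h, 1L)
})

test_that("apportioning follows c_class = sum r_i / h_i and conserves reads", {
  tab <- data.frame(seq = c("s1", "s1"), count = 10, h = 2,
                    class = c("rRNA", "snRNA"))
  expect_equal(apportion_counts(tab), c(rRNA = 5, snRNA = 5))

  tab2 <- rbind(
    data.frame(seq = "a", count = 12, h = 3, class = c("A", "B", "C")),
    data.frame(seq = "b", count = 4, h = 1, class = "A"))
  got <- apportion_counts(tab2)
  expect_equal(got, c(A = 8, B = 4, C = 4))
  expect_equal(sum(got), 16)
})

test_that("apportioning conserves counts on random hit tables", {
  set.seed(31)
  classes <- LETTERS[1:6]
  for (k in 1:50) {
    n <- sample(1:30, 1)
    rows <- lapply(seq_len(n), function(i) {
      h <- sample(1:4, 1)
      data.frame(seq = paste0("s", i), count = sample(1:500, 1), h = h,
                 class = sample(classes, h))
    })
    tab <- do.call(rbind, rows)
    per_seq <- tab[!duplicated(tab$seq), ]
    expect_equal(sum(apportion_counts(tab)), sum(per_seq$count),
                 tolerance = 1e-9)
  }
})

test_that("tRNA models project the canonical cloverleaf onto any length", {
  tr <- toy_trna()
  mod <- build_trna_model(tr)
  expect_equal(mod$L, 76L)
  expect_equal(c(mod$d_loop_end, mod$ac_start, mod$ac_end, mod$tpsi_start),
               c(25, 31, 39, 52))
  expect_equal(mod$oligo_t_end, 76L + 18L)  # TTTT at trailer pos 15..18

  tr72 <- tr
  tr72$seq <- paste0(substr(tr$seq, 1, 20 + 72), substr(tr$seq, 97, 116))
  mod72 <- build_trna_model(tr72)
  expect_equal(c(mod72$d_loop_end, mod72$ac_start, mod72$ac_end,
                 mod72$tpsi_start),
               round(72 * c(25, 31, 39, 52) / 76))

  short <- tr
  short$seq <- substr(tr$seq, 1, 75)
  expect_error(build_trna_model(short), "40")
})

test_that("tRF classes follow the cloverleaf anatomy", {
  tr <- toy_trna()
  mod <- build_trna_model(tr)
  pad <- mod$pad5
  aln <- function(s, e, tail = "", read = "NNN") {
    list(start = pad + s, end = pad + e, strand = "+", tail = tail,
         read_seq = read)
  }
  # 5' anchored
  expect_equal(classify_trf(aln(1, 25), mod), "5' tRF")
  expect_equal(classify_trf(aln(1, 33), mod), "5' tR-half")
  # 3' anchored
  expect_equal(classify_trf(aln(55, 76, read = "GGG"), mod), "3' tRF")
  expect_equal(classify_trf(aln(55, 76, tail = "CCA",
                                read = paste0(substr(mod$body, 55, 76), "CCA")),
                            mod), "3' CCA-tRF")
  expect_equal(classify_trf(aln(35, 76, read = "GGG"), mod), "3' tR-half")
  # trailer and leader
  expect_equal(classify_trf(aln(77, 90), mod), "tRF-1")   # oligo-T at 91..94
  expect_equal(classify_trf(list(start = 3, end = 20, strand = "+",
                                 tail = "", read_seq = "X"), mod),
               "tRNA-leader")
  # internal
  expect_equal(classify_trf(aln(28, 50), mod), "misc-tRF")
  # full-length tRNA read is no tRF
  expect_equal(classify_trf(aln(1, 76, read = "GGG"), mod), "misc-tRF")
  # antisense
  expect_equal(classify_trf(list(start = pad + 1, end = pad + 25,
                                 strand = "-", tail = "", read_seq = "X"),
                            mod), "misc-tRF")
  # out of range
  expect_error(classify_trf(list(start = 0, end = 10, strand = "+",
                                 tail = "", read_seq = "X"), mod), "outside")
})

test_that("synthetic tRF reads are assigned and classified correctly", {
  trnas <- gen_trnas(8, seed = 4)
  ts <- gen_trf_testset(trnas, mismatch_fraction = 0.5, seed = 4)
  expect_equal(sum(ts$truth$mutated), round(0.5 * nrow(ts$truth)))
  ann <- annotate_ncrna(ts$reads, list(trna = trnas))
  assigned <- total_reads(ann$assigned) / total_reads(ts$reads)
  expect_gte(assigned, 0.95)
  # truth agreement of the tRF class labels
  m <- merge(ann$trf, ts$truth[, c("seq", "class", "trna")], by = "seq",
             suffixes = c(".got", ".true"))
  agree <- sum(m$count[m$class.got == m$class.true]) / sum(m$count)
  expect_gte(agree, 0.97)
  # per-class shares within 3 percentage points of the generator truth
  tot <- sum(ts$truth$count)
  truth_share <- tapply(ts$truth$count, ts$truth$class, sum) / tot
  got_share <- tapply(ann$trf$count, ann$trf$class, sum) / tot
  for (cl in names(truth_share)) {
    gs <- got_share[cl]
    if (is.na(gs)) gs <- 0
    expect_lt(abs(truth_share[[cl]] - gs), 0.03)
  }
})

test_that("multi-class reads are split, tRNA share lands in tRF classes", {
  tr <- toy_trna()
  mod <- build_trna_model(tr)
  read <- substr(mod$body, 1, 25)  # 5' tRF
  refs <- list(
    ncrna = data.frame(class = "rRNA", id = "r1",
                       seq = paste0("GGGG", read, "GGGG")),
    trna = tr)
  ann <- annotate_ncrna(read_set(read, 10), refs)
  expect_equal(sort(ann$table$class), c("rRNA", "tRNA"))
  expect_equal(unique(ann$table$h), 2L)
  expect_equal(apportion_counts(ann$table), c(rRNA = 5, tRNA = 5))
  expect_equal(ann$trf$class, "5' tRF")
  expect_equal(ann$trf$count, 5)
})
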