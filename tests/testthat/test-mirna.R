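test_that("canonical, tailed, offset and modified reads hit the right tier", {
  refs <- toy_mirna_ref()
  mature <- toy_mature_seq()

  # exact mature -> canonical, no tail, no modification
  ann <- annotate_mirnas(read_set(mature), refs)
  expect_equal(ann$hits$tier, "canonical")
  expect_equal(ann$hits$tail, "")
  expect_equal(nrow(ann$hits$mismatches[[1]]), 0)
  expect_equal(nrow(ann$unassigned), 0)

  # one internal substitution + non-template "AA" tail -> tier "tailed",
  # modification recorded at its mature position (defaults: tail <= 2,
  # internal modifications <= 1)
  mod <- mature
  substr(mod, 7, 7) <- "C"   # A at mature position 7 -> C
  read <- paste0(mod, "AA")  # template continues "CT" after the mature
  ann2 <- annotate_mirnas(read_set(read), refs)
  expect_equal(ann2$hits$tier, "tailed")
  expect_equal(ann2$hits$tail, "AA")
  d <- ann2$hits$mismatches[[1]]
  expect_equal(d$position, 7)
  expect_equal(d$from_base, "A")
  expect_equal(d$to_base, "C")

  # read starting 3 nt upstream of the mature 5' end -> offset
  hp <- refs$hairpins$seq[1]
  up <- substr(hp, 8, 8 + 21)
  ann3 <- annotate_mirnas(read_set(up), refs)
  expect_equal(ann3$hits$tier, "offset")
  expect_equal(ann3$hits$offset, -3L)

  # read 20 nt away from the mature start: not a miRNA at all
  far <- substr(hp, 36, 36 + 18)
  ann4 <- annotate_mirnas(read_set(far), refs)
  expect_equal(nrow(ann4$hits), 0)
  expect_equal(nrow(ann4$unassigned), 1)

  # 3-nt tail exceeds the default allowance -> unassigned
  long_tail <- paste0(mature, "AAA")
  ann5 <- annotate_mirnas(read_set(long_tail), refs)
  expect_equal(nrow(ann5$hits), 0)
})

test_that("offset classification window is +-5 around mature 5' ends", {
  expect_true(classify_offset(98, 100))   # within window, not canonical
  expect_true(classify_offset(105, 100))
  expect_false(classify_offset(100, 100)) # canonical start
  expect_false(classify_offset(120, 100)) # outside window
  expect_false(classify_offset(106, 100))
})

test_that("cross-species annotation is reported after the self pass", {
  refs <- toy_mirna_ref()
  # same hairpin catalogued under two species; library species = "other"
  hp2 <- refs$hairpins
  hp2$species <- "spc2"
  mt2 <- refs$matures[, c("gene", "species", "hairpin_id", "start", "end")]
  mt2$species <- "spc2"
  mt2$gene <- "mirY"
  both <- mirna_ref(rbind(refs$hairpins[, c("id", "species", "seq")],
                          hp2[, c("id", "species", "seq")]),
                    rbind(refs$matures[, c("gene", "species", "hairpin_id",
                                           "start", "end")], mt2))
  ann <- annotate_mirnas(read_set(toy_mature_seq()), both,
                         mirna_params(species = "spc"))
  expect_equal(ann$hits$scope, "self")
  expect_equal(ann$hits$gene, "mirX")

  ann2 <- annotate_mirnas(read_set(toy_mature_seq()), both,
                          mirna_params(species = "none_of_these"))
  expect_equal(unique(ann2$hits$scope), "cross")
  expect_setequal(ann2$hits$gene, c("mirX", "mirY"))
  # multi-gene equal hits split counts uniformly
  expect_equal(ann2$hits$count_apportioned, c(0.5, 0.5))
  expect_equal(ann2$hits$n_genes, c(2L, 2L))
})

test_that("the tier hierarchy partitions the read set", {
  hp <- gen_hairpins(6, seed = 2)
  ts <- gen_mirna_testset(hp, seed = 2)
  ann <- annotate_mirnas(ts$reads, hp)
  per_read <- tapply(ann$hits$count_apportioned, ann$hits$seq, sum)
  # each assigned read contributes exactly its count, once
  rs_counts <- setNames(ts$reads$count, ts$reads$seq)
  expect_equal(as.numeric(per_read),
               as.numeric(rs_counts[names(per_read)]))
  # assigned + unassigned == total
  expect_equal(sum(per_read) + total_reads(ann$unassigned),
               total_reads(ts$reads))
  # a read appears in exactly one tier
  tiers_per_read <- tapply(ann$hits$tier, ann$hits$seq,
                           function(x) length(unique(x)))
  expect_true(all(tiers_per_read == 1))
})

test_that("the full artificial grid is recovered as miRNA with true genes", {
  hp <- gen_hairpins(8, seed = 3)
  ts <- gen_mirna_testset(hp, seed = 3, count_range = 1:10)
  # grid size: matures x offsets x tails x mismatch scenarios
  expect_equal(nrow(ts$truth), 8 * 11 * 21 * 2)
  ann <- annotate_mirnas(ts$reads, hp)
  recovery <- 1 - total_reads(ann$unassigned) / total_reads(ts$reads)
  expect_gte(recovery, 0.999)
  # per-gene read assignment correlates with generator truth
  truth_gene <- tapply(ts$truth$count, ts$truth$gene, sum)
  got_gene <- tapply(ann$hits$count_apportioned, ann$hits$gene, sum)
  expect_gte(cor(as.numeric(truth_gene),
                 as.numeric(got_gene[names(truth_gene)])), 0.95)
  # canonical reads are never classified as tailed/offset: every read whose
  # truth is canonical must be annotated canonical
  canon <- ts$truth$seq[ts$truth$tier == "canonical" &
                          ts$truth$n_mismatch == 0]
  hits_c <- ann$hits[ann$hits$seq %in% canon, ]
  expect_true(all(hits_c$tier == "canonical"))
})

test_that("modification and tail matrices conserve read counts", {
  refs <- toy_mirna_ref()
  mature <- toy_mature_seq()
  mod <- mature
  substr(mod, 10, 10) <- "G"  # mature position 10 is A -> A>G (ADAR-like)
  # hairpin template continues "CT" after the mature: "AA" is a pure
  # di-tail; in "CG" the C is templated, so only "G" is a mono-tail
  reads <- read_set(c(mod, paste0(mature, "AA"), paste0(mature, "CG")),
                    c(7, 3, 2))
  ann <- annotate_mirnas(reads, refs)
  mm <- modification_matrix(ann$hits)
  expect_equal(mm$modifications[10, "A>G"], 7)
  expect_equal(sum(mm$modifications), 7)  # one modified sequence, 7 reads
  expect_equal(sum(mm$tails), 5)
  expect_equal(mm$tails["di", "A"], 3)
  expect_equal(mm$tails["mono", "G"], 2)

  # no modified hits -> zero matrix
  mm0 <- modification_matrix(annotate_mirnas(read_set(mature), refs)$hits)
  expect_true(all(mm0$modifications == 0))
})
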