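# brute-force oracle: all placements of a read on a set of references
# within a mismatch budget, both strands, via plain character comparison
oracle_map <- function(read, refs, max_mm) {
  out <- list()
  for (nm in names(refs)) {
    ref <- refs[[nm]]
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else {
        paste(rev(strsplit(chartr("ACGT", "TGCA", read), "")[[1]]),
              collapse = "")
      }
      P <- nchar(pat)
      if (P > nchar(ref)) next
      for (s in 1:(nchar(ref) - P + 1)) {
        mm <- sum(strsplit(pat, "")[[1]] !=
                    strsplit(substr(ref, s, s + P - 1), "")[[1]])
        if (mm <= max_mm) {
          out[[length(out) + 1L]] <- data.frame(
            target_id = nm, start = s, strand = strand, n_mismatch = mm)
        }
      }
    }
  }
  if (length(out) == 0) return(NULL)
  df <- do.call(rbind, out)
  df[order(df$target_id, df$strand, df$start), ]
}

test_that("simple hits are found with coordinates and mismatch detail", {
  refs <- c(r1 = "AAAACCCCGGGGTTTTACGTACGT")
  h <- map_reads(read_set("CCCCGGGG"), refs, map_params(0, strand_mode = "plus-only"))
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 5L)
  expect_equal(h$n_mismatch, 0L)

  # one substitution recorded with read/ref bases
  h2 <- map_reads(read_set("CCCTGGGG"), refs,
                  map_params(1, strand_mode = "plus-only"))
  expect_equal(h2$n_mismatch, 1L)
  d <- h2$mismatches[[1]]
  expect_equal(d$pos, 4L)
  expect_equal(d$read_base, "T")
  expect_equal(d$ref_base, "C")

  # no hit over budget
  expect_equal(nrow(map_reads(read_set("CCCTGGGG"), refs, map_params(0))), 0)
})

test_that("N-containing reads never align", {
  refs <- c(r1 = "AAAACCCCGGGGTTTT")
  expect_equal(nrow(map_reads(read_set("CCNCGGGG"), refs, map_params(2))), 0)
})

test_that("mapping equals the brute-force oracle on random instances", {
  set.seed(21)
  bases <- c("A", "C", "G", "T")
  refs <- c(ra = paste(sample(bases, 300, replace = TRUE), collapse = ""),
            rb = paste(sample(bases, 200, replace = TRUE), collapse = ""))
  for (k in 1:40) {
    # half random reads, half planted substrings with mutations
    if (k %% 2 == 0) {
      read <- paste(sample(bases, 10, replace = TRUE), collapse = "")
    } else {
      s <- sample(1:290, 1)
      read <- substr(refs[["ra"]], s, s + 9)
      p <- sample(1:10, 1)
      substr(read, p, p) <- sample(bases, 1)
    }
    got <- map_reads(read_set(read), refs, map_params(2))
    want <- oracle_map(read, as.list(refs), 2)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      got <- got[order(got$target_id, got$strand, got$start),
                 c("target_id", "start", "strand", "n_mismatch")]
      expect_equal(got, want, ignore_attr = TRUE)
    }
  }
})

test_that("minus-strand mapping is the mirror of plus-strand mapping", {
  set.seed(33)
  bases <- c("A", "C", "G", "T")
  refs <- c(r = paste(sample(bases, 400, replace = TRUE), collapse = ""))
  for (k in 1:10) {
    s <- sample(1:380, 1)
    read <- substr(refs[["r"]], s, s + 14)
    rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", read), "")[[1]]),
                collapse = "")
    h_plus <- map_reads(read_set(read), refs, map_params(1))
    h_rc <- map_reads(read_set(rc), refs, map_params(1))
    expect_setequal(paste(h_plus$start, h_plus$strand),
                    paste(h_rc$start, chartr("+-", "-+", h_rc$strand)))
  }
})

test_that("exhaustive equivalence for short reads on a short reference", {
  set.seed(55)
  ref <- c(x = paste(sample(c("A", "C", "G", "T"), 64, replace = TRUE),
                     collapse = ""))
  grid <- do.call(expand.grid, rep(list(c("A", "C", "G", "T")), 5))
  seqs <- do.call(paste0, grid)
  got_counts <- integer(length(seqs))
  want_counts <- integer(length(seqs))
  for (i in seq_along(seqs)) {
    got_counts[i] <- nrow(map_reads(read_set(seqs[i]), ref, map_params(0)))
    want <- oracle_map(seqs[i], as.list(ref), 0)
    want_counts[i] <- if (is.null(want)) 0L else nrow(want)
  }
  expect_equal(got_counts, want_counts)
})

test_that("tail splitting prefers the minimal non-template tail", {
  ref <- "ACGTACGTGT"          # template continues "GT" after position 8
  # read = template prefix + "AA": both tail bases disagree -> tail "AA"
  sp <- split_nontemplate_tail("ACGTACGTAA", ref, 1, map_params(0, 2))
  expect_equal(sp$tail, "AA")
  expect_equal(sp$core, "ACGTACGT")

  # suffix identical to template continuation: plain alignment, no tail
  sp2 <- split_nontemplate_tail("ACGTACGTGT", ref, 1, map_params(0, 2))
  expect_equal(sp2$tail, "")

  # read continues "TA" where template continues "TC": the templated T
  # belongs to the core, only "A" is tail
  sp3 <- split_nontemplate_tail("ACGTACGTTA", "ACGTACGTTC", 1,
                                map_params(0, 2))
  expect_equal(sp3$core, "ACGTACGTT")
  expect_equal(sp3$tail, "A")

  # brute-force oracle: the tail is the maximal trailing run of bases that
  # disagree with the template; valid iff run <= max_tail and core within
  # the mismatch budget
  oracle_split <- function(read, ref, start, max_mm, max_tail) {
    P <- nchar(read)
    run <- 0
    for (p in P:1) {
      tp <- start + p - 1
      b <- if (tp <= nchar(ref)) substr(ref, tp, tp) else ""
      if (!nzchar(b) || substr(read, p, p) != b) run <- run + 1 else break
    }
    if (run > max_tail || run >= P) return(NA_integer_)
    nc <- P - run
    tpl <- substr(ref, start, start + nc - 1)
    if (nchar(tpl) < nc) return(NA_integer_)
    mm <- sum(strsplit(substr(read, 1, nc), "")[[1]] !=
                strsplit(tpl, "")[[1]])
    if (mm > max_mm) return(NA_integer_)
    run
  }
  set.seed(77)
  bases <- c("A", "C", "G", "T")
  for (k in 1:60) {
    ref_r <- paste(sample(bases, 40, replace = TRUE), collapse = "")
    st <- sample(1:20, 1)
    read <- substr(ref_r, st, st + 14)
    # randomly mutate up to 3 of the last 4 bases
    for (p in sample(12:15, sample(0:3, 1))) {
      substr(read, p, p) <- sample(bases, 1)
    }
    want_t <- oracle_split(read, ref_r, st, 1, 2)
    got <- split_nontemplate_tail(read, ref_r, st, map_params(1, 2))
    if (is.na(want_t)) {
      expect_null(got)
    } else {
      expect_equal(nchar(got$tail), want_t)
    }
  }

  # tail longer than max_tail: no annotation at this locus
  expect_null(split_nontemplate_tail("ACGTACGTAAA", "ACGTACGTGTC", 1,
                                     map_params(0, 2)))
})
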