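#' Evaluate code under a temporary RNG seed
#'
#' All generators in the package route their randomness through this helper
#' so that identical seeds give byte-identical output without disturbing the
#' caller's RNG state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

#' Generate synthetic miRNA hairpin references
#'
#' Random hairpin sequences with one planted mature miRNA each, positioned
#' so that the full offset grid (+-5 nt) fits inside the hairpin. Synthetic
#' stand-ins for a miRNA reference database; real hairpin/mature collections
#' in the same header dialect are drop-in compatible.
#'
#' @param n number of hairpins.
#' @param seed integer seed.
#' @param species species tag attached to all records.
#' @param hairpin_len,mature_len sequence lengths (defaults 90 / 22).
#' @return A [mirna_ref()].
#' @export
gen_hairpins <- function(n, seed, species = "syn",
                         hairpin_len = 90L, mature_len = 22L) {
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) rand_dna(hairpin_len), character(1))
    starts <- sample(6:(hairpin_len - mature_len - 4L), n, replace = TRUE)
    hairpins <- data.frame(id = sprintf("hp%03d", seq_len(n)),
                           species = species, seq = seqs,
                           stringsAsFactors = FALSE)
    matures <- data.frame(gene = sprintf("mir%03d", seq_len(n)),
                          species = species,
                          hairpin_id = hairpins$id,
                          start = starts, end = starts + mature_len - 1L,
                          stringsAsFactors = FALSE)
    mirna_ref(hairpins, matures)
  })
}

default_tails <- function() {
  b <- c("A", "C", "G", "T")
  c("", b, as.vector(outer(b, b, paste0)))
}

#' Generate the artificial miRNA read grid
#'
#' Enumerates, for every mature miRNA in `refs`, every combination of 5'
#' offset, 3' tail and internal mismatch scenario: reads start at the mature
#' 5' end shifted by each offset, carry each tail of the tail set, and in
#' mismatch scenarios receive one random internal substitution. Tail bases
#' that would coincide with the templated continuation of the hairpin are
#' deterministically replaced by a different base, so every generated tail
#' is genuinely non-template and the truth tier labels are exact.
#'
#' @param refs a [mirna_ref()].
#' @param offsets integer offsets of the read 5' end relative to the mature
#'   5' end (default -5..5).
#' @param tails character vector of 3' tails (default: none, all 4 mono-,
#'   all 16 di-nucleotide tails).
#' @param internal_mm mismatch scenarios, subset of `0:1` (default both).
#' @param seed integer seed (drives mismatch positions/bases).
#' @param count_range read counts sampled uniformly per scenario (default a
#'   single read per scenario, the unweighted grid; a range such as `1:10`
#'   yields per-gene abundance variation for correlation analyses).
#' @return List with `reads` (a [read_set()], one read per scenario, counts
#'   collapsed) and `truth` (one row per scenario: `seq`, `gene`, `tier`,
#'   `offset`, `tail`, `n_mismatch`, `count`).
#' @export
gen_mirna_testset <- function(refs, offsets = -5:5, tails = default_tails(),
                              internal_mm = 0:1, seed = 1, count_range = 1L) {
  stopifnot(inherits(refs, "mirna_ref"))
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    rows <- list()
    hp_seq <- setNames(refs$hairpins$seq, refs$hairpins$key)
    for (m in seq_len(nrow(refs$matures))) {
      mt <- refs$matures[m, ]
      hp <- hp_seq[[mt$key]]
      mlen <- mt$end - mt$start + 1L
      for (o in offsets) {
        s <- mt$start + o
        e <- s + mlen - 1L
        if (s < 1L || e > nchar(hp)) next
        templ <- substr(hp, s, e)
        for (tl in tails) {
          tl_use <- tl
          if (nzchar(tl)) {
            tc <- strsplit(tl, "", fixed = TRUE)[[1]]
            for (ti in seq_along(tc)) {
              tpos <- e + ti
              cont <- if (tpos <= nchar(hp)) substr(hp, tpos, tpos) else ""
              if (nzchar(cont) && tc[ti] == cont) {
                tc[ti] <- bases[bases != cont][ (ti + match(cont, bases)) %% 3 + 1L]
              }
            }
            tl_use <- paste(tc, collapse = "")
          }
          for (nmm in internal_mm) {
            core <- templ
            if (nmm > 0) {
              # never mutate the terminal base: a substitution there is
              # indistinguishable from a 1-nt non-template tail, so the
              # truth label would be ill-defined
              pos <- sample.int(mlen - 1L, 1L)
              orig <- substr(core, pos, pos)
              sub <- sample(bases[bases != orig], 1L)
              substr(core, pos, pos) <- sub
            }
            tier <- if (o == 0L) {
              if (nzchar(tl_use)) "tailed" else "canonical"
            } else {
              if (nzchar(tl_use)) "tailed-offset" else "offset"
            }
            cnt <- if (length(count_range) == 1L) count_range else
              sample(count_range, 1L)
            rows[[length(rows) + 1L]] <- data.frame(
              seq = paste0(core, tl_use), gene = mt$gene, tier = tier,
              offset = o, tail = tl_use, n_mismatch = nmm, count = cnt,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    truth <- do.call(rbind, rows)
    list(reads = read_set(truth$seq, truth$count), truth = truth)
  })
}

#' Generate synthetic tRNA references with genomic flanks
#'
#' Random mature tRNA bodies (70-80 nt, never ending in CCA) with a 20-nt
#' leader and a 20-nt trailer. The trailer starts with `GTT` (disjoint from
#' `CCA` at every position, so a non-template CCA always splits cleanly) and
#' carries an oligo-T terminator signal at trailer positions 15-18.
#'
#' @param n number of tRNAs.
#' @param seed integer seed.
#' @return data.frame with columns `id`, `pad5`, `pad3`, `seq` as consumed
#'   by [annotate_ncrna()].
#' @export
gen_trnas <- function(n, seed) {
  with_seed(seed, {
    rows <- lapply(seq_len(n), function(k) {
      L <- sample(70:80, 1L)
      body <- rand_dna(L)
      while (grepl("CCA$", body)) {
        substr(body, L, L) <- sample(c("G", "T"), 1L)
      }
      leader <- rand_dna(20L)
      trailer <- paste0("GTT", rand_dna(11L, c("A", "C", "G")), "TTTT",
                        rand_dna(2L, c("A", "C", "G")))
      data.frame(id = sprintf("trna%03d", k), pad5 = 20L, pad3 = 20L,
                 seq = paste0(leader, body, trailer),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Generate the artificial tRNA-fragment read set
#'
#' Draws reads of every tRF class from each tRNA according to its cloverleaf
#' model ([build_trna_model()]), attaches random read counts, and plants one
#' random internal substitution in the stated fraction of sequences.
#'
#' @param trnas data.frame from [gen_trnas()].
#' @param mismatch_fraction fraction of sequences receiving one internal
#'   mismatch (default 0.5).
#' @param seed integer seed.
#' @return List with `reads` (a [read_set()]) and `truth` (one row per
#'   read: `seq`, `trna`, `class`, `count`, `mutated`).
#' @export
gen_trf_testset <- function(trnas, mismatch_fraction = 0.5, seed = 1) {
  with_seed(seed, {
    rows <- list()
    for (k in seq_len(nrow(trnas))) {
      mod <- build_trna_model(trnas[k, ])
      L <- mod$L
      body <- mod$body
      full <- mod$seq
      pad5 <- mod$pad5
      ac_mid <- round((mod$ac_start + mod$ac_end) / 2)
      pieces <- list(
        `5' tRF` = substr(body, 1L, mod$d_loop_end),
        `5' tR-half` = substr(body, 1L, ac_mid),
        `3' tRF` = substr(body, mod$tpsi_start, L),
        `3' CCA-tRF` = paste0(substr(body, mod$tpsi_start, L), "CCA"),
        `3' tR-half` = substr(body, ac_mid, L),
        `tRF-1` = substr(full, pad5 + L + 1L, pad5 + L + 14L),
        `tRNA-leader` = substr(full, pad5 - 14L, pad5),
        `misc-tRF` = substr(body, mod$d_loop_end + 3L, mod$d_loop_end + 22L)
      )
      for (cls in names(pieces)) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq = pieces[[cls]], trna = mod$id, class = cls,
          count = sample(1:100, 1L), stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, rows)
    n <- nrow(truth)
    mutate <- sample(seq_len(n), round(mismatch_fraction * n))
    truth$mutated <- seq_len(n) %in% mutate
    bases <- c("A", "C", "G", "T")
    for (r in mutate) {
      sq <- truth$seq[r]
      # keep a CCA 3' end (and the templated base before it) intact so the
      # class identity is preserved
      maxpos <- if (truth$class[r] == "3' CCA-tRF") nchar(sq) - 4L else nchar(sq)
      pos <- sample.int(maxpos, 1L)
      orig <- substr(sq, pos, pos)
      substr(sq, pos, pos) <- sample(bases[bases != orig], 1L)
      truth$seq[r] <- sq
    }
    list(reads = read_set(truth$seq, truth$count), truth = truth)
  })
}

#' Generate a phased small RNA map file
#'
#' Plants `n_loci` phased positions spaced `i` nt apart on a random target,
#' alternating between the plus strand (read 5' end at the register
#' position) and the minus strand (read leftmost coordinate at register + 2,
#' the 2-nt overhang duplex partner), each carrying `reads_per_pos` reads.
#' `background_reads` unphased reads of the same length are placed uniformly
#' on the target outside the planted locus, emulating genome-wide background
#' away from the phasiRNA-producing region.
#'
#' @param n_loci number of planted phased positions (0 for a pure null set).
#' @param reads_per_pos reads per phased position (e.g. 1 or 10).
#' @param i phase length (default 21).
#' @param background_reads number of uniform background reads.
#' @param seed integer seed.
#' @param target_len target sequence length (default 50000).
#' @param locus_start leftmost planted register (default 1001).
#' @return List with `alignments` (an [alignment_frame()]), `genome`
#'   (named character), and `truth` (planted positions and locus span).
#' @export
gen_phased_testset <- function(n_loci, reads_per_pos = 1, i = 21L,
                               background_reads = 0L, seed = 1,
                               target_len = 50000L, locus_start = 1001L) {
  i <- as.integer(i)
  with_seed(seed, {
    genome <- rand_dna(target_len)
    tg <- "pchr1"
    rows <- list()
    positions <- integer()
    if (n_loci > 0) {
      positions <- locus_start + (seq_len(n_loci) - 1L) * i
      for (idx in seq_along(positions)) {
        pos <- positions[idx]
        if (idx %% 2L == 1L) {
          rows[[length(rows) + 1L]] <- data.frame(
            read_seq = substr(genome, pos, pos + i - 1L), target_id = tg,
            start = pos, strand = "+", count = reads_per_pos,
            stringsAsFactors = FALSE)
        } else {
          left <- pos + 2L
          rows[[length(rows) + 1L]] <- data.frame(
            read_seq = revcomp(substr(genome, left, left + i - 1L)),
            target_id = tg, start = left, strand = "-",
            count = reads_per_pos, stringsAsFactors = FALSE)
        }
      }
    }
    if (background_reads > 0) {
      span <- if (n_loci > 0) {
        c(locus_start - i, max(positions) + 2L * i)
      } else c(0L, 0L)
      ok_pos <- setdiff(seq_len(target_len - i - 2L), span[1]:span[2])
      bpos <- sample(ok_pos, background_reads, replace = TRUE)
      bstr <- sample(c("+", "-"), background_reads, replace = TRUE)
      bseq <- substr(rep(genome, background_reads), bpos, bpos + i - 1L)
      bseq[bstr == "-"] <- revcomp(bseq[bstr == "-"])
      rows[[length(rows) + 1L]] <- data.frame(
        read_seq = bseq, target_id = tg, start = bpos, strand = bstr,
        count = 1, stringsAsFactors = FALSE)
    }
    aln <- if (length(rows)) {
      df <- do.call(rbind, rows)
      alignment_frame(read_seq = df$read_seq, target_id = df$target_id,
                      start = df$start, strand = df$strand, count = df$count)
    } else alignment_frame()
    list(alignments = aln, genome = setNames(genome, tg),
         truth = list(positions = positions, i = i,
                      register = if (n_loci > 0) positions[1] %% i else NA))
  })
}

#' Generate a ping-pong map file
#'
#' Opposite-strand read pairs on a random piRNA cluster whose 5' ends
#' overlap by exactly `offset_d` nt (or by a random 1..20 nt offset per pair
#' when `offset_d = NULL`, a signature-free null).
#'
#' @param n_pairs number of read pairs.
#' @param offset_d the planted 5' overlap (default 10); `NULL` for random.
#' @param seed integer seed.
#' @param cluster_len cluster sequence length (default 10000).
#' @return List with `alignments` (an [alignment_frame()]) and `cluster`
#'   (named character vector of the cluster sequence).
#' @export
gen_pingpong_testset <- function(n_pairs, offset_d = 10L, seed = 1,
                                 cluster_len = 10000L) {
  with_seed(seed, {
    cluster <- rand_dna(cluster_len)
    tg <- "piC1"
    rows <- list()
    for (k in seq_len(n_pairs)) {
      plen <- sample(24:30, 1L)
      mlen <- sample(24:30, 1L)
      p <- sample(seq(mlen + 25L, cluster_len - plen - 25L), 1L)
      d <- if (is.null(offset_d)) sample(1:20, 1L) else offset_d
      m5 <- p + d - 1L
      mleft <- m5 - mlen + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        read_seq = c(substr(cluster, p, p + plen - 1L),
                     revcomp(substr(cluster, mleft, m5))),
        target_id = tg, start = c(p, mleft), strand = c("+", "-"),
        count = sample(1:5, 2L, replace = TRUE), stringsAsFactors = FALSE)
    }
    df <- do.call(rbind, rows)
    list(alignments = alignment_frame(read_seq = df$read_seq,
                                      target_id = df$target_id,
                                      start = df$start, strand = df$strand,
                                      count = df$count),
         cluster = setNames(cluster, tg))
  })
}

#' Generate raw adapter-ligated reads
#'
#' Fixed-length reads built as insert + 3' adapter (+ random fill when the
#' adapter does not reach the read end), truncated to `read_len`. Truth is
#' the exact insert of each read. Inserts are redrawn if the resulting read
#' contains a near-match (within 2 substitutions) of any 12-nt adapter
#' window upstream of the true ligation point: for such a read the insert
#' boundary is genuinely ambiguous and no trimmer could define a unique
#' truth.
#'
#' @param n_reads number of reads.
#' @param adapter adapter sequence.
#' @param read_len raw read length.
#' @param seed integer seed.
#' @param insert_len_range insert lengths sampled uniformly (default 18:26).
#' @return List with `reads` (raw [read_set()]) and `truth` (data.frame
#'   `raw`, `insert`).
#' @export
gen_adapter_testset <- function(n_reads, adapter, read_len, seed = 1,
                                insert_len_range = 18:26) {
  adapter <- normalize_seq(adapter)
  windows <- character()
  for (o in seq_len(max(1L, nchar(adapter) - 11L))) {
    windows <- c(windows, substr(adapter, o, o + 11L))
  }
  windows <- windows[nchar(windows) == 12L]
  with_seed(seed, {
    make_read <- function(L) {
      repeat {
        ins <- rand_dna(L)
        x <- paste0(ins, adapter)
        while (nchar(x) < read_len) x <- paste0(x, rand_dna(read_len))
        x <- substr(x, 1L, read_len)
        spurious <- FALSE
        lim <- min(L, read_len - 12L + 1L)
        if (lim >= 1L) {
          xch <- strsplit(x, "", fixed = TRUE)[[1]]
          for (w in windows) {
            wch <- strsplit(w, "", fixed = TRUE)[[1]]
            mm <- integer(lim)
            for (k in 1:12) {
              mm <- mm + (xch[seq_len(lim) + k - 1L] != wch[k])
            }
            if (any(mm <= 2L)) {
              spurious <- TRUE
              break
            }
          }
        }
        if (!spurious) return(list(raw = x, insert = ins))
      }
    }
    lens <- if (length(insert_len_range) == 1L) {
      rep(insert_len_range, n_reads)
    } else {
      sample(insert_len_range, n_reads, replace = TRUE)
    }
    out <- lapply(lens, make_read)
    raw <- vapply(out, `[[`, character(1), "raw")
    inserts <- vapply(out, `[[`, character(1), "insert")
    list(reads = read_set(raw, 1),
         truth = data.frame(raw = raw, insert = inserts,
                            stringsAsFactors = FALSE))
  })
}

#' Generate a class-tagged synthetic ncRNA reference collection
#'
#' Random reference sequences for a set of ncRNA/cDNA classes, used to
#' exercise multi-class annotation and apportioning without any real
#' database.
#'
#' @param classes character vector of class tags.
#' @param n_per_class sequences per class.
#' @param seed integer seed.
#' @param len_range reference lengths sampled uniformly (default 120:400).
#' @return data.frame with columns `class`, `id`, `seq`.
#' @export
gen_ncrna_refs <- function(classes = c("rRNA", "snRNA", "snoRNA", "lncRNA",
                                       "protein_coding"),
                           n_per_class = 3L, seed = 1, len_range = 120:400) {
  with_seed(seed, {
    rows <- list()
    for (cl in classes) {
      for (k in seq_len(n_per_class)) {
        rows[[length(rows) + 1L]] <- data.frame(
          class = cl, id = sprintf("%s_%02d", cl, k),
          seq = rand_dna(sample(len_range, 1L)), stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, rows)
  })
}
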