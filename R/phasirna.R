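#' phasiRNA detection parameters
#'
#' @param i phase length in nt (e.g. 21 or 24); must be supplied.
#' @param window sliding window size in nt (default 1000).
#' @param step window step (default `window / 2`).
#' @param alpha significance level before Bonferroni correction over the
#'   number of analyzed windows (default 0.05).
#' @param min_phased_frac minimal fraction of phased reads among all mapped
#'   reads in a window (default 0.5).
#' @param min_loci minimal number of distinct consolidated positions
#'   occupied by phased reads (default 5).
#' @param max_strand_frac maximal fraction of phased reads from one strand
#'   (default 0.9).
#' @param inclusive if `TRUE`, the binomial tail includes `j` itself
#'   (probability of `j` or more phased reads); the default `FALSE` computes
#'   the strictly-greater tail exactly as the printed formula
#'   `p = 1 - sum_{k=0}^{j} C(n,k) q^k (1-q)^(n-k)`.
#' @return A `phase_params` list.
#' @export
phase_params <- function(i, window = 1000L, step = window %/% 2L,
                         alpha = 0.05, min_phased_frac = 0.5, min_loci = 5L,
                         max_strand_frac = 0.9, inclusive = FALSE) {
  i <- as.integer(i)
  stopifnot(i >= 2, window >= i * 8, alpha > 0, alpha < 1, step >= 1)
  structure(list(i = i, window = as.integer(window), step = as.integer(step),
                 alpha = alpha, min_phased_frac = min_phased_frac,
                 min_loci = as.integer(min_loci),
                 max_strand_frac = max_strand_frac, inclusive = inclusive),
            class = "phase_params")
}

#' Consolidate mapped reads into plus-strand phase registers
#'
#' Reads from both strands are merged into a single coordinate system:
#' a plus-strand read is represented by its 5' (leftmost) coordinate, a
#' minus-strand read by its leftmost coordinate minus 2, reflecting the
#' 2-nt 3'-overhang geometry of the small RNA duplex, so both partners of a
#' duplex land on the same phase register.
#'
#' @param alignments an [alignment_frame()].
#' @param i phase length; only reads of exactly this length are retained
#'   (`NULL` keeps all reads).
#' @return data.frame with columns `target`, `pos` (consolidated position),
#'   `strand`, `count`.
#' @export
consolidate <- function(alignments, i = NULL) {
  a <- alignments
  if (!is.null(i)) a <- a[nchar(a$read_seq) == i, , drop = FALSE]
  if (nrow(a) == 0) {
    return(data.frame(target = character(), pos = integer(),
                      strand = character(), count = numeric()))
  }
  pos <- ifelse(a$strand == "+", a$start, a$start - 2L)
  data.frame(target = a$target_id, pos = as.integer(pos),
             strand = a$strand, count = a$count, stringsAsFactors = FALSE)
}

#' Binomial phasing probability
#'
#' Probability of observing more than `j` (or at least `j`, with
#' `inclusive = TRUE`) phased reads among `n` reads of length `i` under the
#' null hypothesis that each read falls into a given phase register with
#' probability `q = 1/i`:
#' `p = 1 - sum_{k=0}^{j} C(n,k) q^k (1-q)^(n-k)`.
#'
#' @param j observed number of reads in the phase register.
#' @param n total number of reads of length `i` in the window.
#' @param i phase length.
#' @param inclusive include `j` itself in the tail (default `FALSE`, the
#'   printed formula).
#' @return The upper binomial tail probability in `[0, 1]`.
#' @examples
#' phasing_pvalue(0, 1, 21)   # 1/21
#' phasing_pvalue(10, 10, 21) # 0
#' @export
phasing_pvalue <- function(j, n, i, inclusive = FALSE) {
  stopifnot(j >= 0, j <= n, i >= 2)
  q <- 1 / i
  k <- if (inclusive) j - 1 else j
  pbinom(k, n, q, lower.tail = FALSE)
}

#' Legacy eight-cycle phase score
#'
#' The classical phase score `P = ln[(1 + sum(k))^(n-2)]`, where `n` is the
#' number of phase-cycle positions occupied by at least one read within an
#' eight-cycle window and `k` are the read counts at those positions.
#' Provided for comparison with the binomial statistic only; not used for
#' calling. For `n < 2` the exponent is undefined and 0 is returned with
#' attribute `degenerate = TRUE`.
#'
#' @param cycle_counts numeric vector of read counts at the 8 phase-cycle
#'   positions of the window (0 = unoccupied).
#' @return Phase score `P = (n - 2) * log(1 + sum(k))`.
#' @examples
#' phase_score(c(1, 1, 1, 1, 1, 1, 1, 1))  # 6 * log(8)
#' @export
phase_score <- function(cycle_counts) {
  stopifnot(length(cycle_counts) == 8)
  n <- sum(cycle_counts > 0)
  if (n < 2) return(structure(0, degenerate = TRUE))
  (n - 2) * log(1 + sum(cycle_counts))
}

#' Sliding-window phasiRNA scan
#'
#' Slides windows of `params$window` nt (step `params$step`) across each
#' target of a map file. Within a window, reads of length `i` are
#' consolidated ([consolidate()]) and the phase register (position modulo
#' `i`) with the largest count-weighted read total defines `j`; `n` is the
#' total count of length-`i` reads in the window. A window is called phased
#' iff its binomial `p` ([phasing_pvalue()]) is below
#' `alpha / (number of analyzed windows)` (strict Bonferroni; analyzed =
#' containing at least one length-`i` read), the phased reads are at least
#' `min_phased_frac` of all mapped reads in the window, occupy at least
#' `min_loci` distinct consolidated positions, and at most
#' `max_strand_frac` of them come from one strand. Overlapping called
#' windows are merged into maximal runs for reporting; the phasiRNA
#' sequences of all called windows are returned deduplicated.
#'
#' @param alignments an [alignment_frame()], e.g. from [parse_map_file()].
#' @param params a [phase_params()].
#' @return List with `windows` (one row per analyzed window: coordinates,
#'   `j`, `n`, `p`, per-filter flags, `called`), `clusters` (merged runs of
#'   called windows), and `phasirna` (data.frame of called phased sequences
#'   with counts).
#' @export
scan_windows <- function(alignments, params) {
  stopifnot(inherits(params, "phase_params"))
  i <- params$i
  cons_i <- consolidate(alignments, i)
  cons_all <- consolidate(alignments, NULL)
  win_rows <- list()
  for (tg in sort(unique(cons_i$target))) {
    ci <- cons_i[cons_i$target == tg, , drop = FALSE]
    ca <- cons_all[cons_all$target == tg, , drop = FALSE]
    lo <- min(ci$pos)
    hi <- max(ci$pos)
    starts <- seq(from = lo - (lo - 1L) %% params$step, to = hi,
                  by = params$step)
    for (ws in starts) {
      we <- ws + params$window - 1L
      sel <- ci$pos >= ws & ci$pos <= we
      if (!any(sel)) next
      w <- ci[sel, , drop = FALSE]
      reg <- w$pos %% i
      reg_tot <- tapply(w$count, reg, sum)
      win_reg <- as.integer(names(reg_tot)[order(-reg_tot,
                                                 as.integer(names(reg_tot)))][1])
      phased <- w[reg == win_reg, , drop = FALSE]
      j <- sum(phased$count)
      n <- sum(w$count)
      total_all <- sum(ca$count[ca$pos >= ws & ca$pos <= we])
      p <- phasing_pvalue(j, n, i, inclusive = params$inclusive)
      strand_tot <- tapply(phased$count, phased$strand, sum)
      max_strand <- max(strand_tot) / j
      win_rows[[length(win_rows) + 1L]] <- data.frame(
        target = tg, start = ws, end = we, register = win_reg,
        j = j, n = n, total_reads = total_all, p = p,
        phased_frac = j / total_all,
        n_loci = length(unique(phased$pos)),
        max_strand_frac = max_strand, stringsAsFactors = FALSE)
    }
  }
  if (length(win_rows) == 0) {
    empty <- data.frame(target = character(), start = integer(),
                        end = integer(), register = integer(), j = numeric(),
                        n = numeric(), total_reads = numeric(), p = numeric(),
                        phased_frac = numeric(), n_loci = integer(),
                        max_strand_frac = numeric(), p_pass = logical(),
                        called = logical())
    return(list(windows = empty, clusters = empty[0, 1:3],
                phasirna = data.frame(seq = character(), count = numeric())))
  }
  windows <- do.call(rbind, win_rows)
  n_win <- nrow(windows)
  windows$p_pass <- windows$p < params$alpha / n_win
  windows$frac_pass <- windows$phased_frac >= params$min_phased_frac
  windows$loci_pass <- windows$n_loci >= params$min_loci
  windows$strand_pass <- windows$max_strand_frac <= params$max_strand_frac
  windows$called <- windows$p_pass & windows$frac_pass &
    windows$loci_pass & windows$strand_pass
  windows <- windows[order(windows$target, windows$start), , drop = FALSE]
  rownames(windows) <- NULL

  # merge overlapping called windows into maximal runs
  cl <- windows[windows$called, c("target", "start", "end"), drop = FALSE]
  clusters <- list()
  if (nrow(cl) > 0) {
    for (tg in unique(cl$target)) {
      x <- cl[cl$target == tg, , drop = FALSE]
      x <- x[order(x$start), , drop = FALSE]
      cs <- x$start[1]; ce <- x$end[1]
      for (k in seq_len(nrow(x))[-1]) {
        if (x$start[k] <= ce + 1L) {
          ce <- max(ce, x$end[k])
        } else {
          clusters[[length(clusters) + 1L]] <- data.frame(
            target = tg, start = cs, end = ce)
          cs <- x$start[k]; ce <- x$end[k]
        }
      }
      clusters[[length(clusters) + 1L]] <- data.frame(
        target = tg, start = cs, end = ce)
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    data.frame(target = character(), start = integer(), end = integer())

  # collect phased sequences of called windows, deduplicated
  phas <- list()
  called <- windows[windows$called, , drop = FALSE]
  if (nrow(called) > 0) {
    ai <- alignments[nchar(alignments$read_seq) == i, , drop = FALSE]
    cpos <- ifelse(ai$strand == "+", ai$start, ai$start - 2L)
    for (k in seq_len(nrow(called))) {
      sel <- ai$target_id == called$target[k] &
        cpos >= called$start[k] & cpos <= called$end[k] &
        cpos %% i == called$register[k]
      if (any(sel)) {
        phas[[length(phas) + 1L]] <- data.frame(
          seq = ai$read_seq[sel], count = ai$count[sel],
          stringsAsFactors = FALSE)
      }
    }
  }
  phasirna <- if (length(phas)) {
    x <- do.call(rbind, phas)
    x <- x[!duplicated(x$seq), , drop = FALSE]
    rownames(x) <- NULL
    x[order(x$seq), , drop = FALSE]
  } else data.frame(seq = character(), count = numeric())

  list(windows = windows, clusters = clusters, phasirna = phasirna)
}
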