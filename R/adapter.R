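#' Adapter motif length rule
#'
#' The length `m` of the 3' adapter motif searched for in raw reads is tied
#' to the raw read length `n` by `m = n - 22` (22 nt being a typical miRNA
#' length), clamped into `6 <= m <= 12`.
#'
#' @param n raw sequence read length.
#' @return Motif length, an integer in 6..12.
#' @examples
#' infer_motif_length(34)  # 12
#' infer_motif_length(28)  # 6
#' @export
infer_motif_length <- function(n) {
  stopifnot(n >= 1)
  pmin(pmax(as.integer(n) - 22L, 6L), 12L)
}

#' Mismatch allowance for an adapter motif
#'
#' Adapter motif matching tolerates 2 mismatches for 12 nt motifs,
#' 1 mismatch for motifs of 9-11 nt and 0 mismatches for motifs of 6-8 nt.
#'
#' @param motif_len motif length in 6..12.
#' @return Integer mismatch allowance.
#' @export
mismatch_allowance <- function(motif_len) {
  motif_len <- as.integer(motif_len)
  if (any(motif_len < 6L | motif_len > 12L)) {
    stop("motif length must be within 6..12")
  }
  ifelse(motif_len >= 12L, 2L, ifelse(motif_len >= 9L, 1L, 0L))
}

#' Infer the 3' adapter motif from raw reads
#'
#' Identifies the most frequently occurring m-mer in the read set, ignoring
#' read positions 1..`ignore_5p` (default 22, a typical miRNA length, so that
#' the frequent motif reflects the adapter rather than abundant small RNAs).
#' The motif length is derived from the modal raw read length via
#' [infer_motif_length()]. Counting is weighted by read count; ties are
#' broken lexicographically.
#'
#' @param reads a [read_set()] of raw (untrimmed) reads.
#' @param ignore_5p number of 5' positions excluded from motif counting.
#' @param bias_threshold positional nucleotide bias threshold stored in the
#'   model for the subsequent over-trimming step (default 0.8).
#' @return An `adapter_model` list with elements `motif`, `read_length`,
#'   `ignore_5p`, `bias_threshold`.
#' @export
detect_adapter <- function(reads, ignore_5p = 22, bias_threshold = 0.8) {
  stopifnot(inherits(reads, "read_set"), nrow(reads) > 0)
  lens <- nchar(reads$seq)
  len_tab <- tapply(reads$count, lens, sum)
  n <- as.integer(names(len_tab)[order(-len_tab, as.integer(names(len_tab)))][1])
  m <- infer_motif_length(n)
  first <- as.integer(ignore_5p) + 1L
  usable <- lens >= first + m - 1L
  if (!any(usable)) {
    stop("no ", m, "-mer observable beyond position ", ignore_5p,
         "; reads too short - consider lowering trim_ignore_5p")
  }
  counts <- new.env(parent = emptyenv())
  seqs <- reads$seq[usable]
  wts <- reads$count[usable]
  maxlen <- max(nchar(seqs))
  acc <- list()
  for (p in first:(maxlen - m + 1L)) {
    ok <- nchar(seqs) >= p + m - 1L
    if (!any(ok)) next
    kmer <- substr(seqs[ok], p, p + m - 1L)
    acc[[length(acc) + 1L]] <- data.frame(kmer = kmer, w = wts[ok])
  }
  all_k <- do.call(rbind, acc)
  all_k <- all_k[!grepl("N", all_k$kmer, fixed = TRUE), , drop = FALSE]
  if (nrow(all_k) == 0) stop("no adapter motif observable (all candidate k-mers contain N)")
  tab <- tapply(all_k$w, all_k$kmer, sum)
  best <- names(tab)[order(-tab, names(tab))][1]
  structure(list(motif = best, read_length = n,
                 ignore_5p = as.integer(ignore_5p),
                 bias_threshold = bias_threshold),
            class = "adapter_model")
}

#' Adapter model from a known motif
#'
#' Builds an `adapter_model` directly from a user-supplied adapter sequence
#' (its first 6-12 nt are used as the motif), bypassing inference.
#'
#' @param adapter adapter sequence (>= 6 nt).
#' @param ignore_5p,bias_threshold see [detect_adapter()].
#' @return An `adapter_model`.
#' @export
adapter_model <- function(adapter, ignore_5p = 22, bias_threshold = 0.8) {
  adapter <- normalize_seq(adapter)
  if (nchar(adapter) < 6) stop("adapter sequence must be at least 6 nt")
  structure(list(motif = substr(adapter, 1, 12), read_length = NA_integer_,
                 ignore_5p = as.integer(ignore_5p),
                 bias_threshold = bias_threshold),
            class = "adapter_model")
}

# mismatch counts of `motif` placed at positions `starts` of each sequence;
# vectorized over sequences, fixed position
motif_mismatch_at <- function(seqs, motif, pos) {
  m <- nchar(motif)
  mm <- integer(length(seqs))
  mo <- strsplit(motif, "", fixed = TRUE)[[1]]
  for (k in seq_len(m)) {
    mm <- mm + (substr(seqs, pos + k - 1L, pos + k - 1L) != mo[k])
  }
  mm
}

#' Trim the 3' adapter from reads
#'
#' For each read, searches for the leftmost occurrence of the full adapter
#' motif within the mismatch allowance of its length and cuts the read there.
#' If the full motif is not found, the motif is truncated by one 3' nt at a
#' time (re-deriving the mismatch allowance from the truncated length) and
#' tested as a suffix of the read only, down to 6 nt. Reads without any
#' match are left unchanged; reads trimmed to zero length are discarded.
#'
#' @param reads a [read_set()].
#' @param model an `adapter_model` from [detect_adapter()] or
#'   [adapter_model()].
#' @return Trimmed [read_set()].
#' @export
trim_reads <- function(reads, model) {
  stopifnot(inherits(reads, "read_set"), inherits(model, "adapter_model"))
  if (nrow(reads) == 0) return(reads)
  motif <- model$motif
  m <- nchar(motif)
  allow_full <- mismatch_allowance(m)
  seqs <- reads$seq
  lens <- nchar(seqs)
  cut_at <- rep(NA_integer_, length(seqs))  # first adapter base position

  # pass 1: full motif, leftmost occurrence anywhere in the read
  maxpos <- max(lens) - m + 1L
  if (maxpos >= 1L) {
    for (p in seq_len(maxpos)) {
      open <- is.na(cut_at) & lens >= p + m - 1L
      if (!any(open)) next
      mm <- motif_mismatch_at(seqs[open], motif, p)
      hit <- which(open)[mm <= allow_full]
      cut_at[hit] <- p
    }
  }

  # pass 2: truncated motif as read 3' suffix only
  if (m > 6L) {
    for (ml in (m - 1L):6L) {
      sub_motif <- substr(motif, 1L, ml)
      allow <- mismatch_allowance(ml)
      open <- is.na(cut_at) & lens >= ml
      if (!any(open)) next
      pos <- lens[open] - ml + 1L
      mm <- integer(sum(open))
      mo <- strsplit(sub_motif, "", fixed = TRUE)[[1]]
      for (k in seq_len(ml)) {
        mm <- mm + (substr(seqs[open], pos + k - 1L, pos + k - 1L) != mo[k])
      }
      hit <- which(open)[mm <= allow]
      cut_at[hit] <- lens[hit] - ml + 1L
    }
  }

  trimmed <- ifelse(is.na(cut_at), seqs, substr(seqs, 1L, cut_at - 1L))
  keep <- nzchar(trimmed)
  if (!any(keep)) return(read_set())
  read_set(trimmed[keep], reads$count[keep])
}

#' Positional nucleotide bias over-trimming
#'
#' After motif-based trimming, residual adapter bases can remain as a biased
#' nucleotide at the 3' terminus. Reads are aligned at their 3' ends; while
#' the count-weighted most frequent terminal base exceeds `bias_threshold`,
#' that base is stripped from all reads ending in it, and the check repeats
#' inward (at most `max_strip` positions).
#'
#' @param reads a motif-trimmed [read_set()].
#' @param bias_threshold bias fraction in (0, 1] (default 0.8).
#' @param max_strip maximum number of terminal positions stripped.
#' @return A [read_set()].
#' @export
positional_bias_trim <- function(reads, bias_threshold = 0.8, max_strip = 5L) {
  stopifnot(inherits(reads, "read_set"))
  if (nrow(reads) == 0) return(reads)
  seqs <- reads$seq
  counts <- reads$count
  for (it in seq_len(max_strip)) {
    lens <- nchar(seqs)
    term <- substr(seqs, lens, lens)
    freq <- weighted_base_freq(term, counts)
    if (sum(freq) == 0) break
    frac <- freq / sum(freq)
    top <- names(frac)[order(-frac, names(frac))][1]
    # strictly exceed the threshold; a universal terminal base (fraction 1)
    # is always treated as bias so that threshold 1 remains meaningful
    if (!(frac[[top]] > bias_threshold || frac[[top]] == 1)) break
    affected <- term == top
    seqs[affected] <- substr(seqs[affected], 1L, lens[affected] - 1L)
    keep <- nzchar(seqs)
    seqs <- seqs[keep]
    counts <- counts[keep]
    if (length(seqs) == 0) break
  }
  read_set(seqs, counts)
}
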