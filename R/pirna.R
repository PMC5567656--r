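#' Call piRNA candidates by piRNA-cluster mapping
#'
#' Reads not annotated as (a fragment of) any other ncRNA class are mapped
#' to known piRNA-producing loci (cluster sequences). Because piRNAs are
#' sequence-diverse, a read with at least one hit on a cluster is labeled a
#' piRNA candidate; mapping is exact by default.
#'
#' @param reads a [read_set()] (post-ncRNA remainder).
#' @param cluster_refs data.frame with columns `id`, `seq` (as in the
#'   `clusters` component of [read_reference_fasta()]), or a named character
#'   vector of cluster sequences.
#' @param max_mismatch mapping mismatch allowance (default 0).
#' @return List with `candidates` and `not_annotated` [read_set()]s and
#'   `alignments` (an [alignment_frame()] of all candidate hits).
#' @export
call_pirna_candidates <- function(reads, cluster_refs, max_mismatch = 0L) {
  stopifnot(inherits(reads, "read_set"))
  if (is.data.frame(cluster_refs)) {
    cluster_refs <- setNames(cluster_refs$seq, cluster_refs$id)
  }
  if (nrow(reads) == 0 || length(cluster_refs) == 0) {
    return(list(candidates = read_set(), not_annotated = reads,
                alignments = alignment_frame()))
  }
  aln <- map_reads(reads, cluster_refs,
                   map_params(max_mismatch = max_mismatch, max_tail = 0L,
                              strand_mode = "both"))
  hit <- reads$seq %in% aln$read_seq
  list(candidates = as_read_set(reads[hit, , drop = FALSE]),
       not_annotated = as_read_set(reads[!hit, , drop = FALSE]),
       alignments = aln)
}

#' 5' overlap histogram of opposite-strand read pairs
#'
#' For every pair of reads mapped to opposite strands of the same target
#' whose 5' ends overlap by `d` nt (`d` in 1..20), the product of the two
#' read counts is added to bin `d`. An exact 10-nt overlap enrichment is the
#' ping-pong signature of secondary piRNA biogenesis.
#'
#' The 5' end of a plus-strand read is its leftmost coordinate; the 5' end
#' of a minus-strand read is its rightmost coordinate on the plus strand.
#' The overlap is `d = (minus 5' coordinate) - (plus 5' coordinate) + 1`.
#'
#' @param alignments an [alignment_frame()] with columns `target_id`,
#'   `start`, `strand`, `count` and `read_seq` (for read lengths).
#' @param d_range overlaps tallied (default 1..20).
#' @return Named numeric vector of weighted pair counts, one bin per `d`.
#' @export
pingpong_histogram <- function(alignments, d_range = 1:20) {
  a <- alignments
  bins <- setNames(numeric(length(d_range)), d_range)
  if (is.null(a) || nrow(a) == 0) return(bins)
  len <- nchar(a$read_seq)
  five <- ifelse(a$strand == "+", a$start, a$start + len - 1L)
  for (tg in unique(a$target_id)) {
    sel <- a$target_id == tg
    p5 <- five[sel & a$strand == "+"]
    pc <- a$count[sel & a$strand == "+"]
    m5 <- five[sel & a$strand == "-"]
    mc <- a$count[sel & a$strand == "-"]
    if (length(p5) == 0 || length(m5) == 0) next
    ptab <- tapply(pc, p5, sum)
    mtab <- tapply(mc, m5, sum)
    ppos <- as.integer(names(ptab))
    for (d in d_range) {
      partner <- as.character(ppos + d - 1L)
      found <- partner %in% names(mtab)
      if (any(found)) {
        bins[as.character(d)] <- bins[as.character(d)] +
          sum(ptab[found] * mtab[partner[found]])
      }
    }
  }
  bins
}

#' Ping-pong Z-score
#'
#' Standard score of the 10-nt overlap bin against the background of all
#' other overlap bins (1..9 and 11..20): `z = (count[10] - mean(bg)) /
#' sd(bg)` with the sample standard deviation. Undefined (NA) when the
#' background is constant.
#'
#' @param overlap_counts named vector from [pingpong_histogram()].
#' @param signal_d the signature overlap (default 10).
#' @return Numeric Z-score, or `NA` if the background sd is zero.
#' @export
pingpong_zscore <- function(overlap_counts, signal_d = 10) {
  nm <- as.integer(names(overlap_counts))
  if (is.null(nm) || anyNA(nm)) nm <- seq_along(overlap_counts)
  bg <- overlap_counts[nm != signal_d]
  s <- sd(bg)
  if (is.na(s) || s == 0) return(NA_real_)
  (overlap_counts[[as.character(signal_d)]] - mean(bg)) / s
}
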