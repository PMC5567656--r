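#' Low-complexity filter parameters
#'
#' @param f_threshold length-fraction threshold `f` (default 0.75): reads
#'   with more than this fraction covered by one repetitive motif are
#'   rejected, and reads composed of more than `f + (1 - f) * f` of only two
#'   nucleotides are rejected.
#' @param motif_lengths motif lengths considered (default 1..5).
#' @return A `complexity_params` list.
#' @export
complexity_params <- function(f_threshold = 0.75, motif_lengths = 1:5) {
  stopifnot(f_threshold > 0, f_threshold <= 1, all(motif_lengths >= 1))
  structure(list(f_threshold = f_threshold,
                 motif_lengths = as.integer(motif_lengths)),
            class = "complexity_params")
}

# primitive root of a motif ("ACAC" -> "AC", "AAA" -> "A")
primitive_root <- function(motif) {
  L <- nchar(motif)
  for (d in seq_len(L)) {
    if (L %% d == 0L) {
      root <- substr(motif, 1L, d)
      if (strrep(root, L %/% d) == motif) return(root)
    }
  }
  motif
}

#' Repetitive-motif length fraction of a sequence
#'
#' For every motif of the given lengths occurring in the sequence, computes
#' the fraction of the sequence covered by non-overlapping occurrences of
#' that motif (greedy left-to-right), and returns the maximum. Motifs that
#' are themselves periodic are canonicalized to their primitive root before
#' counting, so e.g. "AA" does not double-count runs of "A".
#'
#' @param seq a single DNA sequence.
#' @param motif_lengths motif lengths considered (default 1..5).
#' @return The maximal covered length fraction `f` in (0, 1].
#' @examples
#' repeat_fraction("ACACACACACACACACACAC")  # 1
#' @export
repeat_fraction <- function(seq, motif_lengths = 1:5) {
  stopifnot(nzchar(seq))
  seq <- normalize_seq(seq)
  n <- nchar(seq)
  best <- 0
  seen <- character()
  for (L in motif_lengths) {
    if (L > n) next
    motifs <- unique(substring(seq, 1:(n - L + 1L), L:n))
    motifs <- unique(vapply(motifs, primitive_root, character(1),
                            USE.NAMES = FALSE))
    motifs <- setdiff(motifs, seen)
    seen <- c(seen, motifs)
    for (mo in motifs) {
      Lm <- nchar(mo)
      cnt <- 0L
      p <- 1L
      while (p + Lm - 1L <= n) {
        if (substr(seq, p, p + Lm - 1L) == mo) {
          cnt <- cnt + 1L
          p <- p + Lm
        } else {
          p <- p + 1L
        }
      }
      best <- max(best, cnt * Lm / n)
    }
  }
  best
}

#' Two-nucleotide composition fraction
#'
#' Maximum, over the six unordered base pairs, of the fraction of sequence
#' positions drawn from that pair.
#'
#' @param seq a single DNA sequence.
#' @return Fraction in (0, 1].
#' @examples
#' two_nt_fraction("AGAGAGGGAA")  # 1
#' @export
two_nt_fraction <- function(seq) {
  stopifnot(nzchar(seq))
  ch <- strsplit(normalize_seq(seq), "", fixed = TRUE)[[1]]
  pairs <- utils::combn(c("A", "C", "G", "T"), 2, simplify = FALSE)
  max(vapply(pairs, function(p) mean(ch %in% p), numeric(1)))
}

#' Low-complexity decision for a read
#'
#' A read is rejected as low complexity if its repetitive-motif fraction
#' exceeds `f`, or if the fraction of positions composed of only two
#' specific nucleotides exceeds `f' = f + (1 - f) * f` (0.9375 at the
#' default `f = 0.75`). Both inequalities are strict.
#'
#' @param seq a single DNA sequence.
#' @param params a [complexity_params()].
#' @return Logical: `TRUE` if the read is low complexity.
#' @export
is_low_complexity <- function(seq, params = complexity_params()) {
  f <- params$f_threshold
  if (repeat_fraction(seq, params$motif_lengths) > f) return(TRUE)
  two_nt_fraction(seq) > f + (1 - f) * f
}

#' Split a read set into retained and low-complexity rejected reads
#'
#' @param reads a [read_set()].
#' @param params a [complexity_params()].
#' @return List with elements `kept` and `rejected`, both [read_set()]s.
#' @export
filter_low_complexity <- function(reads, params = complexity_params()) {
  stopifnot(inherits(reads, "read_set"))
  if (nrow(reads) == 0) return(list(kept = reads, rejected = read_set()))
  low <- vapply(reads$seq, is_low_complexity, logical(1), params = params,
                USE.NAMES = FALSE)
  list(kept = as_read_set(reads[!low, , drop = FALSE]),
       rejected = as_read_set(reads[low, , drop = FALSE]))
}
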