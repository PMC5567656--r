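#' Collapsed small RNA read set
#'
#' A `read_set` stores the unique sequences of a small RNA library together
#' with their integer read counts. All annotation functions in the package
#' operate on this collapsed representation so that a sequence observed many
#' times is processed once and weighted by its count.
#'
#' @param seq character vector of DNA sequences (uppercase `A`/`C`/`G`/`T`/`N`;
#'   lowercase and `U` are normalized on construction).
#' @param count integer vector of positive read counts, recycled if length 1.
#' @return An object of class `read_set`: a data.frame with columns `seq` and
#'   `count`, one row per unique sequence.
#' @examples
#' rs <- read_set(c("ACGTACGT", "ACGTACGT", "TTTTACGT"), c(2, 1, 5))
#' total_reads(rs)   # 8
#' @export
read_set <- function(seq = character(), count = 1L) {
  if (length(seq) == 0) {
    out <- data.frame(seq = character(), count = numeric())
    class(out) <- c("read_set", "data.frame")
    return(out)
  }
  seq <- normalize_seq(as.character(seq))
  count <- rep_len(as.numeric(count), length(seq))
  if (any(is.na(count)) || any(count <= 0)) {
    stop("read counts must be positive")
  }
  if (any(!nzchar(seq))) stop("empty sequences are not allowed in a read_set")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("invalid characters in sequence(s): ",
         paste(head(seq[bad], 3), collapse = ", "))
  }
  tot <- tapply(count, seq, sum)
  out <- data.frame(seq = names(tot), count = as.numeric(tot),
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$seq), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("read_set", "data.frame")
  out
}

#' Total number of reads in a read set
#'
#' @param x a [read_set()].
#' @return Numeric scalar, the sum of per-sequence read counts.
#' @export
total_reads <- function(x) {
  stopifnot(inherits(x, "read_set"))
  sum(x$count)
}

#' @export
print.read_set <- function(x, ...) {
  cat(sprintf("read_set: %d unique sequences, %s reads\n",
              nrow(x), format(total_reads(x))))
  if (nrow(x) > 0) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

# internal: keep class after subsetting
as_read_set <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("read_set", "data.frame")
  df
}
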