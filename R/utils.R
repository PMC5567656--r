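#' @importFrom stats pbinom sd setNames aggregate
#' @importFrom utils head tail write.table read.table
NULL

# reverse complement of plain character vectors (DNA, N allowed)
revcomp <- function(x) {
  comp <- chartr("ACGTN", "TGCAN", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# uppercase and convert RNA alphabet to DNA
normalize_seq <- function(x) {
  chartr("U", "T", toupper(x))
}

# split sequences into a character matrix padded with NA (rows = reads)
seq_char_list <- function(x) strsplit(x, "", fixed = TRUE)

# count-weighted base frequency table over a character vector of single bases
weighted_base_freq <- function(bases, counts) {
  keep <- bases %in% c("A", "C", "G", "T")
  tab <- tapply(counts[keep], bases[keep], sum)
  out <- setNames(numeric(4), c("A", "C", "G", "T"))
  out[names(tab)] <- tab
  out
}

# hamming distance between two equal-length strings
str_mismatches <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  which(ca != cb)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
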