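#' Read small RNA sequences from FASTA/FASTQ/collapsed FASTA
#'
#' Reads a sequence file and collapses it into a [read_set()]. Identical
#' sequences are merged with summed counts, sequences are uppercased and
#' `U` is converted to `T`. In `"collapsed-fasta"` format the read count of
#' each record is taken from its header, which must end in an integer count
#' in one of the two widespread dialects `>name-COUNT` or `>name COUNT`;
#' headers without a trailing integer default to count 1 with a warning.
#'
#' @param path path to the input file.
#' @param format one of `"fasta"`, `"fastq"`, `"collapsed-fasta"`.
#' @return A [read_set()].
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1-120", "ACGT", ">s2-3", "GGGC"), fa)
#' read_sequences(fa, format = "collapsed-fasta")
#' @export
read_sequences <- function(path, format = c("fasta", "fastq", "collapsed-fasta")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file not found: ", path)
  bio_fmt <- if (format == "fastq") "fastq" else "fasta"
  recs <- tryCatch(
    Biostrings::readBStringSet(path, format = bio_fmt),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (length(recs) == 0) return(read_set())
  seqs <- as.character(recs)
  counts <- rep(1, length(recs))
  if (format == "collapsed-fasta") {
    counts <- parse_collapsed_counts(names(recs))
  }
  read_set(seqs, counts)
}

# parse ">name-COUNT" / ">name COUNT" collapsed header dialects
parse_collapsed_counts <- function(headers) {
  m <- regmatches(headers, regexpr("[-[:space:]](-?[0-9]+)[[:space:]]*$", headers))
  counts <- rep(NA_real_, length(headers))
  has <- lengths(regmatches(headers,
                            gregexpr("[-[:space:]]-?[0-9]+[[:space:]]*$", headers))) > 0
  counts[has] <- as.numeric(sub("^[-[:space:]]", "", m))
  if (any(!is.na(counts) & counts <= 0)) {
    stop("collapsed FASTA header with non-positive read count: ",
         headers[which(!is.na(counts) & counts <= 0)[1]])
  }
  if (anyNA(counts)) {
    warning(sum(is.na(counts)),
            " collapsed FASTA header(s) without a trailing integer count; ",
            "assuming count 1")
    counts[is.na(counts)] <- 1
  }
  counts
}

#' Construct a table of ungapped alignment records
#'
#' The common container for hits of reads on references or on a genome.
#' `start` is the 1-based leftmost coordinate on the target's plus strand;
#' `read_seq` is always stored in read orientation (for minus-strand hits the
#' aligned target region is its reverse complement).
#'
#' @param read_seq,target_id,start,strand,count,n_mismatch vectors, recycled
#'   to a common length.
#' @param tail optional non-template 3' suffix already split off `read_seq`'s
#'   alignment (empty string when none).
#' @return data.frame of class `alignment_frame`.
#' @export
alignment_frame <- function(read_seq = character(), target_id = character(),
                            start = integer(), strand = "+", count = 1,
                            n_mismatch = 0L, tail = "") {
  n <- max(length(read_seq), length(target_id), length(start))
  out <- data.frame(
    read_seq = rep_len(as.character(read_seq), n),
    target_id = rep_len(as.character(target_id), n),
    start = rep_len(as.integer(start), n),
    strand = rep_len(as.character(strand), n),
    count = rep_len(as.numeric(count), n),
    n_mismatch = rep_len(as.integer(n_mismatch), n),
    tail = rep_len(as.character(tail), n),
    stringsAsFactors = FALSE
  )
  if (n > 0 && any(out$start < 1)) stop("alignment coordinates must be >= 1")
  if (n > 0 && !all(out$strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-'")
  }
  class(out) <- c("alignment_frame", "data.frame")
  out
}

as_alignment_frame <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("alignment_frame", "data.frame")
  df
}

#' Parse a SAM or ELAND3 map file
#'
#' Reads genome/reference map files into an [alignment_frame()]. For SAM,
#' only primary ungapped hits are consumed: unmapped records are dropped and
#' records whose CIGAR is not a pure match (`<n>M`) are skipped with a
#' warning. Minus-strand SAM sequences are reverse-complemented back to read
#' orientation. Read counts are taken from the collapsed read-name dialect
#' (`name-COUNT`), defaulting to 1.
#'
#' The ELAND3 dialect used here has 6 tab-separated columns:
#' target, 1-based position, sequence (read orientation), read count,
#' strand (`+`/`-`), mismatch count.
#'
#' @param path path to the map file.
#' @param dialect `"sam"` or `"eland3"`.
#' @return An [alignment_frame()].
#' @export
parse_map_file <- function(path, dialect = c("sam", "eland3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("map file not found: ", path)
  lines <- readLines(path)
  if (dialect == "sam") parse_sam_lines(lines) else parse_eland3_lines(lines)
}

parse_sam_lines <- function(lines) {
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (length(lines) == 0) return(alignment_frame())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 11
  if (any(short)) {
    stop("malformed SAM record at data line ", which(short)[1])
  }
  qname <- vapply(fields, `[[`, character(1), 1)
  flag <- as.integer(vapply(fields, `[[`, character(1), 2))
  rname <- vapply(fields, `[[`, character(1), 3)
  pos <- as.integer(vapply(fields, `[[`, character(1), 4))
  cigar <- vapply(fields, `[[`, character(1), 6)
  seq <- toupper(vapply(fields, `[[`, character(1), 10))
  nm <- vapply(fields, function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1])) else 0L
  }, integer(1))

  mapped <- bitwAnd(flag, 4L) == 0L
  qname <- qname[mapped]; flag <- flag[mapped]; rname <- rname[mapped]
  pos <- pos[mapped]; cigar <- cigar[mapped]; seq <- seq[mapped]; nm <- nm[mapped]
  if (length(pos) == 0) return(alignment_frame())
  if (any(pos < 1)) stop("SAM coordinate < 1")

  gapped <- !grepl("^[0-9]+M$", cigar)
  if (any(gapped)) {
    warning(sum(gapped), " SAM record(s) with non-match CIGAR skipped")
    qname <- qname[!gapped]; flag <- flag[!gapped]; rname <- rname[!gapped]
    pos <- pos[!gapped]; seq <- seq[!gapped]; nm <- nm[!gapped]
  }
  if (length(pos) == 0) return(alignment_frame())
  minus <- bitwAnd(flag, 16L) == 16L
  seq[minus] <- revcomp(seq[minus])
  count <- rep(1, length(qname))
  hit <- grepl("-[0-9]+$", qname)
  count[hit] <- as.numeric(sub("^.*-([0-9]+)$", "\\1", qname[hit]))
  alignment_frame(read_seq = seq, target_id = rname, start = pos,
                  strand = ifelse(minus, "-", "+"), count = count,
                  n_mismatch = nm)
}

parse_eland3_lines <- function(lines) {
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(alignment_frame())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) != 6
  if (any(bad)) stop("malformed ELAND3 record at data line ", which(bad)[1])
  pos <- as.integer(vapply(fields, `[[`, character(1), 2))
  if (anyNA(pos) || any(pos < 1)) stop("ELAND3 coordinate < 1 or non-numeric")
  alignment_frame(
    read_seq = toupper(vapply(fields, `[[`, character(1), 3)),
    target_id = vapply(fields, `[[`, character(1), 1),
    start = pos,
    strand = vapply(fields, `[[`, character(1), 5),
    count = as.numeric(vapply(fields, `[[`, character(1), 4)),
    n_mismatch = as.integer(vapply(fields, `[[`, character(1), 6))
  )
}

#' Write alignment records to a map file
#'
#' Inverse of [parse_map_file()] for both supported dialects. SAM output uses
#' the collapsed read-name dialect `seq<i>-<count>` so that read counts
#' survive a round trip, and stores mismatch counts in the `NM` tag.
#'
#' @param alignments an [alignment_frame()].
#' @param path output path.
#' @param dialect `"sam"` or `"eland3"`.
#' @return `path`, invisibly.
#' @export
write_map_file <- function(alignments, path, dialect = c("sam", "eland3")) {
  dialect <- match.arg(dialect)
  a <- alignments
  if (dialect == "eland3") {
    lines <- sprintf("%s\t%d\t%s\t%s\t%s\t%d",
                     a$target_id, a$start, a$read_seq,
                     format(a$count, trim = TRUE, scientific = FALSE),
                     a$strand, a$n_mismatch)
  } else {
    minus <- a$strand == "-"
    seq_out <- a$read_seq
    seq_out[minus] <- revcomp(seq_out[minus])
    lines <- sprintf("seq%d-%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                     seq_len(nrow(a)),
                     format(a$count, trim = TRUE, scientific = FALSE),
                     ifelse(minus, 16L, 0L), a$target_id, a$start,
                     nchar(a$read_seq), seq_out, a$n_mismatch)
  }
  writeLines(lines, path)
  invisible(path)
}

# write a data.frame as a tab-separated table with a '#'-prefixed header line
write_tsv_table <- function(df, path) {
  header <- paste0("#", paste(names(df), collapse = "\t"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  if (nrow(df) > 0) {
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Write annotation result tables to a directory
#'
#' Writes the deterministic (key-sorted) tab-separated result tables of a
#' pipeline run: per-class summary counts, the miRNA hit table, the tRF
#' table, the phasing window table, the read length distribution and the
#' positional nucleotide composition. All files are UTF-8 with a header line
#' starting `#`.
#'
#' @param result a result list as returned by [run_pipeline()].
#' @param outdir output directory, created if missing.
#' @return Character vector of written file paths, invisibly.
#' @export
write_outputs <- function(result, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character()
  put <- function(df, name) {
    p <- file.path(outdir, name)
    write_tsv_table(df, p)
    paths <<- c(paths, p)
  }

  summ <- result$summary %||% data.frame(category = character(), reads = numeric())
  summ <- summ[order(summ$category), , drop = FALSE]
  put(summ, "summary.tsv")

  mir <- result$mirna$hits %||%
    data.frame(seq = character(), gene = character(), species = character(),
               tier = character(), tail = character(), count = numeric(),
               count_apportioned = numeric())
  mir <- mir[, setdiff(names(mir), "modifications"), drop = FALSE]
  mir <- mir[order(mir$gene, mir$seq), , drop = FALSE]
  put(mir, "mirna.tsv")

  trf <- result$trf %||%
    data.frame(seq = character(), trna = character(), class = character(),
               count = numeric())
  trf <- trf[do.call(order, trf[intersect(c("trna", "class", "seq"), names(trf))]), ,
             drop = FALSE]
  put(trf, "trf.tsv")

  ph <- result$phasing$windows %||%
    data.frame(target = character(), start = integer(), end = integer(),
               j = numeric(), n = numeric(), p = numeric(), called = logical())
  ph <- ph[order(ph$target, ph$start), , drop = FALSE]
  put(ph, "phasing.tsv")

  ld <- result$length_distribution %||%
    data.frame(length = integer(), reads = numeric())
  ld <- ld[order(ld$length), , drop = FALSE]
  put(ld, "length_distribution.tsv")

  pc <- result$positional_composition %||%
    data.frame(position = integer(), A = numeric(), C = numeric(),
               G = numeric(), T = numeric())
  pc <- pc[order(pc$position), , drop = FALSE]
  put(pc, "positional_composition.tsv")

  invisible(paths)
}
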