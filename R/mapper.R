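#' Mapping parameters
#'
#' @param max_mismatch maximum number of substitutions in the aligned core.
#' @param max_tail maximum length of a non-template 3' tail split off the
#'   read (default 2).
#' @param strand_mode `"both"` or `"plus-only"`.
#' @return A `map_params` list.
#' @export
map_params <- function(max_mismatch = 0L, max_tail = 2L,
                       strand_mode = c("both", "plus-only")) {
  strand_mode <- match.arg(strand_mode)
  stopifnot(max_mismatch >= 0, max_tail >= 0)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 max_tail = as.integer(max_tail),
                 strand_mode = strand_mode),
            class = "map_params")
}

# Index a reference collection for repeated position scans. References are
# concatenated into one subject with N-runs as separators; a candidate hit is
# kept only if it falls entirely inside one reference segment. N never
# matches an A/C/G/T pattern base, so separator overlap always costs
# mismatches and is additionally excluded by the containment check.
ref_index <- function(references) {
  if (inherits(references, "DNAStringSet") || inherits(references, "BStringSet")) {
    references <- setNames(as.character(references), names(references))
  }
  stopifnot(is.character(references), length(references) > 0,
            !is.null(names(references)))
  references <- toupper(references)
  sep <- strrep("N", 40L)
  lens <- nchar(references)
  starts <- cumsum(c(1L, head(lens + nchar(sep), -1L)))
  subject <- paste(references, collapse = sep)
  structure(list(refs = references, lens = lens, seg_start = starts,
                 seg_end = starts + lens - 1L,
                 subject = Biostrings::DNAString(subject)),
            class = "ref_index")
}

# All ungapped placements of `pattern` on the index with <= max_mm
# substitutions. Returns data.frame(ref (integer), start (in-reference), mm).
scan_core <- function(pattern, index, max_mm) {
  P <- nchar(pattern)
  S <- length(index$subject)
  if (P < 1L || P > S) return(NULL)
  if (grepl("N", pattern, fixed = TRUE)) return(NULL)  # N reads never align
  pat <- Biostrings::DNAString(pattern)
  at <- seq_len(S - P + 1L)
  ok <- Biostrings::isMatchingStartingAt(pat, index$subject, starting.at = at,
                                         max.mismatch = max_mm, fixed = TRUE)
  hits <- at[ok]
  if (length(hits) == 0) return(NULL)
  seg <- findInterval(hits, index$seg_start)
  inside <- hits >= index$seg_start[seg] &
    (hits + P - 1L) <= index$seg_end[seg]
  hits <- hits[inside]
  seg <- seg[inside]
  if (length(hits) == 0) return(NULL)
  start <- hits - index$seg_start[seg] + 1L
  mm <- vapply(seq_along(hits), function(i) {
    length(str_mismatches(pattern,
                          substr(index$refs[[seg[i]]], start[i], start[i] + P - 1L)))
  }, integer(1))
  data.frame(ref = seg, start = start, mm = mm)
}

# mismatch detail of a plus-strand core placement, positions on the read
core_mismatch_detail <- function(core, refseq, start) {
  tpl <- substr(refseq, start, start + nchar(core) - 1L)
  pos <- str_mismatches(core, tpl)
  if (length(pos) == 0) {
    return(data.frame(pos = integer(), read_base = character(),
                      ref_base = character()))
  }
  data.frame(pos = pos,
             read_base = substring(core, pos, pos),
             ref_base = substring(tpl, pos, pos))
}

#' Map reads to a reference collection
#'
#' Exhaustive ungapped alignment: every placement of each read on each
#' reference with at most `max_mismatch` substitutions is reported, on both
#' strands unless `strand_mode = "plus-only"`. Reads containing `N` never
#' align. Mismatch positions are reported 1-based on the read, with the
#' reference base given in read orientation.
#'
#' @param reads a [read_set()] or character vector of sequences.
#' @param references named character vector (or `DNAStringSet`) of reference
#'   sequences.
#' @param params a [map_params()].
#' @return An [alignment_frame()] with additional list-column `mismatches`
#'   (one data.frame of `pos`/`read_base`/`ref_base` per hit) and column
#'   `end` (rightmost target coordinate).
#' @export
map_reads <- function(reads, references, params = map_params()) {
  if (inherits(reads, "read_set")) {
    seqs <- reads$seq
    counts <- reads$count
  } else {
    seqs <- normalize_seq(as.character(reads))
    counts <- rep(1, length(seqs))
  }
  index <- if (inherits(references, "ref_index")) references else ref_index(references)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- map_one_read(seqs[i], counts[i], index, params)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    af <- alignment_frame()
    af$end <- integer()
    af$mismatches <- list()
    return(af)
  }
  as_alignment_frame(do.call(rbind, out))
}

map_one_read <- function(seq, count, index, params) {
  res <- list()
  P <- nchar(seq)
  plus <- scan_core(seq, index, params$max_mismatch)
  if (!is.null(plus)) {
    mml <- lapply(seq_len(nrow(plus)), function(k) {
      core_mismatch_detail(seq, index$refs[[plus$ref[k]]], plus$start[k])
    })
    res[[length(res) + 1L]] <- data.frame(
      read_seq = seq, target_id = names(index$refs)[plus$ref],
      start = plus$start, strand = "+", count = count, n_mismatch = plus$mm,
      tail = "", end = plus$start + P - 1L,
      mismatches = I(mml), stringsAsFactors = FALSE)
  }
  if (params$strand_mode == "both") {
    rc <- revcomp(seq)
    minus <- scan_core(rc, index, params$max_mismatch)
    if (!is.null(minus)) {
      mml <- lapply(seq_len(nrow(minus)), function(k) {
        d <- core_mismatch_detail(rc, index$refs[[minus$ref[k]]], minus$start[k])
        if (nrow(d) > 0) {
          d <- data.frame(pos = P - d$pos + 1L,
                          read_base = chartr("ACGT", "TGCA", d$read_base),
                          ref_base = chartr("ACGT", "TGCA", d$ref_base))
          d <- d[order(d$pos), , drop = FALSE]
          rownames(d) <- NULL
        }
        d
      })
      res[[length(res) + 1L]] <- data.frame(
        read_seq = seq, target_id = names(index$refs)[minus$ref],
        start = minus$start, strand = "-", count = count, n_mismatch = minus$mm,
        tail = "", end = minus$start + P - 1L,
        mismatches = I(mml), stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0) return(NULL)
  do.call(rbind, res)
}

#' Split a non-template 3' tail off a read alignment
#'
#' Given that a prefix of `read` aligns at `start` on `reference`, the tail
#' is the maximal trailing run of read bases that disagree with the
#' templated continuation of the reference at this locus (a position beyond
#' the reference end always disagrees); a templated base always belongs to
#' the core, never to the tail. The split is valid if the run is at most
#' `max_tail` nt and the remaining core aligns with at most `max_mismatch`
#' substitutions; a longer run means no annotation at this locus.
#'
#' @param read read sequence.
#' @param reference reference sequence (single string).
#' @param start 1-based alignment start of the read prefix on the reference.
#' @param params a [map_params()].
#' @return List with `core`, `tail`, `n_mismatch`, `mismatches`, or `NULL`
#'   if the non-template run exceeds `max_tail` or the core exceeds
#'   `max_mismatch`.
#' @export
split_nontemplate_tail <- function(read, reference, start, params = map_params()) {
  read <- normalize_seq(read)
  reference <- toupper(reference)
  P <- nchar(read)
  # maximal trailing non-template run
  run <- 0L
  for (p in P:1) {
    tp <- start + p - 1L
    tpl_base <- if (tp >= 1L && tp <= nchar(reference)) {
      substr(reference, tp, tp)
    } else ""
    if (!nzchar(tpl_base) || substr(read, p, p) != tpl_base) {
      run <- run + 1L
    } else {
      break
    }
  }
  if (run > params$max_tail || run >= P) return(NULL)
  nc <- P - run
  if (start + nc - 1L > nchar(reference)) return(NULL)
  core <- substr(read, 1L, nc)
  mmd <- core_mismatch_detail(core, reference, start)
  if (nrow(mmd) > params$max_mismatch) return(NULL)
  list(core = core, tail = substr(read, nc + 1L, P),
       n_mismatch = nrow(mmd), mismatches = mmd)
}

# All tail-split hits of one read on an index: for each tail length t the
# core is scanned and a hit is kept only when t equals the maximal trailing
# non-template run of the read at that locus - every tail base disagrees
# with the template and the core's terminal base is templated (or the whole
# read is the tail-free core when max_tail is 0, plain-alignment mode).
tailed_hits <- function(read, index, max_mm, max_tail,
                        strand_mode = "plus-only", tail_check = NULL) {
  P <- nchar(read)
  found <- character()
  res <- list()
  for (t in 0:max_tail) {
    nc <- P - t
    if (nc < 1L) break
    core <- substr(read, 1L, nc)
    tl <- substr(read, nc + 1L, P)
    for (strand in if (strand_mode == "both") c("+", "-") else "+") {
      pat <- if (strand == "+") core else revcomp(core)
      hits <- scan_core(pat, index, max_mm)
      if (is.null(hits)) next
      for (k in seq_len(nrow(hits))) {
        refseq <- index$refs[[hits$ref[k]]]
        s <- hits$start[k]
        key <- paste(hits$ref[k], strand,
                     if (strand == "+") s else s + nc - 1L)
        if (key %in% found) next
        tpl_at <- function(pos_on_read) {
          tp <- if (strand == "+") s + pos_on_read - 1L else s + nc - pos_on_read
          if (tp >= 1L && tp <= nchar(refseq)) {
            b <- substr(refseq, tp, tp)
            if (strand == "-") chartr("ACGT", "TGCA", b) else b
          } else ""
        }
        if (max_tail > 0L) {
          # the tail must be exactly the maximal non-template run
          b <- tpl_at(nc)
          if (!nzchar(b) || substr(read, nc, nc) != b) next
        }
        if (t > 0L) {
          ok <- TRUE
          for (i in seq_len(t)) {
            tpl_base <- tpl_at(nc + i)
            if (nzchar(tpl_base) && substr(read, nc + i, nc + i) == tpl_base) {
              ok <- FALSE
              break
            }
          }
          if (!ok) next
        }
        if (!is.null(tail_check) && !tail_check(tl)) next
        found <- c(found, key)
        mmd <- if (strand == "+") {
          core_mismatch_detail(core, refseq, s)
        } else {
          d <- core_mismatch_detail(revcomp(core), refseq, s)
          if (nrow(d) > 0) {
            d <- data.frame(pos = nc - d$pos + 1L,
                            read_base = chartr("ACGT", "TGCA", d$read_base),
                            ref_base = chartr("ACGT", "TGCA", d$ref_base))
            d <- d[order(d$pos), , drop = FALSE]
          }
          d
        }
        res[[length(res) + 1L]] <- data.frame(
          ref = hits$ref[k], target_id = names(index$refs)[hits$ref[k]],
          start = s, end = s + nc - 1L, strand = strand,
          core_len = nc, tail = tl, n_mismatch = hits$mm[k],
          mismatches = I(list(mmd)), stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) return(NULL)
  do.call(rbind, res)
}
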