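#' ncRNA annotation parameters
#'
#' @param max_mismatch substitutions tolerated when mapping reads to the
#'   ncRNA/cDNA collection (default 1).
#' @param tolerance boundary tolerance in nt for tRF classification
#'   (default 2).
#' @param strand_mode mapping strand mode (default both strands).
#' @return An `ncrna_params` list.
#' @export
ncrna_params <- function(max_mismatch = 1L, tolerance = 2L,
                         strand_mode = c("both", "plus-only")) {
  strand_mode <- match.arg(strand_mode)
  structure(list(max_mismatch = as.integer(max_mismatch),
                 tolerance = as.integer(tolerance),
                 strand_mode = strand_mode),
            class = "ncrna_params")
}

#' Structural model of a tRNA reference
#'
#' Projects the canonical 76-nt tRNA cloverleaf onto a mature tRNA of length
#' `L`: D-loop end `round(L*25/76)`, anticodon loop `round(L*31/76)` to
#' `round(L*39/76)`, T-psi-C loop start `round(L*52/76)`. Genomic 5'/3'
#' flanks (leader/trailer) are described by the `pad5`/`pad3` lengths of the
#' record, and the position of the first oligo-T (>= 4 T) terminator signal
#' in the trailer is located for tRF-1 classification.
#'
#' @param trna_record a one-row data.frame or list with `id`, `seq`
#'   (flanked genomic sequence), `pad5`, `pad3`.
#' @return A `trna_model` list with boundary coordinates relative to the
#'   mature tRNA (position 1 = mature 5' end).
#' @export
build_trna_model <- function(trna_record) {
  id <- trna_record$id
  seq <- normalize_seq(trna_record$seq)
  pad5 <- as.integer(trna_record$pad5 %||% 0L)
  pad3 <- as.integer(trna_record$pad3 %||% 0L)
  L <- nchar(seq) - pad5 - pad3
  if (L < 40) stop("mature tRNA shorter than 40 nt in record ", id)
  b <- round(L * c(25, 31, 39, 52) / 76)
  trailer <- if (pad3 > 0) substr(seq, pad5 + L + 1L, nchar(seq)) else ""
  m <- regexpr("TTTT+", trailer)
  oligo_t_end <- if (m[1] > 0) L + m[1] + attr(m, "match.length") - 1L else NA_integer_
  structure(list(id = id, seq = seq, pad5 = pad5, pad3 = pad3, L = L,
                 body = substr(seq, pad5 + 1L, pad5 + L),
                 d_loop_end = b[1], ac_start = b[2], ac_end = b[3],
                 tpsi_start = b[4], oligo_t_end = oligo_t_end),
            class = "trna_model")
}

trf_classes <- c("5' tRF", "5' tR-half", "3' tRF", "3' CCA-tRF",
                 "3' tR-half", "tRF-1", "tRNA-leader", "misc-tRF")

#' Classify a tRNA alignment into a tRF class
#'
#' Classes follow the cloverleaf anatomy: 5' tRFs run from the 5' end to the
#' D-loop, 5' tR-halves to the anticodon loop, 3' tRFs from the T-psi-C loop
#' to the 3' end (3' CCA-tRFs when the read carries the CCA end), 3'
#' tR-halves from the anticodon loop to the 3' end, tRF-1 from just after
#' the mature 3' end to the oligo-T signal in the trailer, tRNA-leader ends
#' just upstream of the mature 5' end; everything else on the tRNA is a
#' miscellaneous (internal) tRF. Boundary comparisons use `tolerance` nt of
#' slack. Antisense alignments are miscellaneous.
#'
#' @param alignment list or one-row data.frame with `start`, `end` (1-based
#'   on the flanked tRNA reference, aligned core only), `strand`, `tail`
#'   (non-template 3' tail, possibly `""`), `read_seq`.
#' @param model a [build_trna_model()] result.
#' @param tolerance boundary slack in nt (default 2).
#' @return One of the eight tRF class labels.
#' @export
classify_trf <- function(alignment, model, tolerance = 2L) {
  if (alignment$start < 1 || alignment$end > nchar(model$seq)) {
    stop("alignment outside the flanked tRNA region")
  }
  if (alignment$strand == "-") return("misc-tRF")
  tol <- tolerance
  L <- model$L
  ms <- alignment$start - model$pad5
  me <- alignment$end - model$pad5
  tail_len <- nchar(alignment$tail %||% "")
  me_total <- me + tail_len

  if (me <= 0) {
    return(if (me >= -tol) "tRNA-leader" else "misc-tRF")
  }
  if (ms >= L + 1L && ms <= L + 1L + tol) {
    if (!is.na(model$oligo_t_end) && me <= model$oligo_t_end) return("tRF-1")
    return("misc-tRF")
  }
  if (abs(ms - 1L) <= tol) {
    if (me <= model$d_loop_end + tol) return("5' tRF")
    if (me >= model$ac_start - tol && me <= model$ac_end + tol) {
      return("5' tR-half")
    }
  }
  if (me >= L - tol || me_total >= L - tol) {
    is_cca <- grepl("CCA$", alignment$read_seq) && me_total >= L
    if (ms >= model$tpsi_start - tol) {
      return(if (is_cca) "3' CCA-tRF" else "3' tRF")
    }
    if (ms >= model$ac_start - tol && ms <= model$ac_end + tol) {
      return("3' tR-half")
    }
  }
  "misc-tRF"
}

# tail accepted on tRNA references: empty or a 3'-suffix of the
# post-transcriptional CCA end
cca_tail_ok <- function(tl) {
  !nzchar(tl) || tl == substr("CCA", 4L - nchar(tl), 3L)
}

#' Map reads to the class-tagged ncRNA/cDNA collection
#'
#' For each read, all hits within `max_mismatch` are collected across the
#' ncRNA/cDNA references and the flanked tRNA references (where a
#' non-template 3' CCA of up to 3 nt may be split off at the mature 3' end).
#' The best hits of a read are those with the minimal mismatch count; the
#' distinct reference classes among them define `h`, the divisor used by
#' [apportion_counts()]. Reads hitting tRNAs are further classified into
#' tRF classes via [classify_trf()].
#'
#' @param reads a [read_set()] (normally the miRNA-unassigned remainder).
#' @param refs reference list with components `ncrna` (data.frame
#'   `class`/`id`/`seq`) and/or `trna` (data.frame `id`/`pad5`/`pad3`/`seq`),
#'   as from [read_reference_fasta()].
#' @param params an [ncrna_params()].
#' @return List with `table` (long data.frame seq/count/h/class, one row per
#'   read-class best hit, input to [apportion_counts()]), `trf` (data.frame
#'   seq/trna/class/count of fractional tRF counts), `assigned` and
#'   `unassigned` [read_set()]s.
#' @export
annotate_ncrna <- function(reads, refs, params = ncrna_params()) {
  stopifnot(inherits(reads, "read_set"))
  nc <- refs$ncrna
  tr <- refs$trna
  seqs <- character()
  cls_map <- character()
  if (!is.null(nc) && nrow(nc) > 0) {
    nm <- paste0("ncrna|", nc$class, "|", nc$id)
    seqs <- c(seqs, setNames(nc$seq, nm))
    cls_map <- c(cls_map, setNames(nc$class, nm))
  }
  models <- list()
  if (!is.null(tr) && nrow(tr) > 0) {
    for (i in seq_len(nrow(tr))) {
      mod <- build_trna_model(tr[i, ])
      nm <- paste0("trna|", mod$id)
      models[[nm]] <- mod
      seqs <- c(seqs, setNames(mod$seq, nm))
      cls_map <- c(cls_map, setNames("tRNA", nm))
    }
  }
  empty <- list(
    table = data.frame(seq = character(), count = numeric(), h = integer(),
                       class = character()),
    trf = data.frame(seq = character(), trna = character(),
                     class = character(), count = numeric()),
    assigned = read_set(), unassigned = reads)
  if (length(seqs) == 0 || nrow(reads) == 0) return(empty)

  index_all <- ref_index(seqs)
  trna_names <- names(models)
  index_trna <- if (length(trna_names)) ref_index(seqs[trna_names]) else NULL

  tab_rows <- list()
  trf_rows <- list()
  hit_any <- logical(nrow(reads))
  for (r in seq_len(nrow(reads))) {
    seq <- reads$seq[r]
    cnt <- reads$count[r]
    plain <- tailed_hits(seq, index_all, params$max_mismatch, 0L,
                         strand_mode = params$strand_mode)
    cca <- if (!is.null(index_trna)) {
      tailed_hits(seq, index_trna, params$max_mismatch, 3L,
                  strand_mode = params$strand_mode, tail_check = cca_tail_ok)
    } else NULL
    hits <- rbind(plain, cca)
    if (is.null(hits) || nrow(hits) == 0) next
    # dedupe the same locus found with and without a CCA split: keep the
    # better (fewer mismatches, then shorter tail) explanation
    anchor <- ifelse(hits$strand == "+", hits$start, hits$end)
    key <- paste(hits$target_id, hits$strand, anchor)
    ord <- order(key, hits$n_mismatch, nchar(hits$tail))
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$target_id, hits$strand,
                                   ifelse(hits$strand == "+", hits$start,
                                          hits$end))), , drop = FALSE]
    best_mm <- min(hits$n_mismatch)
    best <- hits[hits$n_mismatch == best_mm, , drop = FALSE]
    classes <- sort(unique(unname(cls_map[best$target_id])))
    h <- length(classes)
    hit_any[r] <- TRUE
    tab_rows[[length(tab_rows) + 1L]] <- data.frame(
      seq = seq, count = cnt, h = h, class = classes,
      stringsAsFactors = FALSE)
    if ("tRNA" %in% classes) {
      tb <- best[cls_map[best$target_id] == "tRNA", , drop = FALSE]
      tb <- tb[!duplicated(tb$target_id), , drop = FALSE]
      share <- cnt / h / nrow(tb)
      for (k in seq_len(nrow(tb))) {
        mod <- models[[tb$target_id[k]]]
        lab <- classify_trf(list(start = tb$start[k], end = tb$end[k],
                                 strand = tb$strand[k], tail = tb$tail[k],
                                 read_seq = seq),
                            mod, params$tolerance)
        trf_rows[[length(trf_rows) + 1L]] <- data.frame(
          seq = seq, trna = mod$id, class = lab, count = share,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- empty
  if (length(tab_rows)) out$table <- do.call(rbind, tab_rows)
  if (length(trf_rows)) out$trf <- do.call(rbind, trf_rows)
  out$assigned <- as_read_set(reads[hit_any, , drop = FALSE])
  out$unassigned <- as_read_set(reads[!hit_any, , drop = FALSE])
  out
}

#' Apportion multi-class read counts
#'
#' Implements the fractional assignment `c_class = sum_i r_i / h_i`: the
#' read count `r_i` of each sequence that maps to `h_i` different reference
#' classes equally well contributes `r_i / h_i` to each of those classes, so
#' no read is ever counted twice.
#'
#' @param hit_table data.frame with one row per (sequence, class) best hit
#'   and columns `seq`, `count`, `h`, `class` (as returned in the `table`
#'   component of [annotate_ncrna()]).
#' @return Named numeric vector of fractional per-class read counts, sorted
#'   by class name. The sum equals the total read count of all annotated
#'   sequences.
#' @examples
#' tab <- data.frame(seq = c("A", "A", "B"), count = c(10, 10, 4),
#'                   h = c(2, 2, 1), class = c("rRNA", "snRNA", "rRNA"))
#' apportion_counts(tab)  # rRNA 9, snRNA 5
#' @export
apportion_counts <- function(hit_table) {
  stopifnot(all(c("seq", "count", "h", "class") %in% names(hit_table)))
  if (nrow(hit_table) == 0) return(setNames(numeric(), character()))
  stopifnot(all(hit_table$h >= 1))
  contrib <- hit_table$count / hit_table$h
  out <- tapply(contrib, hit_table$class, sum)
  setNames(as.numeric(out), names(out))[order(names(out))]
}
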