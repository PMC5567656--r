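#' miRNA annotation parameters
#'
#' @param max_tail maximum non-template 3' tail length (default 2).
#' @param max_internal maximum number of internal modifications, i.e.
#'   substitutions within the aligned read (default 1).
#' @param offset_window offset miRNA (moR) window: a read whose 5' end lies
#'   within this many nt of a mature 5' end (but not at it) is an offset
#'   miRNA; reads elsewhere on the hairpin are not miRNAs (default 5).
#' @param species species tag of the library; matching reference records are
#'   annotated first, all other species in a second cross-species pass.
#'   `NULL` treats every record as self-species.
#' @return A `mirna_params` list.
#' @export
mirna_params <- function(max_tail = 2L, max_internal = 1L,
                         offset_window = 5L, species = NULL) {
  structure(list(max_tail = as.integer(max_tail),
                 max_internal = as.integer(max_internal),
                 offset_window = as.integer(offset_window),
                 species = species),
            class = "mirna_params")
}

#' Is a hairpin hit an offset miRNA?
#'
#' @param hit_start 5' end (1-based hairpin coordinate) of the read.
#' @param mature_starts 5' starts of the mature miRNAs on the hairpin.
#' @param offset_window window half-width (default 5).
#' @return `TRUE` iff the 5' end lies within the window around a mature 5'
#'   end but is not the canonical start itself.
#' @export
classify_offset <- function(hit_start, mature_starts, offset_window = 5L) {
  d <- abs(hit_start - mature_starts)
  any(d <= offset_window & d > 0) && !any(d == 0)
}

mirna_tiers <- c("canonical", "tailed", "offset", "tailed-offset")

#' Tiered miRNA annotation
#'
#' Annotates reads against hairpin references in four tiers per species
#' scope: (i) canonical miRNAs, (ii) 3'-tailed canonical miRNAs,
#' (iii) offset miRNAs, (iv) 3'-tailed offset miRNAs - first for the
#' library's own species, then, for still unassigned reads, against all
#' other species. Each read is assigned to the first tier in which it has at
#' least one hit; equal hits to multiple genes within the winning tier are
#' all recorded with counts apportioned uniformly per gene.
#'
#' Mapping is sense-strand only, tolerating `max_internal` substitutions in
#' the aligned core and a non-template 3' tail of up to `max_tail` nt (tails
#' are split minimally, so templated bases always remain part of the core).
#'
#' @param reads a [read_set()].
#' @param refs a [mirna_ref()].
#' @param params a [mirna_params()].
#' @return List with `hits` (data.frame, one row per read x gene with tier,
#'   tail, modifications list-column, apportioned count) and `unassigned`
#'   (a [read_set()]).
#' @export
annotate_mirnas <- function(reads, refs, params = mirna_params()) {
  stopifnot(inherits(reads, "read_set"), inherits(refs, "mirna_ref"))
  hp <- refs$hairpins
  mt <- refs$matures
  if (is.null(params$species)) {
    scopes <- list(self = rep(TRUE, nrow(hp)))
  } else {
    is_self <- hp$species == params$species
    scopes <- list(self = is_self, cross = !is_self)
    scopes <- scopes[vapply(scopes, any, logical(1))]
  }
  indices <- lapply(scopes, function(sel) {
    ref_index(setNames(hp$seq[sel], hp$key[sel]))
  })
  mat_by_key <- split(mt, mt$key)

  hit_rows <- list()
  assigned <- logical(nrow(reads))
  for (r in seq_len(nrow(reads))) {
    seq <- reads$seq[r]
    cnt <- reads$count[r]
    for (scope in names(indices)) {
      th <- tailed_hits(seq, indices[[scope]], params$max_internal,
                        params$max_tail, strand_mode = "plus-only")
      if (is.null(th)) next
      cls <- classify_mirna_hits(th, mat_by_key, params$offset_window)
      if (is.null(cls)) next
      win <- mirna_tiers[min(match(cls$tier, mirna_tiers))]
      cls <- cls[cls$tier == win, , drop = FALSE]
      genes <- unique(cls$gene)
      cls <- cls[!duplicated(cls$gene), , drop = FALSE]
      cls$seq <- seq
      cls$count <- cnt
      cls$scope <- scope
      cls$n_genes <- length(genes)
      cls$count_apportioned <- cnt / length(genes)
      hit_rows[[length(hit_rows) + 1L]] <- cls
      assigned[r] <- TRUE
      break
    }
  }
  hits <- if (length(hit_rows)) {
    out <- do.call(rbind, hit_rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(tier = character(), gene = character(), species = character(),
               hairpin = character(), offset = integer(), tail = character(),
               n_mismatch = integer(), mismatches = I(list()),
               seq = character(), count = numeric(), scope = character(),
               n_genes = integer(), count_apportioned = numeric())
  }
  list(hits = hits,
       unassigned = as_read_set(reads[!assigned, , drop = FALSE]))
}

# classify raw hairpin hits of one read into miRNA tiers; NULL if no hit is
# anchored near a mature 5' end
classify_mirna_hits <- function(th, mat_by_key, offset_window) {
  rows <- list()
  for (k in seq_len(nrow(th))) {
    mats <- mat_by_key[[th$target_id[k]]]
    if (is.null(mats)) next
    d <- th$start[k] - mats$start
    ok <- abs(d) <= offset_window
    if (!any(ok)) next
    j <- which(ok)[which.min(abs(d[ok]))]
    o <- d[j]
    tier <- if (o == 0L) {
      if (nzchar(th$tail[k])) "tailed" else "canonical"
    } else {
      if (nzchar(th$tail[k])) "tailed-offset" else "offset"
    }
    mmd <- th$mismatches[[k]]
    if (nrow(mmd) > 0) {
      # read position i sits at mature position i + offset
      mmd <- data.frame(position = mmd$pos + o,
                        from_base = mmd$ref_base, to_base = mmd$read_base)
    } else {
      mmd <- data.frame(position = integer(), from_base = character(),
                        to_base = character())
    }
    rows[[length(rows) + 1L]] <- data.frame(
      tier = tier, gene = mats$gene[j], species = mats$species[j],
      hairpin = mats$hairpin_id[j], offset = o, tail = th$tail[k],
      n_mismatch = th$n_mismatch[k], mismatches = I(list(mmd)),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-position miRNA modification and tail composition matrices
#'
#' Aggregates miRNA hits into (1) a count-weighted matrix of internal
#' modifications, rows = mature positions, columns = the 12 possible
#' `from>to` substitutions, and (2) a tail composition table with rows
#' `mono`/`di` (tail length) and columns `A`/`C`/`G`/`T`/`mixed`
#' (di-nucleotide tails of two different bases count as `mixed`).
#'
#' @param hits the `hits` data.frame from [annotate_mirnas()].
#' @return List with matrices `modifications` and `tails`.
#' @export
modification_matrix <- function(hits) {
  bases <- c("A", "C", "G", "T")
  combos <- as.vector(outer(bases, bases, function(a, b) paste0(a, ">", b)))
  combos <- combos[substr(combos, 1, 1) != substr(combos, 3, 3)]
  combos <- sort(combos)

  maxpos <- 1L
  if (nrow(hits) > 0) {
    pl <- unlist(lapply(hits$mismatches, function(d) d$position))
    if (length(pl)) maxpos <- max(maxpos, max(pl))
  }
  mod <- matrix(0, nrow = maxpos, ncol = length(combos),
                dimnames = list(seq_len(maxpos), combos))
  tails <- matrix(0, nrow = 2, ncol = 5,
                  dimnames = list(c("mono", "di"),
                                  c("A", "C", "G", "T", "mixed")))
  for (k in seq_len(nrow(hits))) {
    w <- hits$count_apportioned[k] %||% hits$count[k]
    d <- hits$mismatches[[k]]
    if (!is.null(d) && nrow(d) > 0) {
      for (i in seq_len(nrow(d))) {
        if (d$position[i] >= 1 && d$position[i] <= maxpos) {
          key <- paste0(d$from_base[i], ">", d$to_base[i])
          if (key %in% combos) mod[d$position[i], key] <- mod[d$position[i], key] + w
        }
      }
    }
    tl <- hits$tail[k]
    if (nzchar(tl)) {
      if (nchar(tl) == 1) {
        tails["mono", tl] <- tails["mono", tl] + w
      } else {
        ch <- unique(strsplit(tl, "", fixed = TRUE)[[1]])
        col <- if (length(ch) == 1) ch else "mixed"
        tails["di", col] <- tails["di", col] + w
      }
    }
  }
  list(modifications = mod, tails = tails)
}
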