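#' miRNA reference (hairpins plus mature coordinates)
#'
#' @param hairpins data.frame with columns `id`, `species`, `seq`.
#' @param matures data.frame with columns `gene`, `species`, `hairpin_id`,
#'   `start`, `end` (1-based coordinates of the mature miRNA on its hairpin).
#' @return A `mirna_ref` list. Every mature must lie within its hairpin.
#' @export
mirna_ref <- function(hairpins, matures) {
  stopifnot(all(c("id", "species", "seq") %in% names(hairpins)),
            all(c("gene", "species", "hairpin_id", "start", "end") %in%
                  names(matures)))
  hairpins$seq <- normalize_seq(hairpins$seq)
  hairpins$key <- paste(hairpins$species, hairpins$id, sep = "|")
  matures$key <- paste(matures$species, matures$hairpin_id, sep = "|")
  idx <- match(matures$key, hairpins$key)
  if (anyNA(idx)) stop("mature miRNA references a missing hairpin")
  hl <- nchar(hairpins$seq)[idx]
  if (any(matures$start < 1 | matures$end > hl | matures$start > matures$end)) {
    stop("mature miRNA coordinates outside the hairpin")
  }
  matures$seq <- substr(hairpins$seq[idx], matures$start, matures$end)
  structure(list(hairpins = hairpins, matures = matures), class = "mirna_ref")
}

#' Read a reference FASTA collection
#'
#' Parses a FASTA file whose headers follow the class-tagged dialects used
#' throughout the package:
#' \itemize{
#'   \item `>hairpin|<species>|<id>` - miRNA hairpin
#'   \item `>mirna|<species>|<gene>|hairpin=<id>|start=<s>|end=<e>` - mature
#'     miRNA located on a hairpin
#'   \item `>ncrna|<class>|<id>` - class-tagged ncRNA/cDNA sequence
#'   \item `>trna|<id>|pad5=<n>|pad3=<n>` - tRNA with genomic flanks
#'   \item `>picluster|<id>` - piRNA cluster sequence
#' }
#'
#' @param path FASTA file path.
#' @return A list with components `mirna` (a [mirna_ref()] or `NULL`),
#'   `ncrna`, `trna`, `clusters` (data.frames or `NULL`).
#' @export
read_reference_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  headers <- names(recs)
  seqs <- normalize_seq(as.character(recs))
  tag <- sub("\\|.*$", "", headers)
  fields <- strsplit(headers, "|", fixed = TRUE)

  get_kv <- function(f, key) {
    hit <- grep(paste0("^", key, "="), f, value = TRUE)
    if (length(hit) == 0) NA else sub(paste0("^", key, "="), "", hit[1])
  }

  out <- list(mirna = NULL, ncrna = NULL, trna = NULL, clusters = NULL)

  hp <- tag == "hairpin"
  mt <- tag == "mirna"
  if (any(hp) || any(mt)) {
    hairpins <- data.frame(
      id = vapply(fields[hp], `[[`, character(1), 3),
      species = vapply(fields[hp], `[[`, character(1), 2),
      seq = seqs[hp], stringsAsFactors = FALSE)
    matures <- data.frame(
      gene = vapply(fields[mt], `[[`, character(1), 3),
      species = vapply(fields[mt], `[[`, character(1), 2),
      hairpin_id = vapply(fields[mt], get_kv, character(1), "hairpin"),
      start = as.integer(vapply(fields[mt], get_kv, character(1), "start")),
      end = as.integer(vapply(fields[mt], get_kv, character(1), "end")),
      stringsAsFactors = FALSE)
    out$mirna <- mirna_ref(hairpins, matures)
  }

  nc <- tag == "ncrna"
  if (any(nc)) {
    out$ncrna <- data.frame(
      class = vapply(fields[nc], `[[`, character(1), 2),
      id = vapply(fields[nc], `[[`, character(1), 3),
      seq = seqs[nc], stringsAsFactors = FALSE)
  }

  tr <- tag == "trna"
  if (any(tr)) {
    out$trna <- data.frame(
      id = vapply(fields[tr], `[[`, character(1), 2),
      pad5 = as.integer(vapply(fields[tr], get_kv, character(1), "pad5")),
      pad3 = as.integer(vapply(fields[tr], get_kv, character(1), "pad3")),
      seq = seqs[tr], stringsAsFactors = FALSE)
    out$trna$pad5[is.na(out$trna$pad5)] <- 0L
    out$trna$pad3[is.na(out$trna$pad3)] <- 0L
  }

  pc <- tag == "picluster"
  if (any(pc)) {
    out$clusters <- data.frame(
      id = vapply(fields[pc], `[[`, character(1), 2),
      seq = seqs[pc], stringsAsFactors = FALSE)
  }
  out
}

#' Write a reference collection to FASTA
#'
#' Inverse of [read_reference_fasta()]; used mainly to materialize synthetic
#' references for command-line runs.
#'
#' @param refs list as returned by [read_reference_fasta()] (any subset of
#'   components may be present).
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  lines <- character()
  add <- function(h, s) lines <<- c(lines, paste0(">", h), s)
  if (!is.null(refs$mirna)) {
    hp <- refs$mirna$hairpins
    for (i in seq_len(nrow(hp))) {
      add(sprintf("hairpin|%s|%s", hp$species[i], hp$id[i]), hp$seq[i])
    }
    mt <- refs$mirna$matures
    for (i in seq_len(nrow(mt))) {
      add(sprintf("mirna|%s|%s|hairpin=%s|start=%d|end=%d",
                  mt$species[i], mt$gene[i], mt$hairpin_id[i],
                  mt$start[i], mt$end[i]), mt$seq[i])
    }
  }
  if (!is.null(refs$ncrna)) {
    for (i in seq_len(nrow(refs$ncrna))) {
      add(sprintf("ncrna|%s|%s", refs$ncrna$class[i], refs$ncrna$id[i]),
          refs$ncrna$seq[i])
    }
  }
  if (!is.null(refs$trna)) {
    for (i in seq_len(nrow(refs$trna))) {
      add(sprintf("trna|%s|pad5=%d|pad3=%d", refs$trna$id[i],
                  refs$trna$pad5[i], refs$trna$pad3[i]), refs$trna$seq[i])
    }
  }
  if (!is.null(refs$clusters)) {
    for (i in seq_len(nrow(refs$clusters))) {
      add(sprintf("picluster|%s", refs$clusters$id[i]), refs$clusters$seq[i])
    }
  }
  writeLines(lines, path)
  invisible(path)
}
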