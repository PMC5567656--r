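#' Pipeline run configuration
#'
#' Bundles input, reference collection and all stage parameters for
#' [run_pipeline()]. References are supplied as local files or in-memory
#' objects; no network access is ever required.
#'
#' @param input a [read_set()], or a path to a FASTA/FASTQ/collapsed-FASTA
#'   file.
#' @param format input sequence format (see [read_sequences()]); ignored
#'   when `input` is already a [read_set()].
#' @param refs either a reference list (components `mirna`, `ncrna`, `trna`,
#'   `clusters`, as from [read_reference_fasta()]) or a path to a reference
#'   FASTA file in the header dialect of [read_reference_fasta()].
#' @param trim infer and trim the 3' adapter ([detect_adapter()],
#'   [trim_reads()], [positional_bias_trim()]).
#' @param adapter known adapter sequence; skips inference when given.
#' @param trim_ignore_5p,bias_threshold adapter stage parameters.
#' @param complexity apply the low-complexity filter.
#' @param complexity_f threshold `f` of [complexity_params()].
#' @param mir run the miRNA stage (disable to send all reads straight to
#'   ncRNA annotation).
#' @param species self-species tag for the miRNA stage.
#' @param max_tail,max_internal,offset_window miRNA stage parameters.
#' @param nc_mismatch,tolerance ncRNA/tRF stage parameters.
#' @param pirna_mismatch piRNA cluster mapping mismatch allowance.
#' @param map optional genome map input for phasing/ping-pong analyses: an
#'   [alignment_frame()] or a path to a SAM/ELAND3 file.
#' @param map_dialect `"sam"` or `"eland3"` when `map` is a path.
#' @param phasi phase length for phasiRNA detection (`NULL` = skip).
#' @param pp compute the ping-pong signature on the map input.
#' @param outdir output directory for result tables (`NULL` = none).
#' @param seed integer seed recorded in the run report.
#' @return A `run_config` list.
#' @export
run_config <- function(input, format = "fasta", refs = list(),
                       trim = FALSE, adapter = NULL, trim_ignore_5p = 22L,
                       bias_threshold = 0.8,
                       complexity = TRUE, complexity_f = 0.75,
                       mir = TRUE, species = NULL,
                       max_tail = 2L, max_internal = 1L, offset_window = 5L,
                       nc_mismatch = 1L, tolerance = 2L,
                       pirna_mismatch = 0L,
                       map = NULL, map_dialect = "eland3",
                       phasi = NULL, pp = FALSE,
                       outdir = NULL, seed = 1L) {
  cfg <- as.list(environment())
  if (is.character(cfg$refs)) {
    if (!file.exists(cfg$refs)) stop("reference file not found: ", cfg$refs)
  }
  if (is.character(cfg$input) && !file.exists(cfg$input)) {
    stop("input file not found: ", cfg$input)
  }
  if (is.character(cfg$map) && !file.exists(cfg$map)) {
    stop("map file not found: ", cfg$map)
  }
  structure(cfg, class = "run_config")
}

#' Length distribution and positional nucleotide composition
#'
#' Standard per-class descriptive output: the count-weighted read length
#' histogram and, for every read position, the fraction of A/C/G/T among
#' reads long enough to cover that position (each row sums to 1).
#'
#' @param reads a [read_set()].
#' @return List with data.frames `length_distribution` (`length`, `reads`)
#'   and `composition` (`position`, `A`, `C`, `G`, `T`).
#' @export
summarize_class <- function(reads) {
  stopifnot(inherits(reads, "read_set"))
  if (nrow(reads) == 0) {
    return(list(length_distribution = data.frame(length = integer(),
                                                 reads = numeric()),
                composition = data.frame(position = integer(), A = numeric(),
                                         C = numeric(), G = numeric(),
                                         T = numeric())))
  }
  lens <- nchar(reads$seq)
  ld <- tapply(reads$count, lens, sum)
  length_distribution <- data.frame(length = as.integer(names(ld)),
                                    reads = as.numeric(ld))
  maxlen <- max(lens)
  comp <- matrix(0, nrow = maxlen, ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  for (p in seq_len(maxlen)) {
    has <- lens >= p
    freq <- weighted_base_freq(substr(reads$seq[has], p, p), reads$count[has])
    if (sum(freq) > 0) comp[p, ] <- freq / sum(freq)
  }
  list(length_distribution = length_distribution,
       composition = data.frame(position = seq_len(maxlen), comp))
}

#' Run the complete annotation pipeline
#'
#' Executes the fixed annotation hierarchy on a small RNA library:
#' optional adapter trimming, low-complexity filtering, tiered miRNA
#' annotation, ncRNA/cDNA annotation with fractional apportioning and tRF
#' classification, piRNA-cluster candidate calling, and (given a map input)
#' phasiRNA detection and the ping-pong signature. Every input read lands in
#' exactly one summary category, so the summary column sum equals the total
#' input read count.
#'
#' @param config a [run_config()].
#' @return A result list with components `summary` (category/reads
#'   data.frame), `total_input`, `mirna`, `ncrna_classes`, `trf`, `pirna`,
#'   `phasing`, `pingpong`, `length_distribution`,
#'   `positional_composition`, and `report` (parameters echoed for
#'   reproducibility). If `config$outdir` is set, tables are also written
#'   via [write_outputs()] together with a JSON run report.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  refs <- config$refs
  if (is.character(refs)) refs <- read_reference_fasta(refs)

  reads <- if (inherits(config$input, "read_set")) config$input else
    read_sequences(config$input, config$format)
  total_input <- total_reads(reads)
  cat_counts <- c()

  # adapter stage
  if (isTRUE(config$trim) && nrow(reads) > 0) {
    model <- if (!is.null(config$adapter)) {
      adapter_model(config$adapter, config$trim_ignore_5p,
                    config$bias_threshold)
    } else {
      detect_adapter(reads, config$trim_ignore_5p, config$bias_threshold)
    }
    before <- total_reads(reads)
    reads <- trim_reads(reads, model)
    reads <- positional_bias_trim(reads, model$bias_threshold)
    dropped <- before - total_reads(reads)
    if (dropped > 0) cat_counts["empty_after_trim"] <- dropped
  }
  trimmed_reads <- reads

  # low-complexity stage
  if (isTRUE(config$complexity) && nrow(reads) > 0) {
    fl <- filter_low_complexity(reads,
                                complexity_params(config$complexity_f))
    cat_counts["low_complexity"] <- total_reads(fl$rejected)
    reads <- fl$kept
  } else {
    cat_counts["low_complexity"] <- 0
  }

  # miRNA stage
  mirna_res <- NULL
  if (isTRUE(config$mir) && !is.null(refs$mirna) && nrow(reads) > 0) {
    mirna_res <- annotate_mirnas(reads, refs$mirna,
                                 mirna_params(config$max_tail,
                                              config$max_internal,
                                              config$offset_window,
                                              config$species))
    h <- mirna_res$hits
    if (nrow(h) > 0) {
      per_tier <- tapply(h$count_apportioned, paste0("miRNA_", h$tier), sum)
      cat_counts[names(per_tier)] <- as.numeric(per_tier)
    }
    reads <- mirna_res$unassigned
  }

  # ncRNA / tRF stage
  ncrna_res <- NULL
  class_counts <- setNames(numeric(), character())
  trf <- data.frame(seq = character(), trna = character(),
                    class = character(), count = numeric())
  if ((!is.null(refs$ncrna) || !is.null(refs$trna)) && nrow(reads) > 0) {
    ncrna_res <- annotate_ncrna(reads, refs,
                                ncrna_params(config$nc_mismatch,
                                             config$tolerance))
    class_counts <- apportion_counts(ncrna_res$table)
    trf <- ncrna_res$trf
    # report the tRNA share broken down into tRF classes (same total)
    if ("tRNA" %in% names(class_counts)) {
      class_counts <- class_counts[names(class_counts) != "tRNA"]
      if (nrow(trf) > 0) {
        per_trf <- tapply(trf$count, trf$class, sum)
        class_counts <- c(class_counts, setNames(as.numeric(per_trf),
                                                 names(per_trf)))
      }
    }
    if (length(class_counts)) {
      cat_counts[names(class_counts)] <- as.numeric(class_counts)
    }
    reads <- ncrna_res$unassigned
  }

  # piRNA cluster stage
  pirna_res <- NULL
  if (!is.null(refs$clusters) && nrow(reads) > 0) {
    pirna_res <- call_pirna_candidates(reads, refs$clusters,
                                       config$pirna_mismatch)
    cat_counts["piRNA_candidate"] <- total_reads(pirna_res$candidates)
    reads <- pirna_res$not_annotated
  }
  cat_counts["not_annotated"] <- if (nrow(reads) > 0) total_reads(reads) else 0

  # map-based analyses
  phasing <- NULL
  pingpong <- NULL
  map_aln <- NULL
  if (!is.null(config$map)) {
    map_aln <- if (inherits(config$map, "alignment_frame")) config$map else
      parse_map_file(config$map, config$map_dialect)
  }
  if (!is.null(config$phasi) && !is.null(map_aln)) {
    phasing <- scan_windows(map_aln, phase_params(config$phasi))
  }
  if (isTRUE(config$pp) && !is.null(map_aln)) {
    hist <- pingpong_histogram(map_aln)
    pingpong <- list(overlap_counts = hist, z_score = pingpong_zscore(hist))
  }

  summ <- data.frame(category = names(cat_counts),
                     reads = as.numeric(cat_counts),
                     stringsAsFactors = FALSE)
  summ <- summ[order(summ$category), , drop = FALSE]
  rownames(summ) <- NULL

  desc <- summarize_class(trimmed_reads)
  result <- list(
    summary = summ,
    total_input = total_input,
    mirna = mirna_res,
    ncrna = ncrna_res,
    ncrna_classes = class_counts,
    trf = trf,
    pirna = pirna_res,
    phasing = phasing,
    pingpong = pingpong,
    length_distribution = desc$length_distribution,
    positional_composition = desc$composition,
    report = list(
      package = "srnannot",
      version = as.character(utils::packageVersion("srnannot")),
      seed = config$seed,
      parameters = config[setdiff(names(config), c("input", "refs", "map"))]
    )
  )
  if (!is.null(config$outdir)) {
    write_outputs(result, config$outdir)
    jsonlite::write_json(result$report,
                         file.path(config$outdir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  }
  result
}
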