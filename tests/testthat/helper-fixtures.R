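# shared fixture builders; everything is generated in code, no stored data

write_fasta_lines <- function(headers, seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

write_fastq_lines <- function(seqs, path = tempfile(fileext = ".fq")) {
  q <- vapply(nchar(seqs), function(n) strrep("I", n), character(1))
  writeLines(as.vector(rbind(paste0("@r", seq_along(seqs)), seqs, "+", q)),
             path)
  path
}

# one hairpin with a known mature at a fixed position, for hand-built cases
toy_mirna_ref <- function() {
  # hairpin: 10 nt flank + 22 nt mature + flank
  mature <- "TGAGGTAGTAGGTTGTATAGTT"
  hp <- paste0("GCGCAGGACC", mature, "CTGATCCTACTACCTCAGCCAT")
  mirna_ref(
    hairpins = data.frame(id = "hpX", species = "spc", seq = hp),
    matures = data.frame(gene = "mirX", species = "spc", hairpin_id = "hpX",
                         start = 11L, end = 32L)
  )
}

toy_mature_seq <- function() "TGAGGTAGTAGGTTGTATAGTT"

# a synthetic tRNA record with known geometry: 76 nt body, 20 nt flanks,
# oligo-T at trailer positions 15-18
toy_trna <- function() {
  set.seed(42)
  body <- paste(sample(c("A", "C", "G", "T"), 76, replace = TRUE),
                collapse = "")
  if (grepl("CCA$", body)) substr(body, 76, 76) <- "G"
  leader <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                  collapse = "")
  trailer <- paste0("GTT", paste(sample(c("A", "C", "G"), 11, replace = TRUE),
                                 collapse = ""), "TTTT", "AC")
  data.frame(id = "trnaX", pad5 = 20L, pad3 = 20L,
             seq = paste0(leader, body, trailer), stringsAsFactors = FALSE)
}
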