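# Shared fixtures (built once per run) and independent oracles.

.fixtures <- new.env()

# the standard simulated dataset + its full mapping, cached across tests
fixture_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_dataset(sim_config(seed = 42))
  }
  .fixtures$sim
}

fixture_map <- function() {
  if (is.null(.fixtures$map)) {
    sim <- fixture_sim()
    .fixtures$map <- map_psms(sim$psms, sim$transcripts, sim$genome,
                              meta = list(genome_version = "simg1",
                                          dataset_id = "SIMDS001"))
  }
  .fixtures$map
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Brute-force oracle: enumerate every CDS nucleotide's genomic position one
# by one (in translation order), trim a trailing stop codon against the
# genome, select the peptide's nucleotides and group contiguous runs.
# Independent of the package's cds_range_to_blocks arithmetic.
oracle_blocks <- function(t, genome, start_aa, len_aa) {
  cds <- t$cds[order(t$cds$start), ]
  pos <- unlist(lapply(seq_len(nrow(cds)), function(i) {
    cds$start[i]:(cds$end[i] - 1L)
  }))
  if (t$strand == "-") pos <- rev(pos)
  chrseq <- as.character(genome[[t$chrom]])
  nt_at <- function(p) {
    b <- substr(chrseq, p + 1L, p + 1L)
    if (t$strand == "-") COMPLEMENT[[b]] else b
  }
  if (length(pos) %% 3L == 0L && length(pos) >= 3L) {
    last3 <- pos[(length(pos) - 2L):length(pos)]
    codon <- paste(vapply(last3, nt_at, character(1)), collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) {
      pos <- pos[seq_len(length(pos) - 3L)]
    }
  }
  a <- 3L * (start_aa - 1L) + 1L
  sel <- sort(pos[a:(a + 3L * len_aa - 1L)])
  brk <- which(diff(sel) > 1L)
  starts <- sel[c(1L, brk + 1L)]
  ends <- sel[c(brk, length(sel))] + 1L
  data.frame(start = starts, end = ends)
}

# strand-aware translation of a proBAM SEQ column entry
oracle_translate_seq <- function(seq, flag) {
  s <- Biostrings::DNAString(seq)
  if (bitwAnd(flag, 16L) != 0L) s <- Biostrings::reverseComplement(s)
  as.character(Biostrings::translate(s, no.init.codon = TRUE))
}

# minimal hand-built transcript on a tiny genome, for worked examples
toy_map <- function(cds, strand = "+", chrom = "chrT") {
  t <- transcript("tT", "gT", chrom, strand, exons = cds, cds = cds,
                  protein_id = "pT")
  build_cds_map(t)
}
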