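# Gene models: GTF parsing, translation-order CDS maps, and projection of
# protein coordinates onto the genome. Internal coordinates are 0-based
# half-open throughout; GTF's 1-based inclusive coordinates are converted on
# input and never used internally.

#' Construct a transcript gene model
#'
#' A transcript bundles its exon and CDS intervals on one chromosome and
#' strand. Intervals are data frames with integer columns `start` (0-based
#' inclusive) and `end` (exclusive), sorted ascending and pairwise disjoint.
#'
#' @param transcript_id,gene_id,protein_id identifier strings (`protein_id`
#'   may be `NA` for non-coding transcripts).
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds data frames with columns `start`, `end`.
#' @return an object of class `peptrack_transcript`.
#' @export
transcript <- function(transcript_id, gene_id, chrom, strand, exons,
                       cds = exons[0, ], protein_id = NA_character_) {
  stopifnot(strand %in% c("+", "-"))
  exons <- normalize_intervals(exons, transcript_id, "exon")
  cds <- normalize_intervals(cds, transcript_id, "CDS")
  # every CDS interval must lie inside some exon
  if (nrow(cds)) {
    inside <- vapply(seq_len(nrow(cds)), function(i) {
      any(exons$start <= cds$start[i] & cds$end[i] <= exons$end)
    }, logical(1))
    if (!all(inside)) {
      pt_stop("peptrack_model_error",
              "transcript %s: CDS interval outside all exons", transcript_id)
    }
  }
  structure(
    list(transcript_id = transcript_id, gene_id = gene_id,
         protein_id = protein_id, chrom = chrom, strand = strand,
         exons = exons, cds = cds),
    class = "peptrack_transcript"
  )
}

#' @export
print.peptrack_transcript <- function(x, ...) {
  cat(sprintf("<transcript %s gene=%s %s:%s %d exon(s), %d CDS segment(s)>\n",
              x$transcript_id, x$gene_id, x$chrom, x$strand,
              nrow(x$exons), nrow(x$cds)))
  invisible(x)
}

# sort ascending, check invariants; returns data.frame(start, end)
normalize_intervals <- function(df, id, what) {
  df <- data.frame(start = as.integer(df$start), end = as.integer(df$end))
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  if (any(df$start < 0) || any(df$end <= df$start)) {
    pt_stop("peptrack_model_error",
            "transcript %s: invalid %s interval (need 0 <= start < end)",
            id, what)
  }
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)])) {
    pt_stop("peptrack_model_error",
            "transcript %s: overlapping %s intervals", id, what)
  }
  df
}

# merge intervals separated by a zero-length gap (avoids 0N CIGAR elements)
merge_adjacent <- function(df) {
  if (nrow(df) < 2) return(df)
  out <- df[1, , drop = FALSE]
  for (i in 2:nrow(df)) {
    if (df$start[i] == out$end[nrow(out)]) {
      out$end[nrow(out)] <- df$end[i]
    } else {
      out <- rbind(out, df[i, ])
    }
  }
  rownames(out) <- NULL
  out
}

#' Parse gene models from a GTF file
#'
#' Reads `exon` and `CDS` features and groups them per `transcript_id`.
#' GTF coordinates (1-based inclusive) are converted to the internal 0-based
#' half-open convention. Transcripts without CDS features are returned as
#' non-coding models (empty `cds`).
#'
#' @param path path to a GTF file with `gene_id "…"; transcript_id "…";`
#'   (and optionally `protein_id "…";`) attributes.
#' @return named list of [transcript()] objects keyed by `transcript_id`.
#' @export
parse_gtf <- function(path) {
  if (!file.exists(path)) pt_stop("peptrack_io_error", "GTF not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) == 0) return(structure(list(), names = character(0)))
  nf <- lengths(strsplit(body, "\t", fixed = TRUE))
  if (any(nf != 9)) {
    bad <- which(!grepl("^#", lines) & nzchar(lines))[which(nf != 9)[1]]
    pt_stop("peptrack_parse_error", "malformed GTF line %d in %s (expected 9 fields)",
            bad, path)
  }
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) pt_stop("peptrack_parse_error",
                                             "failed to parse GTF %s: %s",
                                             path, conditionMessage(e)))
  md <- S4Vectors::mcols(gr)
  keep <- as.character(md$type) %in% c("exon", "CDS")
  gr <- gr[keep]
  md <- S4Vectors::mcols(gr)
  if (length(gr) == 0) return(structure(list(), names = character(0)))
  tid <- as.character(md$transcript_id)
  gid <- as.character(md$gene_id)
  pid <- if ("protein_id" %in% names(md)) as.character(md$protein_id)
         else rep(NA_character_, length(gr))
  feat <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,   # 1-based inclusive -> 0-based
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type = as.character(md$type),
    transcript_id = tid, gene_id = gid, protein_id = pid,
    stringsAsFactors = FALSE
  )
  out <- lapply(split(feat, feat$transcript_id), function(f) {
    if (length(unique(f$chrom)) > 1 || length(unique(f$strand)) > 1) {
      pt_stop("peptrack_model_error",
              "transcript %s: features on multiple chromosomes/strands",
              f$transcript_id[1])
    }
    ex <- f[f$type == "exon", c("start", "end")]
    cd <- f[f$type == "CDS", c("start", "end")]
    if (nrow(ex) == 0) ex <- cd   # CDS-only annotations imply their own exons
    transcript(
      transcript_id = f$transcript_id[1], gene_id = f$gene_id[1],
      protein_id = stats::na.omit(f$protein_id)[1] %||% NA_character_,
      chrom = f$chrom[1], strand = f$strand[1], exons = ex, cds = cd
    )
  })
  out[order(names(out))]
}

#' Build the translation-order CDS coordinate map of a transcript
#'
#' Orders the (genomically sorted) CDS segments in translation direction
#' (ascending for `+`, descending for `-`), merges segments separated by a
#' zero-length gap, and records the cumulative CDS-nucleotide offset of each
#' segment. When a genome is supplied and the final codon is a stop codon,
#' the trailing 3 nucleotides are trimmed, accommodating GTF dialects whose
#' CDS features include the stop codon.
#'
#' @param t a [transcript()] with at least one CDS interval.
#' @param genome optional [Biostrings::DNAStringSet] named by chromosome,
#'   used only to recognise (and trim) a trailing stop codon.
#' @return an object of class `peptrack_cds_map` with elements `transcript`,
#'   `segments` (translation order), `offsets`, `cds_len`.
#' @export
build_cds_map <- function(t, genome = NULL) {
  stopifnot(inherits(t, "peptrack_transcript"))
  if (nrow(t$cds) == 0) {
    pt_stop("peptrack_model_error", "transcript %s has no CDS", t$transcript_id)
  }
  segs <- merge_adjacent(t$cds)
  if (t$strand == "-") segs <- segs[rev(seq_len(nrow(segs))), , drop = FALSE]
  rownames(segs) <- NULL
  cds_len <- sum(segs$end - segs$start)

  if (!is.null(genome) && cds_len %% 3L == 0L && cds_len >= 3L) {
    codon <- cds_nt_seq(segs, t$strand, t$chrom, genome,
                        from = cds_len - 3L, to = cds_len)
    if (codon %in% c("TAA", "TAG", "TGA")) {
      segs <- trim_translation_end(segs, t$strand, 3L)
      cds_len <- cds_len - 3L
    }
  }
  if (cds_len %% 3L != 0L) {
    pt_stop("peptrack_model_error",
            "transcript %s: CDS length %d not divisible by 3",
            t$transcript_id, cds_len)
  }
  lens <- segs$end - segs$start
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  structure(
    list(transcript = t, segments = segs, offsets = as.integer(offsets),
         cds_len = as.integer(cds_len)),
    class = "peptrack_cds_map"
  )
}

#' @export
print.peptrack_cds_map <- function(x, ...) {
  cat(sprintf("<cds_map %s: %d segment(s), %d coding nt>\n",
              x$transcript$transcript_id, nrow(x$segments), x$cds_len))
  invisible(x)
}

# remove n nucleotides from the translation-order end of the segment list
trim_translation_end <- function(segs, strand, n) {
  while (n > 0L && nrow(segs) > 0L) {
    i <- nrow(segs)
    len <- segs$end[i] - segs$start[i]
    if (len > n) {
      if (strand == "+") segs$end[i] <- segs$end[i] - n
      else segs$start[i] <- segs$start[i] + n
      n <- 0L
    } else {
      segs <- segs[-i, , drop = FALSE]
      n <- n - len
    }
  }
  segs
}

# genomic nucleotide sequence of CDS coordinates [from, to) in translation
# orientation (reverse-complemented per segment for the minus strand)
cds_nt_seq <- function(segs, strand, chrom, genome, from, to) {
  blocks <- cds_range_to_blocks(segs, strand, from, to, merge = FALSE)
  chunks <- vapply(seq_len(nrow(blocks)), function(i) {
    s <- as.character(Biostrings::subseq(genome[[chrom]],
                                         blocks$start[i] + 1L, blocks$end[i]))
    if (strand == "-") s <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  # blocks come back in translation order here (see cds_range_to_blocks)
  toupper(paste(chunks, collapse = ""))
}

# project CDS-nucleotide range [from, to) onto genomic segments; returns a
# data.frame(start, end) in translation order (merge = FALSE) or ascending
# genomic order with adjacent blocks merged (merge = TRUE)
cds_range_to_blocks <- function(segs, strand, from, to, merge = TRUE) {
  lens <- segs$end - segs$start
  offsets <- cumsum(c(0L, lens[-length(lens)]))
  pieces <- list()
  for (i in seq_len(nrow(segs))) {
    a <- max(from, offsets[i])
    b <- min(to, offsets[i] + lens[i])
    if (b <= a) next
    if (strand == "+") {
      g <- c(segs$start[i] + (a - offsets[i]), segs$start[i] + (b - offsets[i]))
    } else {
      g <- c(segs$end[i] - (b - offsets[i]), segs$end[i] - (a - offsets[i]))
    }
    pieces[[length(pieces) + 1L]] <- data.frame(start = g[1], end = g[2])
  }
  out <- do.call(rbind, pieces)
  if (is.null(out)) out <- data.frame(start = integer(0), end = integer(0))
  if (merge) {
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
    out <- merge_adjacent(out)
  }
  out
}

#' Project a protein sub-sequence onto genome coordinates
#'
#' Maps the peptide occupying protein positions `start_aa ..
#' start_aa + len_aa - 1` (1-based) to its genomic footprint: the exonic
#' intervals covering CDS nucleotides `3 (start_aa - 1) .. 3 (start_aa - 1) +
#' 3 len_aa - 1`, split at CDS segment boundaries, merged when genomically
#' adjacent and returned in ascending genomic order.
#'
#' @param m a [build_cds_map()] result.
#' @param start_aa 1-based protein start position of the peptide.
#' @param len_aa peptide length in amino acids.
#' @return an object of class `peptrack_mapped_blocks`: list with `chrom`,
#'   `strand`, `blocks` (data frame `start`, `end`, ascending) and `frame`
#'   (always 0: peptides start on codon boundaries).
#' @export
protein_to_genome <- function(m, start_aa, len_aa) {
  stopifnot(inherits(m, "peptrack_cds_map"))
  if (start_aa < 1L || len_aa < 1L) {
    pt_stop("peptrack_range_error", "start_aa and len_aa must be positive")
  }
  nt0 <- 3L * (as.integer(start_aa) - 1L)
  nt1 <- nt0 + 3L * as.integer(len_aa)
  if (nt1 > m$cds_len) {
    pt_stop("peptrack_range_error",
            "peptide (aa %d..%d) extends past CDS of %s (%d nt)",
            start_aa, start_aa + len_aa - 1L, m$transcript$transcript_id,
            m$cds_len)
  }
  blocks <- cds_range_to_blocks(m$segments, m$transcript$strand, nt0, nt1)
  mapped_blocks(m$transcript$chrom, m$transcript$strand, blocks)
}

#' @rdname protein_to_genome
#' @param chrom,strand,blocks components of the mapped footprint.
#' @export
mapped_blocks <- function(chrom, strand, blocks) {
  blocks <- data.frame(start = as.integer(blocks$start),
                       end = as.integer(blocks$end))
  stopifnot(strand %in% c("+", "-"), nrow(blocks) >= 1,
            all(blocks$end > blocks$start),
            !is.unsorted(blocks$start, strictly = TRUE))
  structure(list(chrom = chrom, strand = strand, blocks = blocks, frame = 0L),
            class = "peptrack_mapped_blocks")
}

#' @export
print.peptrack_mapped_blocks <- function(x, ...) {
  cat(sprintf("<mapped_blocks %s:%s %s>\n", x$chrom, x$strand,
              paste(sprintf("[%d,%d)", x$blocks$start, x$blocks$end),
                    collapse = " ")))
  invisible(x)
}

#' Find all occurrences of a peptide in a protein sequence
#'
#' Exact, possibly overlapping matching; I and L are distinct letters.
#'
#' @param protein_seq,peptide_seq uppercase amino-acid strings.
#' @return integer vector of 1-based start positions, ascending (empty when
#'   the peptide does not occur).
#' @export
find_peptide_in_protein <- function(protein_seq, peptide_seq) {
  if (nchar(peptide_seq) == 0 || nchar(peptide_seq) > nchar(protein_seq)) {
    return(integer(0))
  }
  m <- Biostrings::matchPattern(peptide_seq, Biostrings::AAString(protein_seq))
  sort(IRanges::start(m))
}
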