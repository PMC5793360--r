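# Interconversion between proBAM and proBed, aggregation of PSMs to
# peptides, FDR filtering, gene inference and spectral counting.

#' Convert proBAM records to proBed records
#'
#' One proBed line per mapped proBAM record (primary and secondary alike);
#' unmapped records are not representable in proBed and are dropped, with
#' the dropped count attached as `attr(, "dropped_unmapped")`. The
#' experimental m/z is recovered from the XB mass-error tag when set
#' (`exp = calc + XB / charge`); the calculated m/z is recomputed from
#' peptide, modifications and charge.
#'
#' @param records `peptrack_probam` data frame.
#' @param meta list: `genome_version`, `dataset_id` defaults for records
#'   lacking them.
#' @return `peptrack_probed` data frame.
#' @export
probam_to_probed <- function(records, meta = list()) {
  mapped <- records$rname != "*" & bitwAnd(records$flag, 4L) == 0L
  dropped <- sum(!mapped)
  if (dropped > 0) {
    message(sprintf("probam_to_probed: dropped %d unmapped record(s)", dropped))
  }
  rec <- records[mapped, , drop = FALSE]
  n <- nrow(rec)
  out <- probed_template(n)
  unz <- function(x) ifelse(is.na(x) | x == "*", NA_character_, x)
  for (i in seq_len(n)) {
    b <- cigar_to_blocks(rec$cigar[i], rec$pos[i] - 1L)
    out$chrom[i] <- rec$rname[i]
    out$chromStart[i] <- b$start[1]
    out$chromEnd[i] <- b$end[nrow(b)]
    acc <- unz(rec$YP[i])
    out$name[i] <- sprintf("%s_%s_%d", acc %||% ".", rec$XP[i], i)
    out$strand[i] <- if (bitwAnd(rec$flag[i], 16L) != 0L) "-" else "+"
    out$blockCount[i] <- nrow(b)
    out$blockSizes[i] <- paste(b$end - b$start, collapse = ",")
    out$blockStarts[i] <- paste(b$start - b$start[1], collapse = ",")
    out$proteinAccession[i] <- acc
    out$peptideSequence[i] <- rec$XP[i]
    out$uniqueness[i] <- unz(rec$XO[i])
    out$psmScore[i] <- if (rec$XS[i] == -1) NA_real_ else rec$XS[i]
    out$fdr[i] <- if (rec$XQ[i] == -1) NA_real_ else rec$XQ[i]
    out$modifications[i] <- if (is.na(rec$XM[i]) || rec$XM[i] == "*") "."
                            else rec$XM[i]
    out$charge[i] <- rec$XC[i]
    calc <- tryCatch(calc_mz(rec$XP[i], rec$XM[i], rec$XC[i]),
                     error = function(e) NA_real_)
    out$calcMassToCharge[i] <- calc
    out$expMassToCharge[i] <-
      if (!is.na(calc) && rec$XB[i] != -1) calc + rec$XB[i] / rec$XC[i]
      else NA_real_
    out$uri[i] <- unz(rec$XU[i])
  }
  out$score <- 1000L
  out$thickStart <- out$chromStart
  out$thickEnd <- out$chromEnd
  out$itemRgb <- "0"
  out$genomeReferenceVersion <- meta$genome_version %||% NA_character_
  out$psmRank <- NA_integer_    # rank is not carried by proBAM tags
  out$datasetID <- meta$dataset_id %||% NA_character_
  attr(out, "dropped_unmapped") <- dropped
  out
}

#' Convert proBed records to proBAM records
#'
#' Mandatory SAM columns are reconstructed from the BED block structure
#' (`pos = chromStart + 1`, CIGAR from blockSizes/blockStarts). SEQ is
#' re-extracted from the genome when one is supplied, else `*`. Tags without
#' a proBed counterpart (XL, XI, XB, XR, YB, YA, XN, XT, XE, XF, XA) are
#' emitted as their null sentinels, the expected behaviour when mapping the
#' leaner format back into the richer one.
#'
#' @param records `peptrack_probed` data frame.
#' @param genome optional [Biostrings::DNAStringSet].
#' @return `peptrack_probam` data frame.
#' @export
probed_to_probam <- function(records, genome = NULL) {
  n <- nrow(records)
  out <- probam_template(n)
  for (i in seq_len(n)) {
    sizes <- as.integer(strsplit(records$blockSizes[i], ",")[[1]])
    starts <- as.integer(strsplit(records$blockStarts[i], ",")[[1]])
    if (length(sizes) != records$blockCount[i] ||
        length(starts) != records$blockCount[i] || starts[1] != 0L ||
        records$chromStart[i] + starts[length(starts)] + sizes[length(sizes)] !=
          records$chromEnd[i]) {
      pt_stop("peptrack_format_error",
              "record %d: inconsistent BED12 block structure", i)
    }
    b <- data.frame(start = records$chromStart[i] + starts,
                    end = records$chromStart[i] + starts + sizes)
    mb <- mapped_blocks(records$chrom[i], records$strand[i], b)
    out$qname[i] <- records$name[i]
    out$flag[i] <- compute_flag(records$strand[i])
    out$rname[i] <- records$chrom[i]
    out$pos[i] <- records$chromStart[i] + 1L
    out$mapq[i] <- 255L
    out$cigar[i] <- make_cigar(mb)
    out$rnext[i] <- "*"; out$pnext[i] <- 0L; out$tlen[i] <- 0L
    out$seq[i] <- if (is.null(genome)) "*" else extract_seq(genome, mb)
    out$qual[i] <- "*"
    out$NH[i] <- if (identical(records$uniqueness[i], "unique")) 1L
                 else tag_null("i")
    out$XO[i] <- records$uniqueness[i] %||% "*"
    out$XL[i] <- tag_null("i")
    out$XP[i] <- records$peptideSequence[i]
    out$YP[i] <- records$proteinAccession[i] %||% "*"
    out$XF[i] <- "*"
    out$XI[i] <- -1; out$XB[i] <- -1
    out$XR[i] <- "*"; out$YB[i] <- "*"; out$YA[i] <- "*"
    out$XS[i] <- records$psmScore[i] %||% -1
    out$XQ[i] <- records$fdr[i] %||% -1
    out$XC[i] <- records$charge[i]
    out$XA[i] <- -1L
    out$XM[i] <- if (is.na(records$modifications[i]) ||
                     records$modifications[i] == ".") "*"
                 else records$modifications[i]
    out$XN[i] <- -1L; out$XT[i] <- -1L; out$XE[i] <- -1L
    out$XG[i] <- if (records$blockCount[i] > 1) "J" else "U"
    out$XU[i] <- records$uri[i] %||% "*"
  }
  out
}

#' Aggregate PSM-level proBAM records to peptide-level records
#'
#' Groups mapped records by (peptide sequence, chromosome, strand, block
#' structure) — one record per genomic locus of a peptide, so multi-mapped
#' peptides keep one line per locus. The group representative is the member
#' with the best score; `psm_count`, `best_score` and `best_qvalue` columns
#' are added. Unmapped records are dropped and counted in
#' `attr(, "dropped_unmapped")`.
#'
#' @param records `peptrack_probam` data frame.
#' @return peptide-level `peptrack_probam` data frame with the extra
#'   `psm_count`, `best_score`, `best_qvalue` columns.
#' @export
aggregate_to_peptides <- function(records) {
  mapped <- records$rname != "*" & bitwAnd(records$flag, 4L) == 0L
  dropped <- sum(!mapped)
  rec <- records[mapped, , drop = FALSE]
  key <- paste(rec$XP, rec$rname,
               ifelse(bitwAnd(rec$flag, 16L) != 0L, "-", "+"),
               rec$pos, rec$cigar, sep = "\r")
  groups <- split(seq_len(nrow(rec)), key)
  rows <- lapply(groups, function(idx) {
    g <- rec[idx, , drop = FALSE]
    best <- which.max(ifelse(g$XS == -1, -Inf, g$XS))
    r <- g[best, , drop = FALSE]
    r$qname <- sprintf("%s_%s_%d", r$XP, r$rname, r$pos)
    r$psm_count <- length(idx)
    r$best_score <- r$XS
    r$best_qvalue <- r$XQ
    r
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- probam_template(0L)
    out$psm_count <- integer(0)
    out$best_score <- numeric(0)
    out$best_qvalue <- numeric(0)
  }
  out <- out[order(out$rname, out$pos, out$XP, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peptrack_probam", "data.frame")
  attr(out, "dropped_unmapped") <- dropped
  out
}

#' Filter records at an FDR threshold
#'
#' Keeps records whose q-value is at most `threshold`. Works on proBAM
#' records (`XQ`, -1 sentinel = unset), proBed records (`fdr`) and PSM
#' tables (`qvalue`). Records with an unset q-value are dropped and counted
#' in `attr(, "dropped_unset")`.
#'
#' @param records a record or PSM data frame.
#' @param threshold FDR threshold in `[0, 1]`.
#' @return the filtered data frame.
#' @export
filter_by_fdr <- function(records, threshold) {
  q <- if ("XQ" %in% names(records)) ifelse(records$XQ == -1, NA_real_, records$XQ)
       else if ("fdr" %in% names(records)) records$fdr
       else if ("qvalue" %in% names(records)) records$qvalue
       else pt_stop("peptrack_fdr_error", "no q-value column found")
  keep <- !is.na(q) & q <= threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped_unset") <- sum(is.na(q))
  out
}

# blocks of each record as a list of data.frames (from pos/cigar)
record_blocks <- function(records) {
  lapply(seq_len(nrow(records)), function(i) {
    cigar_to_blocks(records$cigar[i], records$pos[i] - 1L)
  })
}

# is every [start,end) block contained in the (merged) CDS of a transcript?
blocks_within_cds <- function(blocks, cds) {
  cds <- merge_adjacent(cds)
  all(vapply(seq_len(nrow(blocks)), function(i) {
    any(cds$start <= blocks$start[i] & blocks$end[i] <= cds$end)
  }, logical(1)))
}

#' Assign mapped peptide records to genes
#'
#' A record is assigned to every gene one of whose transcripts' CDS contains
#' all of the record's blocks on the same chromosome and strand. Records
#' hitting exactly one gene are `unique`, more than one `shared`, none
#' `none` (intergenic or unannotated).
#'
#' @param records mapped `peptrack_probam` (PSM- or peptide-level) records.
#' @param transcripts list of [transcript()] gene models.
#' @return data frame: `qname`, `peptide`, `chrom`, `pos`, `genes`
#'   (comma-joined, `.` when none), `n_genes`, `status`.
#' @export
infer_genes <- function(records, transcripts) {
  mapped <- records$rname != "*" & bitwAnd(records$flag, 4L) == 0L
  rec <- records[mapped, , drop = FALSE]
  blocks <- record_blocks(rec)
  strands <- ifelse(bitwAnd(rec$flag, 16L) != 0L, "-", "+")
  genes <- vapply(seq_len(nrow(rec)), function(i) {
    hits <- unique(unlist(lapply(transcripts, function(t) {
      if (nrow(t$cds) == 0) return(NULL)
      if (t$chrom != rec$rname[i] || t$strand != strands[i]) return(NULL)
      if (blocks_within_cds(blocks[[i]], t$cds)) t$gene_id else NULL
    })))
    if (length(hits) == 0) "." else paste(sort(hits), collapse = ",")
  }, character(1))
  n_genes <- ifelse(genes == ".", 0L, lengths(strsplit(genes, ",")))
  data.frame(
    qname = rec$qname, peptide = rec$XP, chrom = rec$rname, pos = rec$pos,
    genes = genes, n_genes = as.integer(n_genes),
    status = c("none", "unique", "shared")[pmin(n_genes, 2L) + 1L],
    stringsAsFactors = FALSE
  )
}

#' Gene-level spectral counts
#'
#' Counts, per gene: distinct peptide sequences assigned uniquely to the
#' gene (`unique_peptide_count`), distinct peptide sequences shared with
#' other genes (`shared_peptide_count`), and the spectral count — the
#' number of PSM records assigned uniquely to the gene. A multi-mapped PSM
#' (several loci per `qname`) counts as unique only when all its loci point
#' to the same single gene. Shared PSMs contribute to shared peptide counts
#' only.
#'
#' @param records PSM-level mapped `peptrack_probam` records.
#' @param transcripts list of [transcript()] gene models.
#' @return data frame (`gene_id`, `unique_peptide_count`,
#'   `shared_peptide_count`, `spectral_count`), one row per gene with any
#'   assigned peptide, sorted by `gene_id`.
#' @export
spectral_counts <- function(records, transcripts) {
  empty <- data.frame(gene_id = character(0), unique_peptide_count = integer(0),
                      shared_peptide_count = integer(0),
                      spectral_count = integer(0))
  asg <- infer_genes(records, transcripts)
  if (nrow(asg) == 0) return(empty)
  # union of genes over all loci of one spectrum
  per_q <- lapply(split(asg, asg$qname), function(a) {
    g <- setdiff(unique(unlist(strsplit(a$genes, ","))), ".")
    list(genes = g, peptide = a$peptide[1])
  })
  all_genes <- sort(unique(unlist(lapply(per_q, `[[`, "genes"))))
  if (length(all_genes) == 0) return(empty)
  uniq_pep <- lapply(stats::setNames(all_genes, all_genes), function(g) character(0))
  shared_pep <- uniq_pep
  spec <- stats::setNames(integer(length(all_genes)), all_genes)
  for (q in per_q) {
    if (length(q$genes) == 1) {
      g <- q$genes
      spec[g] <- spec[g] + 1L
      uniq_pep[[g]] <- union(uniq_pep[[g]], q$peptide)
    } else if (length(q$genes) > 1) {
      for (g in q$genes) shared_pep[[g]] <- union(shared_pep[[g]], q$peptide)
    }
  }
  data.frame(
    gene_id = all_genes,
    unique_peptide_count = vapply(uniq_pep, length, 0L)[all_genes],
    shared_peptide_count = vapply(shared_pep, length, 0L)[all_genes],
    spectral_count = unname(spec[all_genes]),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Write a gene count table as TSV
#'
#' @param counts a [spectral_counts()] table.
#' @param path output file.
#' @export
write_gene_counts <- function(counts, path) {
  out <- counts
  names(out) <- c("gene_id", "unique_peptides", "shared_peptides",
                  "spectral_count")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
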