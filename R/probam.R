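# proBAM: a SAM text dialect in which each alignment record is a PSM mapped
# to genome coordinates. Records keep the 11 mandatory SAM columns and carry
# a fixed payload of 21 proteomics tags in TAG:TYPE:VALUE form. Binary
# BAM/BGZF encoding is delegated to standard external tooling (samtools).

# The 21 proBAM tags, in emission order, with their SAM types.
PROBAM_TAGS <- data.frame(
  tag = c("NH", "XO", "XL", "XP", "YP", "XF", "XI", "XB", "XR", "YB", "YA",
          "XS", "XQ", "XC", "XA", "XM", "XN", "XT", "XE", "XG", "XU"),
  type = c("i", "Z", "i", "Z", "Z", "Z", "f", "f", "Z", "Z", "Z",
           "f", "f", "i", "i", "Z", "i", "i", "i", "A", "Z"),
  stringsAsFactors = FALSE
)

SAM_MANDATORY <- c("qname", "flag", "rname", "pos", "mapq", "cigar",
                   "rnext", "pnext", "tlen", "seq", "qual")

# Null sentinels per tag type: -1 for numeric tags whose real values are
# non-negative, "*" for strings; SAM forbids "*" as an A value so the
# peptide-type tag XG uses "U" (unknown).
tag_null <- function(type, tag = "") {
  switch(type, i = -1L, f = -1, Z = "*", A = "U")
}

probam_template <- function(n) {
  df <- data.frame(
    qname = character(n), flag = integer(n), rname = character(n),
    pos = integer(n), mapq = integer(n), cigar = character(n),
    rnext = character(n), pnext = integer(n), tlen = integer(n),
    seq = character(n), qual = character(n),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(PROBAM_TAGS))) {
    tg <- PROBAM_TAGS$tag[i]; ty <- PROBAM_TAGS$type[i]
    df[[tg]] <- rep(switch(ty, i = NA_integer_, f = NA_real_,
                           Z = NA_character_, A = NA_character_), n)
  }
  class(df) <- c("peptrack_probam", "data.frame")
  df
}

#' Spliced CIGAR string of a genomic footprint
#'
#' Alternates `<len>M` for exonic blocks and `<gap>N` for the introns
#' between them, in genomic order regardless of strand.
#'
#' @param blocks a [mapped_blocks()] object or a data frame with ascending
#'   disjoint `start`/`end` columns.
#' @return CIGAR string.
#' @export
make_cigar <- function(blocks) {
  b <- if (inherits(blocks, "peptrack_mapped_blocks")) blocks$blocks else blocks
  if (is.null(b) || nrow(b) == 0) {
    pt_stop("peptrack_cigar_error", "cannot build a CIGAR from zero blocks")
  }
  lens <- b$end - b$start
  gaps <- if (nrow(b) > 1) b$start[-1] - b$end[-nrow(b)] else integer(0)
  parts <- character(2 * nrow(b) - 1)
  parts[seq(1, length(parts), by = 2)] <- sprintf("%dM", lens)
  if (length(gaps)) parts[seq(2, length(parts), by = 2)] <- sprintf("%dN", gaps)
  paste(parts, collapse = "")
}

#' @rdname make_cigar
#' @param cigar CIGAR string (`<len>M`/`<len>N` alternation).
#' @param pos0 0-based leftmost genomic position.
#' @return `cigar_to_blocks()`: data frame of `start`/`end` block intervals.
#' @export
cigar_to_blocks <- function(cigar, pos0) {
  m <- regmatches(cigar, gregexpr("[0-9]+[MN]", cigar))[[1]]
  if (!length(m) || nchar(paste(m, collapse = "")) != nchar(cigar)) {
    pt_stop("peptrack_cigar_error", "unsupported CIGAR: %s", cigar)
  }
  lens <- as.integer(sub("[MN]", "", m))
  ops <- substring(m, nchar(m))
  at <- as.integer(pos0)
  starts <- integer(0); ends <- integer(0)
  for (i in seq_along(ops)) {
    if (ops[i] == "M") { starts <- c(starts, at); ends <- c(ends, at + lens[i]) }
    at <- at + lens[i]
  }
  data.frame(start = starts, end = ends)
}

#' SAM flag of a PSM mapping
#'
#' 0 for a mapped primary plus-strand record; bit 16 (0x10) for the minus
#' strand; bit 4 (0x4), alone, for unmapped; bit 256 (0x100) for secondary
#' mappings of a multi-mapped peptide.
#'
#' @param strand `"+"` or `"-"` (ignored when unmapped).
#' @param mapped logical.
#' @param primary logical; `FALSE` marks a secondary mapping.
#' @return integer flag.
#' @export
compute_flag <- function(strand, mapped = TRUE, primary = TRUE) {
  if (!mapped) return(4L)
  f <- 0L
  if (strand == "-") f <- f + 16L
  if (!primary) f <- f + 256L
  f
}

#' Forward-strand nucleotide sequence under a genomic footprint
#'
#' Concatenates the genome substrings of the blocks in ascending genomic
#' order. Following SAM convention the sequence is reported on the forward
#' genomic strand even for minus-strand peptides (reverse-complement before
#' translating those).
#'
#' @param genome [Biostrings::DNAStringSet] named by chromosome.
#' @param blocks a [mapped_blocks()] object.
#' @return uppercase nucleotide string.
#' @export
extract_seq <- function(genome, blocks) {
  stopifnot(inherits(blocks, "peptrack_mapped_blocks"))
  if (!blocks$chrom %in% names(genome)) {
    pt_stop("peptrack_range_error", "chromosome %s not in genome", blocks$chrom)
  }
  chr <- genome[[blocks$chrom]]
  if (any(blocks$blocks$end > length(chr))) {
    pt_stop("peptrack_range_error",
            "block exceeds length of chromosome %s", blocks$chrom)
  }
  toupper(paste(vapply(seq_len(nrow(blocks$blocks)), function(i) {
    as.character(Biostrings::subseq(chr, blocks$blocks$start[i] + 1L,
                                    blocks$blocks$end[i]))
  }, character(1)), collapse = ""))
}

# count internal tryptic cleavage sites left uncut (K/R not before P)
count_missed_cleavages <- function(peptide) {
  aa <- strsplit(peptide, "")[[1]]
  n <- length(aa)
  if (n < 2) return(0L)
  sum(aa[-n] %in% c("K", "R") & aa[-1] != "P")
}

#' Encode one PSM as proBAM records
#'
#' One record per genomic mapping; the mapping with the smallest
#' (chromosome, start) is primary, the others carry flag bit 256. A PSM with
#' no mapping yields a single unmapped record (flag 4, `rname *`, `pos 0`,
#' `cigar *`, `seq *`). All 21 proteomics tags are always present; unknown
#' values take their null sentinels.
#'
#' @param psm one PSM: a single row of a [read_psm_tsv()] table (or a list
#'   with the same fields).
#' @param mappings list of [mapped_blocks()] (possibly empty).
#' @param genome optional [Biostrings::DNAStringSet] for the SEQ column.
#' @param contexts optional list parallel to `mappings`; each element may
#'   carry `ref_peptide`, `pre_aa`, `post_aa`, `peptide_type`,
#'   `enzymatic_termini`, `annotated` from the protein context.
#' @param meta list; `xl` = number of distinct peptides this spectrum maps
#'   to (default 1 for mapped spectra).
#' @return `peptrack_probam` data frame with one row per record.
#' @export
psm_to_probam <- function(psm, mappings, genome = NULL, contexts = NULL,
                          meta = list()) {
  psm <- as.list(psm)
  n_map <- length(mappings)
  if (n_map > 0) {
    ord <- order(vapply(mappings, function(m) m$chrom, character(1)),
                 vapply(mappings, function(m) m$blocks$start[1], integer(1)))
    mappings <- mappings[ord]
    if (!is.null(contexts)) contexts <- contexts[ord]
  }
  rec <- probam_template(max(1L, n_map))
  peptide <- psm$peptide
  qv <- psm$qvalue
  xq <- if (is.null(qv) || is.na(qv)) -1 else qv
  xs <- if (is.null(psm$score) || is.na(psm$score)) -1 else psm$score
  xn <- if (!is.null(psm$missed_cleavages) && !is.na(psm$missed_cleavages)) {
    as.integer(psm$missed_cleavages)
  } else count_missed_cleavages(peptide)
  xm <- format_mods(parse_mods(psm$mods %||% "."), na = "*")
  xu <- if (is.null(psm$uri) || is.na(psm$uri)) "*" else psm$uri
  decoy <- isTRUE(psm$decoy)

  if (n_map == 0) {
    rec$qname <- psm$spectrum_id
    rec$flag <- 4L; rec$rname <- "*"; rec$pos <- 0L; rec$mapq <- 255L
    rec$cigar <- "*"; rec$rnext <- "*"; rec$pnext <- 0L; rec$tlen <- 0L
    rec$seq <- "*"; rec$qual <- "*"
    rec$NH <- 0L; rec$XO <- "*"; rec$XL <- tag_null("i")
    rec$XP <- peptide
    rec$YP <- psm$protein %||% "*"
    rec$XF <- "*"; rec$XI <- -1; rec$XB <- -1
    rec$XR <- "*"; rec$YB <- "*"; rec$YA <- "*"
    rec$XS <- xs; rec$XQ <- xq; rec$XC <- as.integer(psm$charge)
    rec$XA <- 1L; rec$XM <- xm; rec$XN <- xn; rec$XT <- -1L; rec$XE <- -1L
    rec$XG <- if (decoy) "D" else "U"
    rec$XU <- xu
    return(rec)
  }

  for (i in seq_len(n_map)) {
    m <- mappings[[i]]
    ctx <- if (!is.null(contexts)) contexts[[i]] else list()
    rec$qname[i] <- psm$spectrum_id
    rec$flag[i] <- compute_flag(m$strand, mapped = TRUE, primary = i == 1L)
    rec$rname[i] <- m$chrom
    rec$pos[i] <- m$blocks$start[1] + 1L
    rec$mapq[i] <- 255L
    rec$cigar[i] <- make_cigar(m)
    rec$rnext[i] <- "*"; rec$pnext[i] <- 0L; rec$tlen[i] <- 0L
    rec$seq[i] <- if (is.null(genome)) "*" else extract_seq(genome, m)
    rec$qual[i] <- "*"
    rec$NH[i] <- n_map
    rec$XO[i] <- if (n_map == 1) "unique" else "not-unique"
    rec$XL[i] <- as.integer(meta$xl %||% 1L)
    rec$XP[i] <- peptide
    rec$YP[i] <- ctx$protein %||% psm$protein %||% "*"
    rec$XF[i] <- as.character(m$frame)
    rec$XI[i] <- -1                       # intensity: not carried by inputs
    rec$XB[i] <- mass_error_da(psm)
    rec$XR[i] <- ctx$ref_peptide %||% peptide
    rec$YB[i] <- ctx$pre_aa %||% "*"
    rec$YA[i] <- ctx$post_aa %||% "*"
    rec$XS[i] <- xs; rec$XQ[i] <- xq
    rec$XC[i] <- as.integer(psm$charge)
    rec$XA[i] <- as.integer(ctx$annotated %||% 0L)
    rec$XM[i] <- xm; rec$XN[i] <- xn
    rec$XT[i] <- as.integer(ctx$enzymatic_termini %||% -1L)
    rec$XE[i] <- 0L                       # enzyme code: 0 = trypsin
    rec$XG[i] <- if (decoy) "D" else {
      ctx$peptide_type %||% if (nrow(m$blocks) > 1) "J" else "N"
    }
    rec$XU[i] <- xu
  }
  rec
}

# signed monoisotopic mass error in Da (experimental - calculated); the
# null sentinel -1 is emitted when the experimental m/z is unknown
mass_error_da <- function(psm) {
  if (is.null(psm$exp_mz) || is.na(psm$exp_mz)) return(-1)
  calc <- tryCatch(calc_mz(psm$peptide, psm$mods %||% ".", psm$charge),
                   error = function(e) NA_real_)
  if (is.na(calc)) return(-1)
  psm$charge * (psm$exp_mz - calc)
}

#' Serialize the 21-tag payload of one proBAM record
#'
#' @param rec a single proBAM record (one-row data frame or list).
#' @return character vector of exactly 21 `TAG:TYPE:VALUE` strings in the
#'   canonical order.
#' @export
emit_tags <- function(rec) {
  rec <- as.list(rec)
  vapply(seq_len(nrow(PROBAM_TAGS)), function(i) {
    tg <- PROBAM_TAGS$tag[i]; ty <- PROBAM_TAGS$type[i]
    v <- rec[[tg]]
    val <- switch(ty,
      i = fmt_int(v, na = "-1"),
      f = fmt_float(v, na = "-1"),
      Z = if (is.na(v)) "*" else v,
      A = if (is.na(v)) "U" else v)
    sprintf("%s:%s:%s", tg, ty, val)
  }, character(1))
}

serialize_probam_record <- function(rec) {
  rec <- as.list(rec)
  paste(c(rec$qname, rec$flag, rec$rname, rec$pos, rec$mapq, rec$cigar,
          rec$rnext, rec$pnext, rec$tlen, rec$seq, rec$qual,
          emit_tags(rec)), collapse = "\t")
}

#' Sort proBAM records by genomic coordinate
#'
#' Lexicographic chromosome, then numeric position; unmapped records
#' (`rname == "*"`) sort last. Stable and idempotent.
#'
#' @param records `peptrack_probam` data frame.
#' @return the sorted data frame.
#' @export
sort_probam <- function(records) {
  ord <- order(records$rname == "*",
               records$rname, records$pos, method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read proBAM (SAM text)
#'
#' The header holds `@HD` (`SO:coordinate` when `sort = TRUE`), one `@SQ`
#' per chromosome, a `@PG` line, and optional `@CO` comment lines carrying
#' proteomics metadata as `key=value`. Records referencing a chromosome
#' absent from `seqlengths` are rejected.
#'
#' @param records `peptrack_probam` data frame.
#' @param path output file.
#' @param seqlengths named integer vector of chromosome lengths, or a
#'   [Biostrings::DNAStringSet] whose widths are used.
#' @param sort coordinate-sort records before writing.
#' @param comments character vector of `key=value` strings for `@CO` lines.
#' @return `write_probam()`: the path, invisibly. `read_probam()`: the
#'   record data frame, with the header lines in `attr(, "header")`.
#' @export
write_probam <- function(records, path, seqlengths, sort = FALSE,
                         comments = character()) {
  if (inherits(seqlengths, "DNAStringSet") || inherits(seqlengths, "XStringSet")) {
    seqlengths <- stats::setNames(Biostrings::width(seqlengths),
                                  names(seqlengths))
  }
  mapped <- records$rname != "*"
  unknown <- setdiff(unique(records$rname[mapped]), names(seqlengths))
  if (length(unknown)) {
    pt_stop("peptrack_header_error",
            "record(s) reference chromosome(s) absent from header: %s",
            paste(unknown, collapse = ", "))
  }
  if (sort) records <- sort_probam(records)
  header <- c(
    sprintf("@HD\tVN:1.0%s", if (sort) "\tSO:coordinate" else ""),
    sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths), as.integer(seqlengths)),
    sprintf("@PG\tID:peptrack\tPN:peptrack\tVN:%s",
            as.character(utils::packageVersion("peptrack"))),
    if (length(comments)) sprintf("@CO\t%s", comments)
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    serialize_probam_record(records[i, ])
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname write_probam
#' @export
read_probam <- function(path) {
  if (!file.exists(path)) pt_stop("peptrack_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  header <- lines[grepl("^@", lines)]
  body <- lines[!grepl("^@", lines) & nzchar(lines)]
  sq <- header[grepl("^@SQ\t", header)]
  chroms <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
  rec <- probam_template(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) {
      pt_stop("peptrack_format_error",
              "%s line %d: %d field(s), proBAM needs 11 mandatory columns",
              path, i + length(header), length(f))
    }
    rec$qname[i] <- f[1]; rec$flag[i] <- as.integer(f[2]); rec$rname[i] <- f[3]
    rec$pos[i] <- as.integer(f[4]); rec$mapq[i] <- as.integer(f[5])
    rec$cigar[i] <- f[6]; rec$rnext[i] <- f[7]; rec$pnext[i] <- as.integer(f[8])
    rec$tlen[i] <- as.integer(f[9]); rec$seq[i] <- f[10]; rec$qual[i] <- f[11]
    if (rec$rname[i] != "*" && !rec$rname[i] %in% chroms) {
      pt_stop("peptrack_header_error",
              "%s line %d: chromosome %s not declared in any @SQ line",
              path, i + length(header), rec$rname[i])
    }
    for (tagstr in f[-(1:11)]) {
      parts <- regmatches(tagstr, regexec("^([A-Za-z][A-Za-z0-9]):([AifZ]):(.*)$",
                                          tagstr))[[1]]
      if (length(parts) != 4) next
      tg <- parts[2]; ty <- parts[3]; val <- parts[4]
      if (!tg %in% PROBAM_TAGS$tag) next
      rec[[tg]][i] <- switch(ty, i = as.integer(val), f = as.numeric(val),
                             Z = val, A = val)
    }
  }
  attr(rec, "header") <- header
  rec
}

#' Validate a proBAM file
#'
#' Checks the mandatory-column count, flag/pos/cigar consistency between
#' mapped and unmapped records, the CIGAR-versus-peptide length relation
#' (sum of M lengths = 3x peptide length), SEQ length, tag presence and tag
#' types/domains.
#'
#' @param path proBAM (SAM text) file.
#' @return character vector of issues; empty when the file is valid.
#' @export
validate_probam <- function(path) {
  issues <- character(0)
  add <- function(line, msg) {
    issues <<- c(issues, sprintf("line %d: %s", line, msg))
  }
  lines <- readLines(path, warn = FALSE)
  is_hdr <- grepl("^@", lines)
  type_of <- stats::setNames(PROBAM_TAGS$type, PROBAM_TAGS$tag)
  for (i in which(!is_hdr & nzchar(lines))) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 11) { add(i, "fewer than 11 mandatory columns"); next }
    flag <- suppressWarnings(as.integer(f[2]))
    pos <- suppressWarnings(as.integer(f[4]))
    cig <- f[6]; seq <- f[10]
    tags <- f[-(1:11)]
    tg <- sub("^([A-Za-z][A-Za-z0-9]):.*$", "\\1", tags)
    ty <- sub("^[A-Za-z][A-Za-z0-9]:([^:]):.*$", "\\1", tags)
    tv <- sub("^[A-Za-z][A-Za-z0-9]:[^:]:", "", tags)
    names(tv) <- tg; names(ty) <- tg
    if (is.na(flag)) { add(i, "unparsable flag"); next }
    unmapped <- bitwAnd(flag, 4L) != 0L
    if (!"XP" %in% tg) { add(i, "missing XP peptide tag"); next }
    pep_len <- nchar(tv[["XP"]])
    if (unmapped) {
      if (f[3] != "*" || pos != 0L || cig != "*")
        add(i, "unmapped record must have rname *, pos 0, cigar *")
    } else {
      if (f[3] == "*" || is.na(pos) || pos < 1L)
        add(i, "mapped record must have rname and pos >= 1")
      if (cig == "*") {
        add(i, "mapped record must have a CIGAR")
      } else {
        msum <- sum(as.integer(
          sub("M", "", regmatches(cig, gregexpr("[0-9]+M", cig))[[1]])))
        if (msum != 3L * pep_len)
          add(i, sprintf("cigar/peptide length mismatch (%d M vs %d aa)",
                         msum, pep_len))
        if (seq != "*" && nchar(seq) != msum)
          add(i, "seq length does not equal CIGAR M-sum")
      }
    }
    for (known in intersect(tg, names(type_of))) {
      if (ty[[known]] != type_of[[known]])
        add(i, sprintf("tag %s has type %s, expected %s",
                       known, ty[[known]], type_of[[known]]))
    }
    if ("XC" %in% tg) {
      xc <- suppressWarnings(as.integer(tv[["XC"]]))
      if (is.na(xc) || xc < 1L) add(i, "XC charge must be >= 1")
    }
    if ("XQ" %in% tg) {
      xq <- suppressWarnings(as.numeric(tv[["XQ"]]))
      if (is.na(xq) || (xq != -1 && (xq < 0 || xq > 1)))
        add(i, "XQ must be in [0,1] or the -1 sentinel")
    }
  }
  issues
}
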