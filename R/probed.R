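# proBed: a 25-column BED dialect. The 12 standard BED fields (coordinates,
# BED12 block structure) are followed by 13 proteomics fields. Coordinates
# are 0-based half-open, as in BED. Output is plain sorted text compatible
# with standard BED tooling and with bedToBigBed (no header line by default).

PROBED_BED_FIELDS <- c("chrom", "chromStart", "chromEnd", "name", "score",
                       "strand", "thickStart", "thickEnd", "itemRgb",
                       "blockCount", "blockSizes", "blockStarts")
PROBED_PROT_FIELDS <- c("proteinAccession", "peptideSequence", "uniqueness",
                        "genomeReferenceVersion", "psmScore", "fdr",
                        "modifications", "charge", "expMassToCharge",
                        "calcMassToCharge", "psmRank", "datasetID", "uri")
PROBED_COLUMNS <- c(PROBED_BED_FIELDS, PROBED_PROT_FIELDS)

probed_template <- function(n) {
  df <- data.frame(
    chrom = character(n), chromStart = integer(n), chromEnd = integer(n),
    name = character(n), score = integer(n), strand = character(n),
    thickStart = integer(n), thickEnd = integer(n), itemRgb = character(n),
    blockCount = integer(n), blockSizes = character(n),
    blockStarts = character(n),
    proteinAccession = character(n), peptideSequence = character(n),
    uniqueness = character(n), genomeReferenceVersion = character(n),
    psmScore = numeric(n), fdr = numeric(n), modifications = character(n),
    charge = integer(n), expMassToCharge = numeric(n),
    calcMassToCharge = numeric(n), psmRank = integer(n),
    datasetID = character(n), uri = character(n),
    stringsAsFactors = FALSE
  )
  class(df) <- c("peptrack_probed", "data.frame")
  df
}

#' Encode one mapped PSM as a proBed record
#'
#' The genomic footprint becomes the BED12 block structure (`chromStart`/
#' `chromEnd` span the blocks; `blockStarts` are relative to `chromStart`);
#' `thickStart`/`thickEnd` equal the span (all of a peptide is coding); the
#' BED `score` is fixed at 1000 (display shading only — `psmScore` carries
#' the real value) and `itemRgb` at "0". Unset proteomics fields serialize
#' as `.`. Unmapped PSMs are not representable in proBed.
#'
#' @param psm one PSM (row of a [read_psm_tsv()] table, or a list).
#' @param mapping a non-empty [mapped_blocks()] object.
#' @param meta list: `genome_version`, `dataset_id`, `uniqueness`
#'   (`"unique"`/`"not-unique"`), `ordinal` (1-based index among this
#'   peptide's mappings, used in the `name` field).
#' @return one-row `peptrack_probed` data frame.
#' @export
psm_to_probed <- function(psm, mapping, meta = list()) {
  psm <- as.list(psm)
  if (is.null(mapping) || !inherits(mapping, "peptrack_mapped_blocks") ||
      nrow(mapping$blocks) == 0) {
    pt_stop("peptrack_not_representable",
            "unmapped PSMs cannot be represented in proBed")
  }
  b <- mapping$blocks
  rec <- probed_template(1L)
  rec$chrom <- mapping$chrom
  rec$chromStart <- b$start[1]
  rec$chromEnd <- b$end[nrow(b)]
  acc <- psm$protein %||% "."
  rec$name <- sprintf("%s_%s_%d", acc, psm$peptide,
                      as.integer(meta$ordinal %||% 1L))
  rec$score <- 1000L
  rec$strand <- mapping$strand
  rec$thickStart <- rec$chromStart
  rec$thickEnd <- rec$chromEnd
  rec$itemRgb <- "0"
  rec$blockCount <- nrow(b)
  rec$blockSizes <- paste(b$end - b$start, collapse = ",")
  rec$blockStarts <- paste(b$start - b$start[1], collapse = ",")
  rec$proteinAccession <- acc
  rec$peptideSequence <- psm$peptide
  rec$uniqueness <- meta$uniqueness %||% "unique"
  rec$genomeReferenceVersion <- meta$genome_version %||% NA_character_
  rec$psmScore <- psm$score %||% NA_real_
  rec$fdr <- psm$qvalue %||% NA_real_
  rec$modifications <- format_mods(parse_mods(psm$mods %||% "."), na = ".")
  rec$charge <- as.integer(psm$charge)
  rec$expMassToCharge <- psm$exp_mz %||% NA_real_
  rec$calcMassToCharge <- tryCatch(
    calc_mz(psm$peptide, psm$mods %||% ".", psm$charge),
    error = function(e) NA_real_)
  rec$psmRank <- psm$rank %||% NA_integer_
  rec$datasetID <- psm$dataset_id %||% meta$dataset_id %||% NA_character_
  rec$uri <- psm$uri %||% NA_character_
  rec
}

serialize_probed <- function(records) {
  tok <- function(x) ifelse(is.na(x), ".", as.character(x))
  cols <- list(
    records$chrom, records$chromStart, records$chromEnd, records$name,
    records$score, records$strand, records$thickStart, records$thickEnd,
    records$itemRgb, records$blockCount, records$blockSizes,
    records$blockStarts,
    tok(records$proteinAccession), records$peptideSequence,
    tok(records$uniqueness), tok(records$genomeReferenceVersion),
    fmt_float(records$psmScore, na = "."), fmt_float(records$fdr, na = "."),
    tok(records$modifications), tok(records$charge),
    fmt_float(records$expMassToCharge, na = "."),
    fmt_float(records$calcMassToCharge, na = "."),
    tok(records$psmRank), tok(records$datasetID), tok(records$uri)
  )
  do.call(paste, c(cols, sep = "\t"))
}

#' Write / read proBed files
#'
#' Plain tab-separated text, no header line by default (bedToBigBed rejects
#' headers); `track_line` can prepend one for direct browser upload. With
#' `sort = TRUE` lines are ordered by (chrom lexicographic, chromStart
#' numeric), the order required for bigBed conversion.
#'
#' @param records `peptrack_probed` data frame.
#' @param path file path.
#' @param sort coordinate-sort before writing.
#' @param track_line optional `track ...` line to prepend.
#' @return `write_probed()`: the path, invisibly; `read_probed()`: the
#'   record data frame.
#' @export
write_probed <- function(records, path, sort = FALSE, track_line = NULL) {
  if (sort) records <- sort_probed(records)
  lines <- serialize_probed(records)
  writeLines(c(track_line, lines), path)
  invisible(path)
}

#' @rdname write_probed
#' @export
sort_probed <- function(records) {
  ord <- order(records$chrom, records$chromStart, method = "radix")
  out <- records[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname write_probed
#' @export
read_probed <- function(path) {
  if (!file.exists(path)) pt_stop("peptrack_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  body_ln <- which(nzchar(lines) & !grepl("^(track|browser)\\b", lines))
  body <- lines[body_ln]
  rec <- probed_template(length(body))
  unset <- function(x) ifelse(x == ".", NA_character_, x)
  for (i in seq_along(body)) {
    f <- strsplit(body[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 25) {
      pt_stop("peptrack_format_error",
              "%s line %d: %d field(s), proBed requires 25",
              path, body_ln[i], length(f))
    }
    rec$chrom[i] <- f[1]
    rec$chromStart[i] <- as.integer(f[2]); rec$chromEnd[i] <- as.integer(f[3])
    rec$name[i] <- f[4]; rec$score[i] <- as.integer(f[5]); rec$strand[i] <- f[6]
    rec$thickStart[i] <- as.integer(f[7]); rec$thickEnd[i] <- as.integer(f[8])
    rec$itemRgb[i] <- f[9]; rec$blockCount[i] <- as.integer(f[10])
    rec$blockSizes[i] <- f[11]; rec$blockStarts[i] <- f[12]
    rec$proteinAccession[i] <- unset(f[13]); rec$peptideSequence[i] <- f[14]
    rec$uniqueness[i] <- unset(f[15])
    rec$genomeReferenceVersion[i] <- unset(f[16])
    rec$psmScore[i] <- as.numeric(unset(f[17]))
    rec$fdr[i] <- as.numeric(unset(f[18]))
    rec$modifications[i] <- f[19]   # "." is the explicit no-modifications token
    rec$charge[i] <- as.integer(unset(f[20]))
    rec$expMassToCharge[i] <- as.numeric(unset(f[21]))
    rec$calcMassToCharge[i] <- as.numeric(unset(f[22]))
    rec$psmRank[i] <- as.integer(unset(f[23]))
    rec$datasetID[i] <- unset(f[24]); rec$uri[i] <- unset(f[25])
  }
  rec
}

#' Validate a proBed file
#'
#' Checks the 25-field layout, coordinate ordering, BED12 block arithmetic
#' (first block at 0, last block reaching `chromEnd`, block count matching
#' the size/start lists, total block length = 3x peptide length), strand and
#' score domains, and the numeric proteomics fields.
#'
#' @param path proBed file.
#' @return character vector of issues; empty when valid.
#' @export
validate_probed <- function(path) {
  issues <- character(0)
  add <- function(line, msg) {
    issues <<- c(issues, sprintf("line %d: %s", line, msg))
  }
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    if (!nzchar(lines[i]) || grepl("^(track|browser)\\b", lines[i])) next
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != 25) { add(i, sprintf("%d field(s), expected 25", length(f))); next }
    s <- suppressWarnings(as.integer(f[2])); e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s >= e) add(i, "chromStart must be < chromEnd")
    sc <- suppressWarnings(as.integer(f[5]))
    if (is.na(sc) || sc < 0 || sc > 1000) add(i, "score outside [0,1000]")
    if (!f[6] %in% c("+", "-")) add(i, "strand must be + or -")
    ts <- suppressWarnings(as.integer(f[7])); te <- suppressWarnings(as.integer(f[8]))
    if (!identical(ts, s) || !identical(te, e))
      add(i, "thickStart/thickEnd must equal chromStart/chromEnd")
    bc <- suppressWarnings(as.integer(f[10]))
    sizes <- suppressWarnings(as.integer(strsplit(f[11], ",")[[1]]))
    starts <- suppressWarnings(as.integer(strsplit(f[12], ",")[[1]]))
    if (is.na(bc) || length(sizes) != bc || length(starts) != bc) {
      add(i, "blockCount does not match blockSizes/blockStarts")
    } else if (anyNA(sizes) || anyNA(starts)) {
      add(i, "non-numeric blockSizes/blockStarts")
    } else {
      if (starts[1] != 0L) add(i, "first blockStart must be 0")
      if (!is.na(s) && !is.na(e) &&
          s + starts[bc] + sizes[bc] != e)
        add(i, "last block must end at chromEnd")
      if (sum(sizes) != 3L * nchar(f[14]))
        add(i, sprintf("block sizes sum %d != 3 x peptide length %d",
                       sum(sizes), nchar(f[14])))
    }
    if (f[20] != ".") {
      ch <- suppressWarnings(as.integer(f[20]))
      if (is.na(ch) || ch < 1) add(i, "charge must be a positive integer or .")
    }
    if (f[18] != ".") {
      fdr <- suppressWarnings(as.numeric(f[18]))
      if (is.na(fdr) || fdr < 0 || fdr > 1) add(i, "fdr must be in [0,1] or .")
    }
    for (j in c(17, 21, 22)) {
      if (f[j] != "." && is.na(suppressWarnings(as.numeric(f[j]))))
        add(i, sprintf("field %d must be numeric or .", j))
    }
  }
  issues
}

#' Write the proBed autoSql schema
#'
#' Emits the fixed 25-field autoSql declaration used by bedToBigBed to type
#' the proteomics fields; byte-identical on every call. Nullable proteomics
#' fields are declared as strings so the `.` null token is representable.
#'
#' @param path output `.as` file.
#' @return the path, invisibly.
#' @export
emit_autosql <- function(path) {
  decl <- c(
    'table proBed',
    '"proBed: peptide-spectrum matches as genome annotation tracks"',
    "(",
    'string chrom; "Chromosome"',
    'uint chromStart; "Start position, 0-based"',
    'uint chromEnd; "End position, exclusive"',
    'string name; "Record name: protein_peptide_ordinal"',
    'uint score; "Display score, fixed at 1000"',
    'char[1] strand; "+ or -"',
    'uint thickStart; "Coding start (equals chromStart)"',
    'uint thickEnd; "Coding end (equals chromEnd)"',
    'uint itemRgb; "Display color, fixed at 0"',
    'uint blockCount; "Number of exonic blocks"',
    'int[blockCount] blockSizes; "Block lengths, comma separated"',
    'int[blockCount] blockStarts; "Block starts relative to chromStart"',
    'string proteinAccession; "Protein accession"',
    'string peptideSequence; "Peptide sequence"',
    'string uniqueness; "unique or not-unique genomic mapping"',
    'string genomeReferenceVersion; "Genome assembly version"',
    'string psmScore; "Search engine PSM score"',
    'string fdr; "PSM-level q-value"',
    'string modifications; "Peptide modifications, pos-ACCESSION"',
    'string charge; "Precursor charge state"',
    'string expMassToCharge; "Experimental m/z"',
    'string calcMassToCharge; "Calculated m/z"',
    'string psmRank; "PSM rank"',
    'string datasetID; "Source dataset identifier"',
    'string uri; "Source file URI"',
    ")"
  )
  writeLines(decl, path)
  invisible(path)
}
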