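# PSM input/output: the tabular PSM schema, the mzTab PSM section, peptide
# mass arithmetic and target-decoy q-value estimation.

# Monoisotopic residue masses (Da), standard 20-letter alphabet.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER  <- 18.010565
MASS_PROTON <- 1.007276

# Small built-in table of common Unimod modifications; `pos-ACCESSION` mod
# strings are resolved against it when no explicit mass delta is given.
UNIMOD_MASS <- c(
  "UNIMOD:1"  = 42.010565,   # acetyl
  "UNIMOD:4"  = 57.021464,   # carbamidomethyl
  "UNIMOD:21" = 79.966331,   # phospho
  "UNIMOD:35" = 15.994915    # oxidation
)

PSM_TSV_COLUMNS <- c("spectrum_id", "peptide", "charge", "exp_mz", "score",
                     "rank", "mods", "protein", "start", "missed_cleavages",
                     "decoy", "dataset_id", "uri")

#' Parse a modification string into a modification table
#'
#' Modifications are encoded `pos-ACCESSION` and comma-joined, with `.`
#' (or `*`, the proBAM null) meaning none. Position 0 is the peptide
#' N-terminus, 1..L a residue, L+1 the C-terminus.
#'
#' @param s modification string.
#' @return data frame with columns `position`, `accession`, `mass_delta`
#'   (`NA` for accessions outside the built-in table).
#' @export
parse_mods <- function(s) {
  empty <- data.frame(position = integer(0), accession = character(0),
                      mass_delta = numeric(0))
  if (is.na(s) || s %in% c(".", "*", "")) return(empty)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-(.+)$", parts))
  if (any(lengths(m) != 3)) {
    pt_stop("peptrack_parse_error", "unparsable modification string: %s", s)
  }
  pos <- as.integer(vapply(m, `[`, character(1), 2))
  acc <- vapply(m, `[`, character(1), 3)
  data.frame(position = pos, accession = acc,
             mass_delta = unname(UNIMOD_MASS[acc]))
}

#' @rdname parse_mods
#' @param mods a modification data frame as returned by `parse_mods()`.
#' @param na null token to use when there are no modifications.
#' @export
format_mods <- function(mods, na = ".") {
  if (is.null(mods) || nrow(mods) == 0) return(na)
  paste(sprintf("%d-%s", mods$position, mods$accession), collapse = ",")
}

#' Calculated mass-to-charge of a (modified) peptide
#'
#' Monoisotopic: `(sum of residue masses + water + sum of modification mass
#' deltas + charge protons) / charge`.
#'
#' @param peptide_seq uppercase amino-acid string.
#' @param mods modification table ([parse_mods()] output), a `pos-ACCESSION`
#'   string, or `NULL` for none.
#' @param charge positive integer charge state.
#' @return calculated m/z in Thomson.
#' @export
calc_mz <- function(peptide_seq, mods = NULL, charge = 2L) {
  stopifnot(length(peptide_seq) == 1, charge >= 1)
  aa <- strsplit(peptide_seq, "")[[1]]
  unknown <- setdiff(aa, names(AA_MONO))
  if (length(unknown)) {
    pt_stop("peptrack_residue_error", "unknown residue(s): %s",
            paste(unique(unknown), collapse = ", "))
  }
  if (is.character(mods)) mods <- parse_mods(mods)
  delta <- if (is.null(mods) || nrow(mods) == 0) 0 else {
    md <- mods$mass_delta
    if (anyNA(md)) {
      pt_stop("peptrack_mod_error", "modification(s) with unknown mass: %s",
              paste(mods$accession[is.na(md)], collapse = ", "))
    }
    sum(md)
  }
  (sum(AA_MONO[aa]) + MASS_WATER + delta + charge * MASS_PROTON) / charge
}

#' Read PSMs from the tabular PSM schema
#'
#' A UTF-8 TSV with header columns `spectrum_id, peptide, charge, exp_mz,
#' score, rank, mods, protein, start, missed_cleavages, decoy, dataset_id,
#' uri`; `.` encodes an unset value. `decoy` is 0/1.
#'
#' @param path input file.
#' @return data frame of class `peptrack_psms`, one row per PSM, with typed
#'   columns (`NA` for unset) and `mods` kept in its string encoding
#'   (see [parse_mods()]).
#' @export
read_psm_tsv <- function(path) {
  if (!file.exists(path)) pt_stop("peptrack_io_error", "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          colClasses = "character", check.names = FALSE)
  missing <- setdiff(PSM_TSV_COLUMNS, names(df))
  if (length(missing)) {
    pt_stop("peptrack_schema_error", "PSM TSV missing column(s): %s",
            paste(missing, collapse = ", "))
  }
  df <- df[, PSM_TSV_COLUMNS]
  unset <- function(x) ifelse(x == ".", NA_character_, x)
  out <- data.frame(
    spectrum_id = df$spectrum_id,
    peptide = df$peptide,
    charge = as.integer(unset(df$charge)),
    exp_mz = as.numeric(unset(df$exp_mz)),
    score = as.numeric(unset(df$score)),
    qvalue = NA_real_,
    rank = as.integer(unset(df$rank)),
    mods = df$mods,
    protein = unset(df$protein),
    start = as.integer(unset(df$start)),
    missed_cleavages = as.integer(unset(df$missed_cleavages)),
    decoy = unset(df$decoy) == "1",
    dataset_id = unset(df$dataset_id),
    uri = unset(df$uri),
    stringsAsFactors = FALSE
  )
  validate_psms(out, path)
  class(out) <- c("peptrack_psms", "data.frame")
  out
}

validate_psms <- function(psms, path = "<psms>") {
  for (i in seq_len(nrow(psms))) {
    if (is.na(psms$peptide[i]) || nchar(psms$peptide[i]) < 1) {
      pt_stop("peptrack_schema_error", "%s row %d: empty peptide", path, i)
    }
    if (is.na(psms$charge[i]) || psms$charge[i] < 1) {
      pt_stop("peptrack_schema_error", "%s row %d: charge must be >= 1", path, i)
    }
    tryCatch(parse_mods(psms$mods[i]), error = function(e) {
      pt_stop("peptrack_schema_error", "%s row %d: %s", path, i,
              conditionMessage(e))
    })
  }
  invisible(psms)
}

#' Write PSMs in the tabular PSM schema
#'
#' Exact inverse of [read_psm_tsv()]: unset values serialize as `.`.
#'
#' @param psms PSM data frame.
#' @param path output file.
#' @export
write_psm_tsv <- function(psms, path) {
  tok <- function(x) ifelse(is.na(x), ".", as.character(x))
  out <- data.frame(
    spectrum_id = psms$spectrum_id,
    peptide = psms$peptide,
    charge = tok(psms$charge),
    exp_mz = fmt_float(psms$exp_mz, na = "."),
    score = fmt_float(psms$score, na = "."),
    rank = tok(psms$rank),
    mods = psms$mods,
    protein = tok(psms$protein),
    start = tok(psms$start),
    missed_cleavages = tok(psms$missed_cleavages),
    decoy = ifelse(psms$decoy, "1", "0"),
    dataset_id = tok(psms$dataset_id),
    uri = tok(psms$uri),
    check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read the PSM section of an mzTab file
#'
#' Maps the PSH/PSM lines onto the internal PSM table: `sequence`, `PSM_ID`,
#' `accession`, `charge`, `exp_mass_to_charge`, `search_engine_score[1]`,
#' `modifications`, `spectra_ref` (and `opt_global_cv_MS:1002217_decoy_peptide`
#' when present). Other columns are ignored; mzTab `null` maps to unset.
#' mzTab encodes modifications `pos-ACCESSION`, matching the internal syntax.
#'
#' @param path mzTab file containing a PSH header line and PSM rows.
#' @return data frame of class `peptrack_psms` (see [read_psm_tsv()]).
#' @export
read_mztab_psm <- function(path) {
  if (!file.exists(path)) pt_stop("peptrack_io_error", "file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  psh_i <- grep("^PSH\t", lines)
  if (length(psh_i) == 0) {
    pt_stop("peptrack_format_error", "no PSH header line in %s", path)
  }
  header <- strsplit(lines[psh_i[1]], "\t", fixed = TRUE)[[1]][-1]
  psm_i <- grep("^PSM\t", lines)
  rows <- lapply(psm_i, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]][-1]
    if (length(f) < length(header)) {
      pt_stop("peptrack_format_error",
              "mzTab line %d: %d field(s), PSH declares %d",
              i, length(f), length(header))
    }
    stats::setNames(f[seq_along(header)], header)
  })
  nul <- function(x) ifelse(is.na(x) | x == "null" | x == "", NA_character_, x)
  col <- function(nm) vapply(rows, function(r) nul(r[nm] %||% NA_character_),
                             character(1))
  if (length(rows) == 0) {
    return(read_psm_tsv_empty())
  }
  decoy_col <- "opt_global_cv_MS:1002217_decoy_peptide"
  mods <- col("modifications")
  out <- data.frame(
    spectrum_id = col("spectra_ref") %na% col("PSM_ID"),
    peptide = col("sequence"),
    charge = as.integer(col("charge")),
    exp_mz = as.numeric(col("exp_mass_to_charge")),
    score = as.numeric(col("search_engine_score[1]")),
    qvalue = NA_real_,
    rank = 1L,
    mods = ifelse(is.na(mods), ".", mods),
    protein = col("accession"),
    start = as.integer(col("start")),
    missed_cleavages = NA_integer_,
    decoy = if (decoy_col %in% header) col(decoy_col) == "1" else FALSE,
    dataset_id = NA_character_,
    uri = NA_character_,
    stringsAsFactors = FALSE
  )
  validate_psms(out, path)
  class(out) <- c("peptrack_psms", "data.frame")
  out
}

# elementwise fallback
`%na%` <- function(a, b) ifelse(is.na(a), b, a)

read_psm_tsv_empty <- function() {
  out <- data.frame(
    spectrum_id = character(0), peptide = character(0), charge = integer(0),
    exp_mz = numeric(0), score = numeric(0), qvalue = numeric(0),
    rank = integer(0), mods = character(0), protein = character(0),
    start = integer(0), missed_cleavages = integer(0), decoy = logical(0),
    dataset_id = character(0), uri = character(0)
  )
  class(out) <- c("peptrack_psms", "data.frame")
  out
}

#' Target-decoy q-values
#'
#' For a target PSM with score `s`, the FDR at threshold `t` is
#' `#{decoys with score >= t} / max(1, #{targets with score >= t})`; the
#' q-value is the minimum FDR over all thresholds `t <= s` (monotone
#' non-increasing in score). Tied scores share one threshold. Decoy PSMs get
#' `NA`. Higher score means better by convention; negate ascending-is-better
#' scores upstream.
#'
#' @param psms PSM data frame with `score` and `decoy` columns.
#' @return the same data frame with the `qvalue` column filled for targets.
#' @export
compute_qvalues <- function(psms) {
  stopifnot(all(c("score", "decoy") %in% names(psms)))
  if (!any(!psms$decoy)) {
    pt_stop("peptrack_fdr_error", "no target PSMs: cannot estimate q-values")
  }
  thr <- sort(unique(psms$score))              # ascending thresholds
  n_dec <- vapply(thr, function(t) sum(psms$decoy & psms$score >= t), 0)
  n_tar <- vapply(thr, function(t) sum(!psms$decoy & psms$score >= t), 0)
  fdr <- n_dec / pmax(1, n_tar)
  q_at_thr <- cummin(fdr)                      # min FDR over thresholds <= s
  q <- q_at_thr[match(psms$score, thr)]
  psms$qvalue <- ifelse(psms$decoy, NA_real_, pmin(q, 1))
  psms
}
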