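# End-to-end mapping pipeline: read PSMs, locate peptides in the proteome,
# project them through CDS maps onto the genome, and encode the result as
# proBAM and proBed records.

#' Translate the proteome implied by gene models
#'
#' Builds CDS maps for every coding transcript and translates the spliced
#' CDS against the genome (trailing stop trimmed).
#'
#' @param transcripts named list of [transcript()].
#' @param genome [Biostrings::DNAStringSet].
#' @return list: `proteins` (named character, keyed by protein id) and
#'   `maps` (named list of CDS maps, keyed by protein id).
#' @export
translate_annotation <- function(transcripts, genome) {
  coding <- Filter(function(t) nrow(t$cds) > 0 && !is.na(t$protein_id),
                   transcripts)
  maps <- list(); proteins <- character(0)
  for (t in coding) {
    m <- build_cds_map(t, genome)
    nt <- cds_nt_seq(m$segments, t$strand, t$chrom, genome, 0L, m$cds_len)
    maps[[t$protein_id]] <- m
    proteins[t$protein_id] <- translate_nt(nt)
  }
  list(proteins = proteins, maps = maps)
}

# protein-context annotations for a peptide occurrence
protein_context <- function(prot_seq, start, len, n_blocks,
                            observed = NULL) {
  L <- nchar(prot_seq)
  end <- start + len - 1L
  ref <- substr(prot_seq, start, end)
  pad <- function(s, n) {
    paste0(strrep("-", n - nchar(s)), s)
  }
  pre <- pad(substr(prot_seq, max(1L, start - 2L), start - 1L), 2L)
  post <- substr(prot_seq, end + 1L, min(L, end + 2L))
  post <- paste0(post, strrep("-", 2L - nchar(post)))
  prev_aa <- substr(prot_seq, start - 1L, start - 1L)
  next_aa <- substr(prot_seq, end + 1L, end + 1L)
  obs <- observed %||% ref
  nterm <- start == 1L ||
    (prev_aa %in% c("K", "R") && substr(obs, 1L, 1L) != "P")
  cterm <- end == L ||
    (substr(obs, len, len) %in% c("K", "R") && next_aa != "P")
  type <- if (!is.null(observed) && observed != ref) "V"
          else if (n_blocks > 1L) "J" else "N"
  list(ref_peptide = ref, pre_aa = pre, post_aa = post,
       enzymatic_termini = as.integer(nterm) + as.integer(cterm),
       peptide_type = type, annotated = 0L)
}

#' Map a table of PSMs to genome coordinates
#'
#' For each PSM the peptide is located in the proteome by exact string
#' match (every occurrence yields a mapping; occurrences that resolve to
#' the same genomic locus through different proteins are merged). A PSM
#' whose peptide matches nowhere but that carries `protein` and `start`
#' fields is placed at those coordinates as a single-substitution variant
#' (peptide type V). PSMs with no mapping at all (decoys, typically)
#' become unmapped proBAM records and are absent from proBed.
#'
#' @param psms `peptrack_psms` data frame ([read_psm_tsv()] /
#'   [read_mztab_psm()] output).
#' @param transcripts named list of [transcript()] ([parse_gtf()] output).
#' @param genome [Biostrings::DNAStringSet].
#' @param compute_q estimate target-decoy q-values before mapping.
#' @param meta list: `genome_version`, `dataset_id` for the proBed fields.
#' @return list: `probam` (all records, one per mapping plus one per
#'   unmapped PSM), `probed` (mapped records only), `stats` (named counts:
#'   `n_psms`, `mapped`, `unmapped`, `multi_mapped`, `records`).
#' @export
map_psms <- function(psms, transcripts, genome, compute_q = TRUE,
                     meta = list()) {
  if (compute_q && any(!is.na(psms$score))) psms <- compute_qvalues(psms)
  ann <- translate_annotation(transcripts, genome)
  proteins <- ann$proteins; maps <- ann$maps

  probam_parts <- list(); probed_parts <- list()
  n_mapped <- 0L; n_multi <- 0L
  for (i in seq_len(nrow(psms))) {
    psm <- psms[i, ]
    pep <- psm$peptide
    len <- nchar(pep)
    mappings <- list(); contexts <- list(); keys <- character(0)
    for (pid in names(proteins)) {
      for (s in find_peptide_in_protein(proteins[[pid]], pep)) {
        mb <- tryCatch(protein_to_genome(maps[[pid]], s, len),
                       error = function(e) NULL)
        if (is.null(mb)) next
        key <- paste(mb$chrom, mb$strand,
                     paste(mb$blocks$start, mb$blocks$end, collapse = ";"))
        if (key %in% keys) next
        keys <- c(keys, key)
        ctx <- protein_context(proteins[[pid]], s, len, nrow(mb$blocks))
        ctx$protein <- pid
        mappings[[length(mappings) + 1L]] <- mb
        contexts[[length(contexts) + 1L]] <- ctx
      }
    }
    if (length(mappings) == 0 && !isTRUE(psm$decoy) &&
        !is.na(psm$protein) && !is.na(psm$start) &&
        psm$protein %in% names(proteins)) {
      # variant route: no exact match, but the input names the source locus
      prot <- proteins[[psm$protein]]
      if (psm$start + len - 1L <= nchar(prot)) {
        mb <- tryCatch(protein_to_genome(maps[[psm$protein]], psm$start, len),
                       error = function(e) NULL)
        if (!is.null(mb)) {
          ctx <- protein_context(prot, psm$start, len, nrow(mb$blocks),
                                 observed = pep)
          ctx$protein <- psm$protein
          mappings <- list(mb); contexts <- list(ctx)
        }
      }
    }
    rec <- psm_to_probam(psm, mappings, genome = genome, contexts = contexts,
                         meta = list(xl = 1L))
    probam_parts[[i]] <- rec
    if (length(mappings) > 0) {
      n_mapped <- n_mapped + 1L
      if (length(mappings) > 1) n_multi <- n_multi + 1L
      uniq <- if (length(mappings) == 1) "unique" else "not-unique"
      # proBed lines in the same (chrom, start) order as the proBAM records
      ord <- order(vapply(mappings, function(m) m$chrom, character(1)),
                   vapply(mappings, function(m) m$blocks$start[1], integer(1)))
      for (k in seq_along(ord)) {
        m <- mappings[[ord[k]]]
        psm_bed <- psm
        psm_bed$protein <- contexts[[ord[k]]]$protein
        probed_parts[[length(probed_parts) + 1L]] <-
          psm_to_probed(psm_bed, m,
                        meta = c(meta, list(uniqueness = uniq, ordinal = k)))
      }
    }
  }
  probam <- do.call(rbind, probam_parts)
  if (is.null(probam)) probam <- probam_template(0L)
  class(probam) <- c("peptrack_probam", "data.frame")
  probed <- do.call(rbind, probed_parts)
  if (is.null(probed)) probed <- probed_template(0L)
  class(probed) <- c("peptrack_probed", "data.frame")
  rownames(probam) <- rownames(probed) <- NULL
  list(probam = probam, probed = probed,
       stats = list(n_psms = nrow(psms), mapped = n_mapped,
                    unmapped = nrow(psms) - n_mapped,
                    multi_mapped = n_multi, records = nrow(probam)))
}
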