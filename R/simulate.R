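# Synthetic data generator: a toy genome, spliced gene models on both
# strands, the translated proteome, tryptic peptides, and simulated
# target/decoy PSMs. Every downstream module can be exercised against this
# ground truth without any external data.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defaults describe a small two-chromosome genome with eight multi-exon
#' genes (half on the minus strand, the last two sharing their first coding
#' exon so that shared peptides exist), tryptic digestion with up to one
#' missed cleavage, and 500 PSMs split evenly between targets and
#' reversed-peptide decoys whose scores are drawn from
#' Normal(40, 8) and Normal(25, 8) respectively.
#'
#' @param seed integer seed; every stochastic operation derives its stream
#'   deterministically from it.
#' @param n_chrom,chrom_len number and length (nt) of chromosomes.
#' @param n_genes number of genes (spread across chromosomes).
#' @param exon_count_range,intron_len_range integer ranges.
#' @param minus_strand_fraction fraction of genes on the minus strand.
#' @param protein_len_range protein lengths in amino acids.
#' @param overlapping_pair make the last two genes share their first coding
#'   exon (source of shared peptides).
#' @param enzyme digestion enzyme (only `"trypsin"` is implemented).
#' @param max_missed_cleavages maximum missed cleavages in the digest.
#' @param n_psms total simulated PSMs.
#' @param decoy_fraction fraction of PSMs that are decoys.
#' @param target_score_mean,target_score_sd,decoy_score_mean,decoy_score_sd
#'   score distribution parameters.
#' @param variant_fraction fraction of target PSMs carrying one substituted
#'   residue (single amino-acid variants; ground-truth peptide type V).
#' @param dataset_id dataset identifier written into the PSM table.
#' @return a `peptrack_sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_chrom = 2L, chrom_len = 30000L,
                       n_genes = 8L, exon_count_range = c(1L, 4L),
                       intron_len_range = c(50L, 400L),
                       minus_strand_fraction = 0.5,
                       protein_len_range = c(80L, 220L),
                       overlapping_pair = TRUE,
                       enzyme = "trypsin", max_missed_cleavages = 1L,
                       n_psms = 500L, decoy_fraction = 0.5,
                       target_score_mean = 40, target_score_sd = 8,
                       decoy_score_mean = 25, decoy_score_sd = 8,
                       variant_fraction = 0.05,
                       dataset_id = "SIMDS001") {
  cfg <- as.list(environment())
  stopifnot(cfg$n_chrom >= 1, cfg$chrom_len > 0, cfg$n_genes >= 1,
            cfg$n_psms >= 1, cfg$decoy_fraction >= 0, cfg$decoy_fraction <= 1,
            cfg$minus_strand_fraction >= 0, cfg$minus_strand_fraction <= 1,
            cfg$variant_fraction >= 0, cfg$variant_fraction <= 1)
  if (cfg$enzyme != "trypsin") {
    pt_stop("peptrack_config_error", "unsupported enzyme: %s", cfg$enzyme)
  }
  class(cfg) <- "peptrack_sim_config"
  cfg
}

#' Generate a random genome
#'
#' Uniform random A/C/G/T sequences, one per chromosome, named `chr1..chrN`.
#' Reproducible from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return [Biostrings::DNAStringSet].
#' @export
make_genome <- function(cfg) {
  set.seed(cfg$seed)
  seqs <- vapply(seq_len(cfg$n_chrom), function(i) {
    paste(sample(c("A", "C", "G", "T"), cfg$chrom_len, replace = TRUE),
          collapse = "")
  }, character(1))
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- paste0("chr", seq_len(cfg$n_chrom))
  g
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# no.init.codon: a leading TTG/CTG mid-protein is leucine, not an
# alternative initiator
translate_nt <- function(s) {
  as.character(Biostrings::translate(Biostrings::DNAString(s),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# split `total` into n parts, each a positive multiple-free length >= min_len
split_lengths <- function(total, n, min_len = 9L) {
  if (total < n * min_len) {
    pt_stop("peptrack_config_error",
            "cannot split %d nt into %d exons of >= %d nt", total, n, min_len)
  }
  if (n == 1L) return(as.integer(total))
  for (. in 1:200) {
    cuts <- sort(sample(seq(min_len, total - min_len), n - 1L))
    lens <- diff(c(0L, cuts, total))
    if (all(lens >= min_len)) return(as.integer(lens))
  }
  pt_stop("peptrack_config_error",
          "cannot split %d nt into %d exons of >= %d nt", total, n, min_len)
}

#' Generate gene models and the matching proteome
#'
#' Places non-overlapping multi-exon genes on the genome (the last two
#' genes optionally share their first coding exon, in frame, to create
#' shared peptides). For every gene the spliced CDS is rewritten in place so
#' that it begins with ATG, contains no internal stop codon, and ends with a
#' terminal TAA stop (the CDS features include the stop codon; downstream
#' CDS maps trim it against the genome). The proteome is the standard-code
#' translation of each spliced CDS minus the stop.
#'
#' @param genome [make_genome()] output (returned modified).
#' @param cfg a [sim_config()].
#' @return list: `genome` (edited [Biostrings::DNAStringSet]),
#'   `transcripts` (named list of [transcript()]), `proteins` (named
#'   character vector keyed by protein id).
#' @export
make_annotation <- function(genome, cfg) {
  set.seed(cfg$seed + 1L)
  n <- cfg$n_genes
  chrom_of <- paste0("chr", rep(seq_len(cfg$n_chrom), length.out = n))
  cursor <- stats::setNames(rep(200L, cfg$n_chrom), names(genome))
  transcripts <- list()
  proteins <- character(0)
  pair <- cfg$overlapping_pair && n >= 2L
  shared_exon <- NULL

  for (g in seq_len(n)) {
    gid <- paste0("g", g); tid <- paste0("t", g); pid <- paste0("p", g)
    in_pair <- pair && g >= n - 1L
    chrom <- if (in_pair) chrom_of[n - 1L] else chrom_of[g]
    strand <- if (in_pair) "+" else {
      if (stats::runif(1) < cfg$minus_strand_fraction) "-" else "+"
    }
    P <- sample(seq(cfg$protein_len_range[1], cfg$protein_len_range[2]), 1L)
    total <- 3L * (P + 1L)                       # CDS including stop codon
    n_ex <- sample(seq(cfg$exon_count_range[1], cfg$exon_count_range[2]), 1L)
    if (in_pair) n_ex <- max(2L, n_ex)

    if (in_pair && !is.null(shared_exon)) {
      # second member of the pair: reuse the shared first exon (in frame)
      first_len <- shared_exon$end - shared_exon$start
      n_rest <- max(1L, n_ex - 1L)
      if (total < first_len + 9L * n_rest) {
        # grow the CDS so the shared exon plus n_rest own exons fit
        total <- first_len + 9L * n_rest
        total <- total + (3L - total %% 3L) %% 3L
      }
      lens <- c(first_len, split_lengths(total - first_len, n_rest))
      starts <- integer(length(lens))
      starts[1] <- shared_exon$start
      at <- cursor[chrom]
      for (i in 2:length(lens)) {
        starts[i] <- at
        at <- at + lens[i] + sample(seq(cfg$intron_len_range[1],
                                        cfg$intron_len_range[2]), 1L)
      }
      cursor[chrom] <- at + 200L
    } else {
      lens <- split_lengths(total, n_ex)
      if (in_pair) {
        # first member: force an in-frame shared exon of >= 60 nt
        lens[1] <- max(60L, lens[1] - lens[1] %% 3L)
        lens[2:length(lens)] <- split_lengths(total - lens[1],
                                              length(lens) - 1L)
      }
      starts <- integer(length(lens))
      at <- cursor[chrom]
      for (i in seq_along(lens)) {
        starts[i] <- at
        at <- at + lens[i] + if (i < length(lens)) {
          sample(seq(cfg$intron_len_range[1], cfg$intron_len_range[2]), 1L)
        } else 0L
      }
      cursor[chrom] <- at + 200L
      if (in_pair) shared_exon <- list(start = starts[1],
                                       end = starts[1] + lens[1])
    }
    ends <- starts + lens
    if (max(ends) > Biostrings::width(genome[chrom])) {
      pt_stop("peptrack_config_error",
              "chromosome %s too short for %d genes", chrom, n)
    }
    segs <- data.frame(start = starts, end = ends)
    genome[[chrom]] <- fix_cds_in_genome(genome[[chrom]], segs, strand)
    spliced <- spliced_seq(genome[[chrom]], segs, strand)
    prot <- translate_nt(substr(spliced, 1L, nchar(spliced) - 3L))
    stopifnot(!grepl("\\*", prot), substr(prot, 1, 1) == "M")
    proteins[pid] <- prot
    transcripts[[tid]] <- transcript(tid, gid, chrom, strand,
                                     exons = segs, cds = segs,
                                     protein_id = pid)
  }
  list(genome = genome, transcripts = transcripts, proteins = proteins)
}

# spliced CDS sequence of ascending segments, in translation orientation
spliced_seq <- function(chr_seq, segs, strand) {
  s <- paste(vapply(seq_len(nrow(segs)), function(i) {
    as.character(Biostrings::subseq(chr_seq, segs$start[i] + 1L, segs$end[i]))
  }, character(1)), collapse = "")
  if (strand == "-") revcomp_chr(s) else s
}

# rewrite the genome under `segs` so the spliced CDS is ATG..(no stop)..TAA
fix_cds_in_genome <- function(chr_seq, segs, strand) {
  spliced <- spliced_seq(chr_seq, segs, strand)
  ncod <- nchar(spliced) / 3L
  codons <- substring(spliced, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  codons[1] <- "ATG"
  non_stop <- setdiff(names(Biostrings::GENETIC_CODE), STOP_CODONS)
  internal <- which(codons[-c(1L, ncod)] %in% STOP_CODONS) + 1L
  if (length(internal)) {
    codons[internal] <- sample(non_stop, length(internal), replace = TRUE)
  }
  codons[ncod] <- "TAA"
  fixed <- paste(codons, collapse = "")
  ascending <- if (strand == "-") revcomp_chr(fixed) else fixed
  at <- 1L
  for (i in seq_len(nrow(segs))) {
    len <- segs$end[i] - segs$start[i]
    Biostrings::subseq(chr_seq, segs$start[i] + 1L, segs$end[i]) <-
      Biostrings::DNAString(substr(ascending, at, at + len - 1L))
    at <- at + len
  }
  chr_seq
}

#' In-silico tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P; emits all
#' peptides with 0..`max_missed` internal missed-cleavage sites, together
#' with their 1-based start position and missed-cleavage count, filtered to
#' `len_range` amino acids.
#'
#' @param protein_seq amino-acid string.
#' @param enzyme only `"trypsin"`.
#' @param max_missed maximum internal missed cleavages.
#' @param len_range length filter (inclusive); widen to disable.
#' @return data frame `peptide`, `start`, `missed`.
#' @export
digest <- function(protein_seq, enzyme = "trypsin", max_missed = 0L,
                   len_range = c(6L, 40L)) {
  if (enzyme != "trypsin") {
    pt_stop("peptrack_config_error", "unsupported enzyme: %s", enzyme)
  }
  aa <- strsplit(protein_seq, "")[[1]]
  L <- length(aa)
  sites <- which(aa[-L] %in% c("K", "R") & aa[-1] != "P")
  bounds <- c(0L, sites, L)
  n_frag <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(n_frag)) {
    for (mc in 0:max_missed) {
      j <- i + mc
      if (j > n_frag) break
      s <- bounds[i] + 1L; e <- bounds[j + 1L]
      len <- e - s + 1L
      if (len < len_range[1] || len > len_range[2]) next
      rows[[length(rows) + 1L]] <-
        data.frame(peptide = paste(aa[s:e], collapse = ""),
                   start = s, missed = mc, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(peptide = character(0), start = integer(0),
                      missed = integer(0))
  }
  rownames(out) <- NULL
  out
}

# reverse a peptide keeping the C-terminal residue (K/R endpoint preserved)
reverse_decoy <- function(pep) {
  L <- nchar(pep)
  if (L < 2) return(pep)
  paste0(paste(rev(strsplit(substr(pep, 1L, L - 1L), "")[[1]]), collapse = ""),
         substr(pep, L, L))
}

#' Simulate target and decoy PSMs from a proteome
#'
#' Samples tryptic peptides, assigns charge 2 or 3, draws scores from the
#' configured target/decoy normal distributions, perturbs the calculated
#' m/z with Normal(0, 0.005) measurement noise, occasionally adds a
#' methionine oxidation, substitutes one residue in a `variant_fraction` of
#' targets (peptide type V, still placed at its source coordinates), and
#' reverses peptides for decoys. Reproducible from `cfg$seed`.
#'
#' @param proteins named character vector (protein id -> sequence).
#' @param cfg a [sim_config()].
#' @return list: `psms` (a `peptrack_psms` data frame in the tabular PSM
#'   schema) and `truth` (data frame `spectrum_id`, `peptide`,
#'   `source_peptide`, `protein`, `start_aa`, `is_variant`, `is_decoy`).
#' @export
simulate_psms <- function(proteins, cfg) {
  set.seed(cfg$seed + 2L)
  proteins <- stats::setNames(as.character(proteins), names(proteins))
  pool <- do.call(rbind, lapply(names(proteins), function(pid) {
    d <- digest(proteins[[pid]], cfg$enzyme, cfg$max_missed_cleavages)
    if (nrow(d)) d$protein <- pid
    d
  }))
  if (is.null(pool) || nrow(pool) == 0) {
    pt_stop("peptrack_config_error", "digestion produced no peptides")
  }
  n_decoy <- round(cfg$n_psms * cfg$decoy_fraction)
  n_target <- cfg$n_psms - n_decoy
  idx <- sample(nrow(pool), cfg$n_psms, replace = TRUE)
  is_decoy <- rep(c(FALSE, TRUE), c(n_target, n_decoy))

  src_pep <- pool$peptide[idx]
  obs_pep <- src_pep
  is_variant <- !is_decoy & stats::runif(cfg$n_psms) < cfg$variant_fraction
  aa20 <- names(AA_MONO)
  for (i in which(is_variant)) {
    L <- nchar(obs_pep[i])
    if (L < 4) { is_variant[i] <- FALSE; next }
    p <- sample(2:(L - 1L), 1L)
    orig <- substr(obs_pep[i], p, p)
    repl <- sample(setdiff(aa20, c(orig, "P", "K", "R")), 1L)
    substr(obs_pep[i], p, p) <- repl
  }
  for (i in which(is_decoy)) obs_pep[i] <- reverse_decoy(obs_pep[i])

  score <- round(ifelse(is_decoy,
                        stats::rnorm(cfg$n_psms, cfg$decoy_score_mean,
                                     cfg$decoy_score_sd),
                        stats::rnorm(cfg$n_psms, cfg$target_score_mean,
                                     cfg$target_score_sd)), 4)
  charge <- sample(2:3, cfg$n_psms, replace = TRUE)
  mods <- vapply(obs_pep, function(p) {
    m <- regexpr("M", p, fixed = TRUE)
    if (m > 0 && stats::runif(1) < 0.1) sprintf("%d-UNIMOD:35", m) else "."
  }, character(1), USE.NAMES = FALSE)
  mz <- round(vapply(seq_len(cfg$n_psms), function(i) {
    calc_mz(obs_pep[i], mods[i], charge[i])
  }, numeric(1)) + stats::rnorm(cfg$n_psms, 0, 0.005), 6)

  spectrum_id <- sprintf("scan=%05d", seq_len(cfg$n_psms))
  psms <- data.frame(
    spectrum_id = spectrum_id,
    peptide = obs_pep,
    charge = charge,
    exp_mz = mz,
    score = score,
    qvalue = NA_real_,
    rank = 1L,
    mods = mods,
    protein = ifelse(is_decoy, paste0("DECOY_", pool$protein[idx]),
                     pool$protein[idx]),
    start = ifelse(is_decoy, NA_integer_, pool$start[idx]),
    missed_cleavages = pool$missed[idx],
    decoy = is_decoy,
    dataset_id = cfg$dataset_id,
    uri = sprintf("file://sim/run1.mzML#scan=%d", seq_len(cfg$n_psms)),
    stringsAsFactors = FALSE
  )
  class(psms) <- c("peptrack_psms", "data.frame")
  truth <- data.frame(
    spectrum_id = spectrum_id,
    peptide = obs_pep,
    source_peptide = src_pep,
    protein = pool$protein[idx],
    start_aa = pool$start[idx],
    is_variant = is_variant,
    is_decoy = is_decoy,
    stringsAsFactors = FALSE
  )
  list(psms = psms, truth = truth)
}

#' Write gene models as GTF
#'
#' One `exon` and one `CDS` feature per interval, 1-based inclusive
#' coordinates, `gene_id`/`transcript_id`/`protein_id` attributes.
#'
#' @param transcripts list of [transcript()].
#' @param path output file.
#' @export
write_gtf <- function(transcripts, path) {
  lines <- unlist(lapply(transcripts, function(t) {
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s";%s', t$gene_id,
                        t$transcript_id,
                        if (!is.na(t$protein_id))
                          sprintf(' protein_id "%s";', t$protein_id) else "")
    c(
      sprintf("%s\tpeptrack\texon\t%d\t%d\t.\t%s\t.\t%s",
              t$chrom, t$exons$start + 1L, t$exons$end, t$strand, attr_str),
      if (nrow(t$cds))
        sprintf("%s\tpeptrack\tCDS\t%d\t%d\t.\t%s\t.\t%s",
                t$chrom, t$cds$start + 1L, t$cds$end, t$strand, attr_str)
    )
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Generate a complete synthetic dataset
#'
#' Runs [make_genome()], [make_annotation()] and [simulate_psms()] and,
#' when `outdir` is given, writes `genome.fasta`, `annotation.gtf`,
#' `proteins.fasta`, `psms.tsv` and `ground_truth.tsv`. Identical seeds
#' give identical directory contents.
#'
#' @param cfg a [sim_config()].
#' @param outdir optional output directory (created if missing).
#' @return list: `genome`, `transcripts`, `proteins`, `psms`, `truth`,
#'   `paths` (when written).
#' @export
simulate_dataset <- function(cfg = sim_config(), outdir = NULL) {
  genome <- make_genome(cfg)
  ann <- make_annotation(genome, cfg)
  sim <- simulate_psms(ann$proteins, cfg)
  paths <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(
      genome = file.path(outdir, "genome.fasta"),
      gtf = file.path(outdir, "annotation.gtf"),
      proteins = file.path(outdir, "proteins.fasta"),
      psms = file.path(outdir, "psms.tsv"),
      truth = file.path(outdir, "ground_truth.tsv")
    )
    Biostrings::writeXStringSet(ann$genome, paths$genome)
    write_gtf(ann$transcripts, paths$gtf)
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(ann$proteins), paths$proteins)
    write_psm_tsv(sim$psms, paths$psms)
    utils::write.table(sim$truth, paths$truth, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  list(genome = ann$genome, transcripts = ann$transcripts,
       proteins = ann$proteins, psms = sim$psms, truth = sim$truth,
       paths = paths)
}
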