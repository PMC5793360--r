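# Interconversion, aggregation, FDR filtering, gene inference, counting.

test_that("probam_to_probed carries tags into the 13 proteomics fields and drops unmapped", {
  mp <- fixture_map()
  rec <- mp$probam
  mapped <- rec[rec$rname != "*", ]
  suppressMessages(bed <- probam_to_probed(rec))
  expect_equal(nrow(bed), nrow(mapped))
  expect_equal(attr(bed, "dropped_unmapped"), sum(rec$rname == "*"))
  expect_equal(bed$fdr, ifelse(mapped$XQ == -1, NA_real_, mapped$XQ))
  expect_equal(bed$peptideSequence, mapped$XP)
  expect_equal(bed$charge, mapped$XC)
  # block geometry identical to the direct proBed encoding
  expect_equal(bed$blockSizes, mp$probed$blockSizes)
  expect_equal(bed$chromStart, mp$probed$chromStart)
})

test_that("probed_to_probam reconstructs coordinates and CIGAR from BED12 blocks", {
  bed <- peptrack:::probed_template(1L)
  bed$chrom <- "chr1"; bed$chromStart <- 1090L; bed$chromEnd <- 1220L
  bed$name <- "p1_PEPTIDEKRR_1"; bed$score <- 1000L; bed$strand <- "+"
  bed$thickStart <- 1090L; bed$thickEnd <- 1220L; bed$itemRgb <- "0"
  bed$blockCount <- 2L; bed$blockSizes <- "10,20"; bed$blockStarts <- "0,110"
  bed$proteinAccession <- "p1"; bed$peptideSequence <- "PEPTIDEKRR"
  bed$uniqueness <- "unique"; bed$psmScore <- 55; bed$fdr <- 0.01
  bed$charge <- 2L
  bam <- probed_to_probam(bed)
  expect_equal(bam$pos, 1091L)
  expect_equal(bam$cigar, "10M100N20M")
  expect_equal(bam$XP, "PEPTIDEKRR")
  expect_equal(bam$NH, 1L)
  expect_equal(bam$seq, "*")     # no genome supplied
})

test_that("probam -> probed -> probam preserves the shared field set exactly", {
  mp <- fixture_map(); sim <- fixture_sim()
  rec <- mp$probam[mp$probam$rname != "*", ]
  suppressMessages(bed <- probam_to_probed(rec))
  back <- probed_to_probam(bed, genome = sim$genome)
  for (col in c("rname", "pos", "cigar", "XP", "XC", "XS", "XQ", "YP")) {
    expect_identical(back[[col]], rec[[col]])
  }
  expect_identical(back$seq, rec$seq)    # genome-backed SEQ reconstruction
})

test_that("tags without a proBed counterpart come back as their null sentinels", {
  mp <- fixture_map(); sim <- fixture_sim()
  rec <- mp$probam[mp$probam$rname != "*", ][1:20, ]
  suppressMessages(bed <- probam_to_probed(rec))
  back <- probed_to_probam(bed, genome = sim$genome)
  for (tag in c("XL", "XN", "XT", "XE", "XA")) {
    expect_true(all(back[[tag]] == -1L), label = paste(tag, "sentinel"))
  }
  for (tag in c("XI", "XB")) {
    expect_true(all(back[[tag]] == -1), label = paste(tag, "sentinel"))
  }
  for (tag in c("XR", "YB", "YA", "XF")) {
    expect_true(all(back[[tag]] == "*"), label = paste(tag, "sentinel"))
  }
})

test_that("aggregate_to_peptides groups by peptide and locus with best-score representative", {
  mk <- function(id, score, start = 300L, pep = "PEPTIDEK", chrom = "chr1") {
    psm <- list(spectrum_id = id, peptide = pep, charge = 2L, score = score,
                qvalue = 0.01, mods = ".", decoy = FALSE)
    psm_to_probam(psm, list(mapped_blocks(chrom, "+",
      data.frame(start = start, end = start + 3L * nchar(pep)))))
  }
  rec <- rbind(mk("s1", 30), mk("s2", 50), mk("s3", 40),
               mk("s4", 20, start = 900L), mk("s5", 60, pep = "ELVISLIVK"))
  pep <- aggregate_to_peptides(rec)
  expect_equal(nrow(pep), 3)     # same peptide at 2 loci + a second peptide
  g <- pep[pep$XP == "PEPTIDEK" & pep$pos == 301L, ]
  expect_equal(g$psm_count, 3L)
  expect_equal(g$best_score, 50)
  expect_equal(sum(pep$psm_count), nrow(rec))
})

test_that("total psm_count equals the number of mapped records on the fixture", {
  mp <- fixture_map()
  pep <- aggregate_to_peptides(mp$probam)
  n_mapped <- sum(mp$probam$rname != "*")
  expect_equal(sum(pep$psm_count), n_mapped)
  expect_equal(attr(pep, "dropped_unmapped"), nrow(mp$probam) - n_mapped)
})

test_that("filter_by_fdr keeps records at or below the threshold and is monotone", {
  df <- data.frame(qvalue = c(0.001, 0.02, 0.09), x = 1:3)
  expect_equal(nrow(filter_by_fdr(df, 0.05)), 2)
  expect_equal(nrow(filter_by_fdr(df, 1.0)), 3)
  expect_equal(nrow(filter_by_fdr(df, 0)), 0)
  df2 <- data.frame(qvalue = c(0, 0.5, NA))
  kept <- filter_by_fdr(df2, 0.2)
  expect_equal(nrow(kept), 1)
  expect_equal(attr(kept, "dropped_unset"), 1L)

  mp <- fixture_map()
  thresholds <- c(0, 0.01, 0.05, 0.2, 1)
  kept_sets <- lapply(thresholds, function(t) {
    filter_by_fdr(mp$probam, t)$qname
  })
  for (i in seq_along(thresholds)[-1]) {
    expect_true(all(kept_sets[[i - 1]] %in% kept_sets[[i]]))
  }
})

test_that("infer_genes matches a brute-force containment oracle and finds shared peptides", {
  mp <- fixture_map(); sim <- fixture_sim()
  rec <- mp$probam[mp$probam$rname != "*", ]
  asg <- infer_genes(rec, sim$transcripts)
  # brute-force oracle over every (record, transcript) pair
  for (i in seq_len(min(nrow(rec), 150))) {
    blocks <- cigar_to_blocks(rec$cigar[i], rec$pos[i] - 1L)
    strand <- if (bitwAnd(rec$flag[i], 16L) != 0L) "-" else "+"
    hits <- character(0)
    for (t in sim$transcripts) {
      if (t$chrom != rec$rname[i] || t$strand != strand) next
      ok <- all(vapply(seq_len(nrow(blocks)), function(k) {
        covered <- blocks$start[k]:(blocks$end[k] - 1L)
        all(vapply(covered, function(p) {
          any(t$cds$start <= p & p < t$cds$end)
        }, logical(1)))
      }, logical(1)))
      if (ok) hits <- c(hits, t$gene_id)
    }
    want <- if (length(hits)) paste(sort(unique(hits)), collapse = ",") else "."
    expect_equal(asg$genes[i], want)
  }
  expect_true(any(asg$status == "shared"))   # the overlapping gene pair
  expect_true(all(asg$n_genes[asg$status == "shared"] >= 2))
})

test_that("intergenic records get no gene assignment", {
  psm <- list(spectrum_id = "sX", peptide = "PEPTIDEK", charge = 2L,
              score = 10, qvalue = 0.5, mods = ".", decoy = FALSE)
  rec <- psm_to_probam(psm, list(mapped_blocks("chr1", "+",
    data.frame(start = 10L, end = 34L))))   # upstream of every gene
  sim <- fixture_sim()
  asg <- infer_genes(rec, sim$transcripts)
  expect_equal(asg$status, "none")
  expect_equal(asg$genes, ".")
})

test_that("spectral counts use unique assignments only", {
  # two genes sharing one peptide; gene A also has two unique peptides
  mk_t <- function(tid, gid, s, e) {
    transcript(tid, gid, "chrC", "+", exons = data.frame(start = s, end = e),
               cds = data.frame(start = s, end = e), protein_id = tid)
  }
  tA <- mk_t("tA", "gA", 0L, 300L)
  tB <- mk_t("tB", "gB", 240L, 540L)
  mk_rec <- function(id, pep, start) {
    psm <- list(spectrum_id = id, peptide = pep, charge = 2L, score = 40,
                qvalue = 0.01, mods = ".", decoy = FALSE)
    psm_to_probam(psm, list(mapped_blocks("chrC", "+",
      data.frame(start = start, end = start + 3L * nchar(pep)))))
  }
  rec <- rbind(
    mk_rec("u1", "AAAAAAAK", 0L), mk_rec("u2", "AAAAAAAK", 0L),  # unique gA
    mk_rec("u3", "CCCCCCCK", 90L),                               # unique gA
    mk_rec("sh1", "DDDDDDDK", 250L)                              # in gA and gB
  )
  counts <- spectral_counts(rec, list(tA, tB))
  gA <- counts[counts$gene_id == "gA", ]
  gB <- counts[counts$gene_id == "gB", ]
  expect_equal(gA$spectral_count, 3L)
  expect_equal(gA$unique_peptide_count, 2L)
  expect_equal(gA$shared_peptide_count, 1L)
  expect_equal(gB$spectral_count, 0L)
  expect_equal(gB$unique_peptide_count, 0L)
  expect_equal(gB$shared_peptide_count, 1L)
  expect_true(all(counts$spectral_count >= counts$unique_peptide_count))

  empty <- spectral_counts(aggregate_to_peptides(rec)[0, ], list(tA, tB))
  expect_equal(nrow(empty), 0)
})
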