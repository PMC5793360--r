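# proBAM records: CIGAR construction, flags, sequence extraction, the
# 21-tag payload, round-trip I/O and validation.

test_that("make_cigar alternates M blocks with N gaps in genomic order", {
  expect_equal(make_cigar(data.frame(start = 1000, end = 1030)), "30M")
  expect_equal(make_cigar(data.frame(start = c(1090, 1200),
                                     end = c(1100, 1220))), "10M100N20M")
  expect_equal(make_cigar(data.frame(start = c(0, 10, 20),
                                     end = c(3, 13, 23))), "3M7N3M7N3M")
  expect_s3_class(tryCatch(make_cigar(data.frame(start = integer(0),
                                                 end = integer(0))),
                  error = function(e) e), "peptrack_cigar_error")
})

test_that("cigar_to_blocks inverts make_cigar", {
  b <- data.frame(start = c(1090L, 1200L, 1500L), end = c(1100L, 1220L, 1530L))
  expect_equal(cigar_to_blocks(make_cigar(b), 1090L), b)
})

test_that("compute_flag encodes strand, mapping status and primariness", {
  expect_equal(compute_flag("+", mapped = TRUE, primary = TRUE), 0L)
  expect_equal(compute_flag("-", mapped = TRUE, primary = TRUE), 16L)
  expect_equal(compute_flag("+", mapped = FALSE), 4L)
  expect_equal(compute_flag("-", mapped = TRUE, primary = FALSE), 272L)
})

test_that("extract_seq returns forward-strand sequence whose strand-adjusted translation is the peptide", {
  sim <- fixture_sim()
  maps <- lapply(sim$transcripts, build_cds_map, genome = sim$genome)
  for (tid in names(sim$transcripts)) {
    t <- sim$transcripts[[tid]]
    prot <- sim$proteins[[t$protein_id]]
    mb <- protein_to_genome(maps[[tid]], 3, 8)
    s <- extract_seq(sim$genome, mb)
    expect_equal(nchar(s), 24L)
    flag <- compute_flag(t$strand)
    expect_equal(oracle_translate_seq(s, flag), substr(prot, 3, 10))
  }
  # blocks beyond the chromosome end are rejected
  mb_bad <- mapped_blocks("chr1", "+", data.frame(start = 0, end = 10 +
    Biostrings::width(sim$genome)[1]))
  expect_s3_class(tryCatch(extract_seq(sim$genome, mb_bad),
                           error = function(e) e), "peptrack_range_error")
})

test_that("psm_to_probam emits one record per mapping with NH and primary flags", {
  psm <- list(spectrum_id = "s1", peptide = "PEPTIDEK", charge = 2L,
              exp_mz = NA_real_, score = 31.5, qvalue = 0.01, rank = 1L,
              mods = ".", protein = "p1", decoy = FALSE)
  m1 <- mapped_blocks("chr1", "+", data.frame(start = 300, end = 324))
  m2 <- mapped_blocks("chr2", "-", data.frame(start = c(100, 200),
                                              end = c(110, 214)))
  one <- psm_to_probam(psm, list(m1))
  expect_equal(nrow(one), 1)
  expect_equal(one$flag, 0L)
  expect_equal(one$NH, 1L)
  expect_equal(one$XO, "unique")

  two <- psm_to_probam(psm, list(m2, m1))   # order should not matter
  expect_equal(nrow(two), 2)
  expect_equal(sum(bitwAnd(two$flag, 256L) == 0L), 1)  # exactly one primary
  expect_equal(two$NH, c(2L, 2L))
  expect_equal(two$rname, c("chr1", "chr2"))           # (chrom, pos) order

  none <- psm_to_probam(psm, list())
  expect_equal(none$flag, 4L)
  expect_equal(none$rname, "*")
  expect_equal(none$pos, 0L)
  expect_equal(none$cigar, "*")
  expect_equal(none$seq, "*")
})

test_that("every record carries exactly the 21 tags in canonical order with typed null sentinels", {
  psm <- list(spectrum_id = "s1", peptide = "ELVISLIVESK", charge = 3L,
              exp_mz = 500.1, score = 44.0, qvalue = 0.002, rank = 1L,
              mods = "1-UNIMOD:1", protein = "p9", decoy = FALSE,
              uri = "file://x.mzML#1")
  m <- mapped_blocks("chr1", "+", data.frame(start = c(10, 50),
                                             end = c(25, 68)))
  rec <- psm_to_probam(psm, list(m))
  tags <- emit_tags(rec[1, ])
  expect_length(tags, 21)
  expect_equal(sub(":.*", "", tags),
               c("NH", "XO", "XL", "XP", "YP", "XF", "XI", "XB", "XR", "YB",
                 "YA", "XS", "XQ", "XC", "XA", "XM", "XN", "XT", "XE", "XG",
                 "XU"))
  # intensity is unknown -> sentinel, but the tag count stays 21
  expect_true("XI:f:-1" %in% tags)
  expect_true("XG:A:J" %in% tags)      # two blocks -> junction peptide

  decoy <- psm_to_probam(modifyList(psm, list(decoy = TRUE)), list(m))
  expect_equal(decoy$XG, "D")

  unmapped <- psm_to_probam(psm, list())
  tags_u <- emit_tags(unmapped[1, ])
  expect_length(tags_u, 21)
  expect_true("XR:Z:*" %in% tags_u)
  expect_true("XT:i:-1" %in% tags_u)
})

test_that("write_probam / read_probam round-trips records exactly", {
  mp <- fixture_map()
  sim <- fixture_sim()
  rec <- head(mp$probam, 100)
  path <- tempfile(fileext = ".sam")
  write_probam(rec, path, seqlengths = sim$genome)
  back <- read_probam(path)
  expect_equal(back, rec, ignore_attr = "header")

  hdr <- attr(back, "header")
  sq <- hdr[grepl("^@SQ\t", hdr)]
  expect_length(sq, length(sim$genome))
  expect_equal(as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq)),
               unname(Biostrings::width(sim$genome)))

  # writing a second time from the re-read records is byte-identical
  path2 <- tempfile(fileext = ".sam")
  write_probam(back, path2, seqlengths = sim$genome)
  expect_identical(readLines(path), readLines(path2))
})

test_that("records on undeclared chromosomes are rejected", {
  psm <- list(spectrum_id = "s", peptide = "PEPTIDEK", charge = 2L,
              score = 1, qvalue = NA, mods = ".", decoy = FALSE)
  m <- mapped_blocks("chrZZ", "+", data.frame(start = 0, end = 24))
  rec <- psm_to_probam(psm, list(m))
  expect_s3_class(tryCatch(
    write_probam(rec, tempfile(), seqlengths = c(chr1 = 1000L)),
    error = function(e) e), "peptrack_header_error")
})

test_that("coordinate sorting is idempotent and groups by (rname, pos)", {
  mp <- fixture_map()
  s1 <- sort_probam(mp$probam)
  expect_identical(s1, sort_probam(s1))
  mapped <- s1[s1$rname != "*", ]
  key <- order(mapped$rname, mapped$pos, method = "radix")
  expect_identical(key, seq_len(nrow(mapped)))
  expect_true(all(which(s1$rname == "*") > nrow(mapped)))
})

test_that("validate_probam accepts the fixture file and flags inconsistencies", {
  mp <- fixture_map(); sim <- fixture_sim()
  path <- tempfile(fileext = ".sam")
  write_probam(mp$probam, path, seqlengths = sim$genome)
  expect_length(validate_probam(path), 0)

  lines <- readLines(path)
  i <- which(!grepl("^@", lines))[1]
  f <- strsplit(lines[i], "\t")[[1]]
  pep_len <- nchar(sub("XP:Z:", "", f[grepl("^XP:Z:", f)]))
  f[6] <- sprintf("%dM", 3 * pep_len - 1)   # off-by-one CIGAR
  bad <- lines; bad[i] <- paste(f, collapse = "\t")
  writeLines(bad, path)
  expect_match(validate_probam(path), "cigar/peptide length mismatch",
               all = FALSE)

  f[6] <- sprintf("%dM", 3 * pep_len); f[4] <- "0"   # mapped but pos 0
  bad[i] <- paste(f, collapse = "\t")
  writeLines(bad, path)
  expect_match(validate_probam(path), "pos", all = FALSE)
})
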