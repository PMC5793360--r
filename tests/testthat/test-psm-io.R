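# PSM I/O: mass arithmetic, TSV and mzTab readers, q-value estimation.

test_that("calc_mz matches independent monoisotopic sums", {
  # independent oracle: residue-by-residue sum from the published table
  # P+E+P+T+I+D+E = 781.34938; +water, +2 protons, /2
  expect_equal(calc_mz("PEPTIDE", NULL, 2L), 400.68725, tolerance = 1e-5)
  # G: 57.02146 + 18.010565 + 1.007276 = 76.0393
  expect_equal(calc_mz("G", NULL, 1L), 76.0393, tolerance = 1e-4)
  # a zero-mass modification leaves m/z unchanged
  mods0 <- data.frame(position = 1L, accession = "X:0", mass_delta = 0)
  expect_identical(calc_mz("PEPTIDE", mods0, 2L), calc_mz("PEPTIDE", NULL, 2L))
  # oxidation shifts by 15.994915 / z
  expect_equal(calc_mz("MK", "1-UNIMOD:35", 2L) - calc_mz("MK", NULL, 2L),
               15.994915 / 2, tolerance = 1e-9)
  err <- tryCatch(calc_mz("PEPB", NULL, 2L), error = function(e) e)
  expect_s3_class(err, "peptrack_residue_error")
  expect_match(conditionMessage(err), "B")
})

test_that("neutral mass from calc_mz is charge-invariant", {
  for (pep in c("PEPTIDER", "GASPVTK", "WWWHHH")) {
    masses <- vapply(1:4, function(z) calc_mz(pep, NULL, z) * z - z * 1.007276,
                     numeric(1))
    expect_equal(max(masses) - min(masses), 0, tolerance = 1e-9)
    expect_true(all(diff(vapply(1:4, function(z) calc_mz(pep, NULL, z),
                                numeric(1))) < 0))
  }
})

test_that("read_psm_tsv parses the schema, nulls and modifications", {
  tsv <- tempfile(fileext = ".tsv")
  hdr <- paste(c("spectrum_id", "peptide", "charge", "exp_mz", "score",
                 "rank", "mods", "protein", "start", "missed_cleavages",
                 "decoy", "dataset_id", "uri"), collapse = "\t")
  writeLines(c(hdr,
               "s1\tPEPTIDEK\t2\t450.1\t33.5\t1\t.\tp1\t4\t0\t0\tDS\t.",
               "s2\tMKPEPR\t3\t300.2\t21.0\t1\t3-UNIMOD:35\t.\t.\t.\t1\t.\t."),
             tsv)
  psms <- read_psm_tsv(tsv)
  expect_equal(nrow(psms), 2)
  expect_equal(nrow(parse_mods(psms$mods[1])), 0)
  m <- parse_mods(psms$mods[2])
  expect_equal(m$position, 3L)
  expect_equal(m$accession, "UNIMOD:35")
  expect_true(is.na(psms$protein[2]))
  expect_true(psms$decoy[2])

  # charge 0 violates the schema
  writeLines(c(hdr, "s1\tPEP\t0\t.\t.\t1\t.\t.\t.\t.\t0\t.\t."), tsv)
  expect_s3_class(tryCatch(read_psm_tsv(tsv), error = function(e) e),
                  "peptrack_schema_error")

  # a missing mandatory column is a schema error
  writeLines(c("spectrum_id\tpeptide", "s1\tPEP"), tsv)
  expect_s3_class(tryCatch(read_psm_tsv(tsv), error = function(e) e),
                  "peptrack_schema_error")
})

test_that("write_psm_tsv / read_psm_tsv round-trips the simulator output losslessly", {
  sim <- fixture_sim()
  path <- tempfile(fileext = ".tsv")
  write_psm_tsv(sim$psms, path)
  back <- read_psm_tsv(path)
  expect_equal(back, sim$psms)
})

test_that("read_mztab_psm maps the PSM section onto the PSM table", {
  mztab <- tempfile(fileext = ".mztab")
  psh <- paste(c("PSH", "sequence", "PSM_ID", "accession", "unique",
                 "database", "charge", "exp_mass_to_charge",
                 "search_engine_score[1]", "modifications", "spectra_ref",
                 "start"), collapse = "\t")
  writeLines(c(
    "MTD\tmzTab-version\t1.0",
    psh,
    paste(c("PSM", "ELVISK", "1", "p1", "1", "db", "2", "350.5", "44.2",
            "null", "ms_run[1]:scan=1", "10"), collapse = "\t"),
    paste(c("PSM", "PEPMTIDER", "2", "p2", "1", "db", "3", "361.1", "12.0",
            "4-UNIMOD:35", "ms_run[1]:scan=2", "3"), collapse = "\t")
  ), mztab)
  psms <- read_mztab_psm(mztab)
  expect_equal(nrow(psms), 2)
  expect_equal(psms$peptide, c("ELVISK", "PEPMTIDER"))
  expect_equal(psms$charge, c(2L, 3L))
  expect_equal(psms$spectrum_id[1], "ms_run[1]:scan=1")
  expect_equal(nrow(parse_mods(psms$mods[1])), 0)   # mzTab null -> none
  expect_equal(parse_mods(psms$mods[2])$position, 4L)
  expect_equal(psms$start, c(10L, 3L))

  # a PSM line shorter than the PSH header is a row error
  writeLines(c(psh, "PSM\tELVISK\t1"), mztab)
  expect_s3_class(tryCatch(read_mztab_psm(mztab), error = function(e) e),
                  "peptrack_format_error")

  # no PSH line at all is a format error
  writeLines("MTD\tmzTab-version\t1.0", mztab)
  expect_s3_class(tryCatch(read_mztab_psm(mztab), error = function(e) e),
                  "peptrack_format_error")
})

test_that("compute_qvalues reproduces brute-force target-decoy q-values", {
  psms <- data.frame(score = c(50, 40, 30, 45, 20),
                     decoy = c(FALSE, FALSE, FALSE, TRUE, TRUE))
  q <- compute_qvalues(psms)$qvalue
  expect_equal(q[1:3], c(0, 1/3, 1/3))
  expect_true(all(is.na(q[4:5])))

  # zero decoys -> all zero
  psms2 <- data.frame(score = c(10, 20, 30), decoy = FALSE)
  expect_equal(compute_qvalues(psms2)$qvalue, c(0, 0, 0))

  # one target and one decoy at the same score share the threshold: q = 1
  psms3 <- data.frame(score = c(5, 5), decoy = c(FALSE, TRUE))
  expect_equal(compute_qvalues(psms3)$qvalue[1], 1)

  expect_s3_class(tryCatch(
    compute_qvalues(data.frame(score = 1, decoy = TRUE)),
    error = function(e) e), "peptrack_fdr_error")
})

test_that("q-values are monotone non-increasing in score and within [0,1]", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(5:80, 1)
    psms <- data.frame(score = round(rnorm(n, 30, 10), 2),
                       decoy = runif(n) < 0.4)
    if (!any(!psms$decoy)) psms$decoy[1] <- FALSE
    q <- compute_qvalues(psms)
    tq <- q[!q$decoy, ]
    tq <- tq[order(tq$score), ]
    expect_true(all(diff(tq$qvalue) <= 1e-12))
    expect_true(all(tq$qvalue >= 0 & tq$qvalue <= 1))
  }
})
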