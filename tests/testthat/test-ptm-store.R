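test_that("the worked-example site table parses verbatim", {
  recs <- table2_records()
  expect_s3_class(recs, "ptm_records")
  expect_equal(nrow(recs), 46L)
  expect_equal(as.list(table(recs$accession)),
               list(O00194 = 1L, O43592 = 7L, P07996 = 17L, P17900 = 9L,
                    P25786 = 12L))
  first <- recs[1, ]
  expect_equal(first$modification, "N-acetylthreonine")
  expect_equal(first$position, 2L)
  expect_equal(first$window, "MTDGDY")
  # cross-link partner qualifiers survive parsing untouched
  expect_true(any(grepl("interchain with G-Cter in ubiquitin",
                        recs$modification, fixed = TRUE)))
})

test_that("an empty flat file with a header yields an empty collection", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("accession", "modification", "position", "window",
                     "sources", "pubmed_ids", "asa"), collapse = "\t"), path)
  recs <- read_ptm_flatfile(path)
  expect_equal(nrow(recs), 0L)
})

test_that("rows violating hard invariants are set aside, not silently dropped", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tmodification\tposition\twindow",
               "P12345\tPhosphoserine\t14\tVTVWSPQGR",
               "P12345\tPhosphoserine\tfourteen\tVTVWSPQGR",
               "P12345\tPhosphoserine\t0\tVTVWSPQGR",
               "P12345\tPhosphoserine\t14\tvtvws"), path)
  expect_warning(recs <- read_ptm_flatfile(path), "set aside")
  expect_equal(nrow(recs), 1L)
  errs <- attr(recs, "errors")
  expect_equal(errs$row, c(2L, 3L, 4L))
  expect_match(errs$message[1], "position")
  expect_match(errs$message[3], "amino-acid")
})

test_that("unknown source labels warn but are kept verbatim", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("accession\tmodification\tposition\twindow\tsources",
               "P12345\tPhosphoserine\t14\tVTVWSPQGR\tUniProt;MysteryDB"),
             path)
  expect_warning(recs <- read_ptm_flatfile(path), "MysteryDB")
  expect_equal(recs$sources[[1]], c("UniProt", "MysteryDB"))
})

test_that("expected_window implements the truncated 9-mer convention", {
  expect_equal(expected_window("MTDGDYDYLIK", 2), "MTDGDY")
  expect_equal(expected_window("MDEQALLSSPT", 1), "MDEQA")
  expect_equal(expected_window("ACDEFGHIK", 5), "ACDEFGHIK")  # whole 9-mer
  expect_error(expected_window("ACDEF", 6), "outside")
  expect_error(expected_window("ACDEF", 0), "outside")

  set.seed(3)
  for (i in 1:50) {
    len <- sample(5:60, 1)
    s <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
                      replace = TRUE), collapse = "")
    pos <- sample(len, 1)
    w <- expected_window(s, pos)
    expect_equal(nchar(w), min(pos + 4, len) - max(pos - 4, 1) + 1)
    expect_equal(substr(w, min(pos, 5), min(pos, 5)),
                 substr(s, pos, pos))
  }
})

test_that("window validation flags the anomalous 10-mer and nothing else", {
  chk <- validate_window(table2_records())
  bad <- chk[!chk$length_ok, ]
  expect_equal(nrow(bad), 1L)
  expect_equal(bad$accession, "P25786")
  expect_equal(bad$position, 39L)
  expect_equal(bad$window, "YTVGLKSKTH")
  # chemistry: every row with a defined target centers correctly, except
  # that same anomalous row
  chem_bad <- chk[!is.na(chk$chemistry_ok) & !chk$chemistry_ok, ]
  expect_equal(chem_bad$position, 39L)
  # spot checks from the printed table
  xpot <- chk[chk$accession == "O43592" & chk$position == 661, ]
  expect_equal(xpot$center_residue, "T")
  expect_true(xpot$chemistry_ok)
  expect_true(chk[chk$accession == "P17900" & chk$position == 63, ]$chemistry_ok)
})

test_that("validation against a supplied sequence re-derives the window", {
  recs <- ptm_records("P12345", "Phosphoserine", 6L, "AAAASAAAA")
  seqs <- c(P12345 = "MWWWWSWWWWAAAA")
  chk <- validate_window(recs, seqs)
  expect_false(chk$length_ok)  # window inconsistent with the real sequence
  recs2 <- ptm_records("P12345", "Phosphoserine", 6L,
                       expected_window(seqs[[1]], 6))
  expect_true(validate_window(recs2, seqs)$length_ok)
})

test_that("flat-file round trips are exact and byte-stable", {
  recs <- table2_records()
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_ptm_flatfile(recs, p1)
  back <- read_ptm_flatfile(p1)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(recs))
  write_ptm_flatfile(back, p2)
  expect_identical(readLines(p1), readLines(p2))

  # large randomized collection
  set.seed(11)
  n <- 1000
  classes <- unlist(ptmgrav:::SYNTH_CLASS_POOLS, use.names = FALSE)
  recs <- ptm_records(
    accession = sprintf("Q%05d", sample(500, n, replace = TRUE)),
    modification = sample(classes, n, replace = TRUE),
    position = sample(1000, n, replace = TRUE),
    window = replicate(n, paste(sample(ptmgrav:::AMINO_ACIDS,
                                       sample(5:9, 1), replace = TRUE),
                                collapse = "")),
    sources = replicate(n, sample(c("UniProt", "HPRD", "SysPTM"),
                                  sample(0:3, 1)), simplify = FALSE),
    pubmed_ids = replicate(n, sample.int(3e7, sample(0:2, 1)),
                           simplify = FALSE),
    asa = ifelse(runif(n) < 0.5, NA_real_, round(runif(n, 0, 200), 1)))
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write_ptm_flatfile(recs, p3)
  back <- read_ptm_flatfile(p3)
  attr(back, "errors") <- NULL
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(recs))
})

test_that("FASTA sequences round-trip through Biostrings", {
  seqs <- c(P00001 = "MTDGDYDYLIK", P00002 = "ACDEFGHIKLMNP")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_sequences(seqs, path)
  expect_equal(read_sequences(path), seqs)
})
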