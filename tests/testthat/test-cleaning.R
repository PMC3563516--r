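# Read cleaning: the filter ledger, collapsing, and the length profile.

test_that("ledger arithmetic reproduces published two-library accounting", {
  # fetal-type library
  f <- CleaningSummary("fetal", total_read = 15941389,
                       high_quality = 15881408, adaptor3_null = 10834,
                       insert_null = 5218, adaptor5_contaminants = 23352,
                       small_than_18nt = 387691, polyA = 131)
  expect_identical(cleanReadCount(f), 15454182)
  expect_equal(unname(ledgerPercentages(f)[["clean_reads"]]), 97.31)
  # adult-type library
  a <- CleaningSummary("adult", total_read = 13641806,
                       high_quality = 13606490, adaptor3_null = 6723,
                       insert_null = 577, adaptor5_contaminants = 5830,
                       small_than_18nt = 35162, polyA = 34)
  expect_identical(cleanReadCount(a), 13558164)
  expect_equal(unname(ledgerPercentages(a)[["clean_reads"]]), 99.64)
})

test_that("each read lands in exactly one ledger category with fixed priority", {
  a3 <- "TCGTATGCCGTCTTCTGCTTG"
  a5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  tail5 <- substr(a5, nchar(a5) - 5, nchar(a5))
  reads <- c(
    paste0(strrep("A", 30), a3),                      # polyA
    paste0("ACGTACGTACGTACGTACGTAC", a3),             # clean, 22 nt
    strrep("G", 40),                                  # no 3' adapter
    a3,                                               # empty insert
    paste0(tail5, "ACGTACGTACGTACGTAC", a3),          # 5' contaminated
    paste0("ACGTACG", a3))                            # < 18 nt
  out <- cleanReads(reads, a3, a5, library = "L")
  lc <- ledgerCounts(out$summary)
  expect_equal(unname(lc[c("adaptor3_null", "insert_null",
                           "adaptor5_contaminants", "small_than_18nt",
                           "polyA", "clean_reads")]),
               c(1, 1, 1, 1, 1, 1))
  expect_equal(length(out$tags), 1L)
  expect_equal(as.character(tagSequences(out$tags)), "ACGTACGTACGTACGTACGTAC")
})

test_that("ledger and collapsing conserve reads on random inputs", {
  a3 <- "TCGTATGCCGTCTTCTGCTTG"; a5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  set.seed(404)
  for (rep in 1:5) {
    n <- sample(200:600, 1)
    ins <- replicate(n, paste(sample(c("A", "C", "G", "T"),
                                     sample(5:28, 1), replace = TRUE),
                              collapse = ""))
    reads <- paste0(ins, a3)
    # sprinkle in adapterless junk
    reads <- c(reads, replicate(20, paste(sample(c("A", "C"), 30,
                                                 replace = TRUE),
                                          collapse = "")))
    out <- cleanReads(reads, a3, a5, library = "L")
    lc <- ledgerCounts(out$summary)
    expect_equal(unname(lc[["high_quality"]]),
                 unname(sum(lc[c("adaptor3_null", "insert_null",
                                 "adaptor5_contaminants", "small_than_18nt",
                                 "polyA", "clean_reads")])))
    expect_equal(sum(tagCounts(out$tags)), cleanReadCount(out$summary))
  }
})

test_that("cleaning already-clean inserts removes nothing (idempotence)", {
  a3 <- "TCGTATGCCGTCTTCTGCTTG"; a5 <- "GTTCAGAGTTCTACAGTCCGACGATC"
  set.seed(11)
  ins <- replicate(50, paste(sample(c("A", "C", "G", "T"), 22,
                                    replace = TRUE), collapse = ""))
  ins <- ins[!grepl(substr(a3, 1, 8), ins, fixed = TRUE) &
             !startsWith(ins, substr(a5, 21, 26)) &
             vapply(ins, function(s)
               mean(strsplit(s, "")[[1]] == "A") < 0.8, TRUE)]
  first <- cleanReads(paste0(ins, a3), a3, a5, library = "L")
  again <- cleanReads(paste0(as.character(tagSequences(first$tags)), a3),
                      a3, a5, library = "L")
  expect_equal(cleanReadCount(again$summary), length(first$tags))
  expect_setequal(as.character(tagSequences(again$tags)),
                  as.character(tagSequences(first$tags)))
})

test_that("length distribution weights by abundance and sums to one", {
  ts <- makeTagSet(c("ACGTACGTACGTACGTACGTA", "ACGTACGTACGTACGTACGTAC"),
                   c(3, 7), c(0, 0))
  ld <- lengthDistribution(ts, library = "fetal")
  expect_equal(ld$fraction[ld$length == 21], 0.3)
  expect_equal(ld$fraction[ld$length == 22], 0.7)
  expect_equal(sum(ld$fraction), 1)
  one <- lengthDistribution(makeTagSet("ACGTACGTACGTACGTACGTAC", 5, 0))
  expect_equal(nrow(one), 1L)
  expect_equal(one$fraction, 1)
  expect_error(lengthDistribution(makeTagSet(character(0), integer(0),
                                             integer(0))), "empty")
})

test_that("collapsed FASTA round-trips a TagSet", {
  ts <- makeTagSet(c("ACGTACGTACGTACGTACGTAC", "TTGCATGCATGCATGCATGCAT"),
                   c(12, 3), c(0, 0))
  fp <- tempfile(fileext = ".fa")
  writeCollapsedFasta(ts, fp, library = "fetal")
  back <- readCollapsedFasta(fp, library = "fetal")
  expect_setequal(as.character(tagSequences(back)),
                  as.character(tagSequences(ts)))
  expect_equal(sum(tagCounts(back)), 15)
})

test_that("the ledger cannot be constructed inconsistent", {
  s <- CleaningSummary("x", 100, 100, 1, 1, 1, 1, 1)
  expect_identical(cleanReadCount(s), 95)
  bad <- s
  bad@counts[["clean_reads"]] <- 90
  expect_error(validObject(bad), "identity")
})
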