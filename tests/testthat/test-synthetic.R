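# The synthetic study generator: determinism, planted structure, read
# composition, provenance conservation, qPCR model.

test_that("genome generation is deterministic with controlled composition", {
  cfg <- simulationConfig(seed = 7, genome_length = 50000L)
  set.seed(7); g1 <- generateGenome(cfg)
  set.seed(7); g2 <- generateGenome(cfg)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(Biostrings::width(g1), 50000L)

  pure <- simulationConfig(seed = 1, gc_content = 1)
  set.seed(1); gp <- as.character(generateGenome(pure)[[1]])
  expect_true(grepl("^[GC]+$", gp))

  cfg42 <- simulationConfig(seed = 3, genome_length = 100000L,
                            gc_content = 0.42)
  set.seed(3); g <- as.character(generateGenome(cfg42)[[1]])
  gc <- mean(strsplit(g, "")[[1]] %in% c("G", "C"))
  # binomial concentration: sd ~ sqrt(.42*.58/1e5) ~ 0.0016
  expect_gt(gc, 0.41); expect_lt(gc, 0.43)
})

test_that("planted hairpins satisfy the discovery criteria by construction", {
  set.seed(42)
  genome <- Biostrings::DNAStringSet(
    c(chr1 = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                   collapse = "")))
  mature <- "TGAGGTAGTAGGTTGTATAGTT"   # 22 nt
  pl <- plantHairpin(genome, mature, at = 300, star_mismatches = 0L)
  pre <- pl$hairpin$precursor
  ev <- evaluateCandidate(pre, pl$hairpin$mature_start,
                          pl$hairpin$mature_end)
  expect_true(ev$pass)
  # the planted mature is recoverable from the updated genome
  expect_identical(substr(as.character(pl$genome[[1]]), pl$mature_start,
                          pl$mature_end), mature)
  # too many star mismatches is refused by design
  expect_error(plantHairpin(genome, mature, at = 300,
                            star_mismatches = 7L), "mismatches")
  expect_error(plantHairpin(genome, "ACGT", at = 300), "20-23")
})

test_that("planted loci are disjoint and every read has one provenance label", {
  cfg <- simulationConfig(seed = 13,
                          library_sizes = c(fetal = 5000L, adult = 5000L))
  study <- simulateStudy(cfg)
  loci <- study$loci
  ov <- GenomicRanges::findOverlaps(loci, loci, ignore.strand = TRUE)
  expect_equal(length(ov), length(loci))  # self-overlaps only
  pv <- study$provenance
  expect_equal(as.integer(table(pv$library)[c("fetal", "adult")]),
               unname(cfg@library_sizes))
  expect_false(anyNA(pv$label))
})

test_that("read composition follows the configured study conditions", {
  cfg <- simulationConfig(seed = 101,
                          library_sizes = c(fetal = 40000L, adult = 40000L))
  study <- simulateStudy(cfg)
  cl <- cleanReads(study$reads$fetal, cfg@adapter3, cfg@adapter5,
                   library = "fetal")
  ld <- lengthDistribution(cl$tags)
  expect_equal(ld$length[which.max(ld$reads)], 22L)  # modal insert 22 nt

  # planted 4-fold ratios are realized within sampling error
  tc <- study$truth_counts
  for (id in study$mirna$id[study$mirna$fold_change == 4][1:3]) {
    x <- tc$mature_reads[tc$id == id & tc$library == "fetal"]
    y <- tc$mature_reads[tc$id == id & tc$library == "adult"]
    if (x + y > 400) {
      # binomial check on the fetal share, p = 4/5 under the planted ratio
      se <- sqrt(0.8 * 0.2 / (x + y))
      expect_lt(abs(x / (x + y) - 0.8), 5 * se)
    }
  }
})

test_that("zero rates switch features off", {
  cfg <- simulationConfig(seed = 5, polyA_rate = 0, isomir_rate = 0,
                          edit_rate = 0, error_rate = 0,
                          library_sizes = c(fetal = 3000L, adult = 3000L))
  study <- simulateStudy(cfg)
  pv <- study$provenance
  expect_equal(sum(pv$label == "polyA"), 0L)
  expect_false(any(pv$isomir)); expect_false(any(pv$edited))
  # with all noise off, miRNA reads are exact planted matures
  mm <- pv[pv$label == "mirna", ]
  expect_true(all(mm$insert %in% study$mirna$mature))
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulationConfig(seed = 99,
                          library_sizes = c(fetal = 2000L, adult = 2000L))
  s1 <- simulateStudy(cfg); s2 <- simulateStudy(cfg)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(as.character(s1$reads$fetal),
                   as.character(s2$reads$fetal))
  expect_identical(s1$provenance, s2$provenance)
})

test_that("dinucleotide shuffle preserves dinucleotide composition", {
  set.seed(8)
  dc <- function(s) {
    tb <- table(substring(s, 1:(nchar(s) - 1), 2:nchar(s)))
    tb[order(names(tb))]
  }
  for (rep in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 500, replace = TRUE),
               collapse = "")
    sh <- dinucleotideShuffle(s)
    expect_identical(dc(sh), dc(s))
    expect_false(identical(sh, s))
  }
})

test_that("qPCR simulation follows the log2 Ct model", {
  ab <- matrix(c(1, 2), 1, 2, dimnames = list("miR-x", c("s1", "s2")))
  set.seed(1)
  ct <- simulateQpcr(ab, noise_sd = 0)
  m <- tapply(ct$Ct, paste(ct$gene, ct$sample), mean)
  # doubling the abundance lowers Ct by exactly one cycle
  expect_equal(m[["miR-x s1"]] - m[["miR-x s2"]], 1)
  # triplicates identical at zero noise
  expect_equal(as.numeric(tapply(ct$Ct, paste(ct$gene, ct$sample),
                                 stats::sd)), rep(0, 4))
  expect_error(simulateQpcr(matrix(-1, 1, 1,
    dimnames = list("a", "b"))), "> 0")
})
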