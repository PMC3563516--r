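# Perfect-match mapping and category annotation.

test_that("exact mapping agrees with a naive scan on random tags", {
  set.seed(77)
  g <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE,
                    prob = c(0.29, 0.21, 0.21, 0.29)), collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  idx <- buildGenomeIndex(genome)
  # tags: some genome substrings (both strands), some random, one mutated
  starts <- sample(2900, 12)
  tags <- substring(g, starts, starts + 21)
  tags[5:6] <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(tags[5:6])))
  mut <- tags[1]
  substr(mut, 11, 11) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, 11, 11))[1]
  tags <- unique(c(tags, mut, replicate(5, paste(
    sample(c("A", "C", "G", "T"), 25, replace = TRUE), collapse = ""))))
  mp <- mapTags(tags, idx)
  hits <- as.data.frame(mp$hits)
  for (i in seq_along(tags)) {
    oracle <- naiveScan(tags[i], g)
    mine <- hits[hits$tag_id == i, c("start", "end", "strand")]
    mine <- mine[order(mine$start, mine$strand), ]
    oracle <- oracle[order(oracle$start, oracle$strand), ]
    expect_equal(nrow(mine), nrow(oracle), info = paste("tag", i))
    if (nrow(oracle)) {
      expect_equal(mine$start, oracle$start)
      expect_equal(as.character(mine$strand), oracle$strand)
    }
  }
  # every reported hit satisfies the perfect-match invariant
  for (r in seq_len(nrow(hits))) {
    sub <- substr(g, hits$start[r], hits$end[r])
    if (hits$strand[r] == "-")
      sub <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(sub)))
    expect_identical(sub, tags[hits$tag_id[r]])
  }
})

test_that("a tag planted at 12 loci yields exactly 12 hits", {
  set.seed(5)
  tag <- paste(sample(c("A", "C", "G", "T"), 22, replace = TRUE),
               collapse = "")
  spacer <- function() paste(sample(c("A", "C", "G", "T"), 50,
                                    replace = TRUE), collapse = "")
  g <- paste0(paste(replicate(12, paste0(spacer(), tag)), collapse = ""),
              spacer())
  idx <- buildGenomeIndex(Biostrings::DNAStringSet(c(chr1 = g)))
  mp <- mapTags(tag, idx)
  expect_equal(length(mp$hits), 12L)
  expect_length(mp$unmatched, 0)
})

test_that("annotation assigns one category per tag with fixed priority", {
  set.seed(19)
  g <- paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
             collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  idx <- buildGenomeIndex(genome)
  tag <- substr(g, 101, 122)          # overlaps both loci below
  ann <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(90, 110), c(110, 300)), strand = "+",
    type = c("rRNA", "intron"))
  ts <- TagSet(tag, matrix(5L, 1, 1, dimnames = list(NULL, "L")))
  mp <- mapTags(ts, idx)
  out <- annotateTags(mp$hits, ann, ts)
  expect_equal(out$assignment$category, "rRNA")
  expect_error(annotateTags(mp$hits,
    GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 10), strand = "+",
                           type = "lincRNA"), ts), "unknown class")
})

test_that("category summaries partition the genome-matched tags exactly", {
  set.seed(21)
  cfg <- simulationConfig(seed = 21,
                          library_sizes = c(fetal = 8000L, adult = 8000L))
  study <- simulateStudy(cfg)
  cl <- lapply(names(study$reads), function(lib)
    cleanReads(study$reads[[lib]], cfg@adapter3, cfg@adapter5,
               library = lib))
  tags <- mergeTagSets(cl[[1]]$tags, cl[[2]]$tags)
  idx <- buildGenomeIndex(study$genome)
  mp <- mapTags(tags, idx)
  out <- annotateTags(mp$hits, study$annotation, tags)
  for (lib in c("fetal", "adult")) {
    s <- out$summary[[lib]]
    w <- tagCounts(tags)[, lib]
    matched <- sort(unique(mp$hits$tag_id))
    expect_equal(unname(categoryTotals(s)[["reads"]]), sum(w[matched]))
    expect_equal(unname(categoryTotals(s)[["unique"]]),
                 sum(w[matched] > 0))
    # miRNA-dominant library, as constructed
    expect_equal(names(which.max(categoryPercentages(s, "reads"))), "miRNA")
  }
})

test_that("reverse-complementing the genome and swapping strands is neutral", {
  set.seed(31)
  cfg <- simulationConfig(seed = 31,
                          library_sizes = c(fetal = 4000L, adult = 4000L))
  study <- simulateStudy(cfg)
  cl <- cleanReads(study$reads$fetal, cfg@adapter3, cfg@adapter5,
                   library = "fetal")
  idx <- buildGenomeIndex(study$genome)
  mp <- mapTags(cl$tags, idx)
  s1 <- annotateTags(mp$hits, study$annotation, cl$tags)$summary$fetal

  glen <- Biostrings::width(study$genome)[1]
  rcgenome <- Biostrings::reverseComplement(study$genome)
  names(rcgenome) <- names(study$genome)
  ann <- study$annotation
  rcann <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(glen - GenomicRanges::end(ann) + 1,
                     glen - GenomicRanges::start(ann) + 1),
    strand = ifelse(as.character(GenomicRanges::strand(ann)) == "+",
                    "-", "+"),
    type = ann$type)
  mp2 <- mapTags(cl$tags, buildGenomeIndex(rcgenome))
  s2 <- annotateTags(mp2$hits, rcann, cl$tags)$summary$fetal
  expect_equal(s1@read_counts, s2@read_counts)
  expect_equal(s1@unique_counts, s2@unique_counts)
})

test_that("published category counts give the published read fractions", {
  fetal <- CategorySummary("fetal",
    unique_counts = c(miRNA = 5073, exon_antisense = 734,
      exon_sense = 72597, intron_antisense = 5624, intron_sense = 26620,
      rRNA = 107912, "repeat" = 47495, scRNA = 696, snRNA = 5023,
      snoRNA = 3330, srpRNA = 2034, tRNA = 24410, unknown = 386507),
    read_counts = c(miRNA = 9512581, exon_antisense = 893,
      exon_sense = 79779, intron_antisense = 8081, intron_sense = 34148,
      rRNA = 2213269, "repeat" = 95063, scRNA = 18870, snRNA = 17415,
      snoRNA = 13414, srpRNA = 28132, tRNA = 251226, unknown = 3181311))
  expect_equal(unname(categoryTotals(fetal)[["reads"]]), 15454182)
  expect_equal(unname(categoryPercentages(fetal, "reads")[["miRNA"]]), 61.55)
})
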