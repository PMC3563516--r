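# Novel discovery: flank extraction, candidate screening, the >10-hit rule,
# and planted-hairpin recovery with a shuffled negative control.

test_that("flank extraction clips at ends and respects strand", {
  set.seed(3)
  g <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
             collapse = "")
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  hit_start <- GenomicRanges::GRanges("chr1", IRanges::IRanges(5, 26),
                                      strand = "+")
  fl <- extractFlanks(hit_start, genome, flank = 150)
  expect_equal(fl$window_start, 1L)             # clipped, no error
  expect_equal(fl$tag_start, 5L)

  plus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 221),
                                 strand = "+")
  minus <- GenomicRanges::GRanges("chr1", IRanges::IRanges(200, 221),
                                  strand = "-")
  fp <- extractFlanks(plus, genome); fm <- extractFlanks(minus, genome)
  expect_identical(fm$sequence, as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(fp$sequence))))
  expect_error(extractFlanks(GenomicRanges::GRanges("chr1",
    IRanges::IRanges(590, 620)), genome), "outside")
})

test_that("the planted precursor is contained in the extracted window", {
  set.seed(12)
  genome <- Biostrings::DNAStringSet(
    c(chr1 = paste(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
                   collapse = "")))
  pl <- plantHairpin(genome, "TGAGGTAGTAGGTTGTATAGTT", at = 900)
  hit <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(pl$mature_start, pl$mature_end), strand = "+")
  fl <- extractFlanks(hit, pl$genome)
  expect_true(grepl(pl$hairpin$precursor, fl$sequence, fixed = TRUE))
  ev <- evaluateCandidate(fl$sequence, fl$tag_start, fl$tag_end)
  expect_true(ev$pass)
})

test_that("candidates violating individual criteria are rejected", {
  set.seed(6)
  genome <- Biostrings::DNAStringSet(
    c(chr1 = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                   collapse = "")))
  pl <- plantHairpin(genome, "TGAGGTAGTAGGTTGTATAGTT", at = 400,
                     loop_len = 12)
  pre <- pl$hairpin$precursor
  # mature spanning the loop: pairs on both sides -> hairpin criterion fails
  mid <- nchar(pre) %/% 2
  ev_loop <- evaluateCandidate(pre, mid - 10, mid + 11)
  expect_false(ev_loop$criteria[["hairpin"]])
  expect_false(ev_loop$pass)
  # an AU-rich precursor fails the AU-content window
  at_rich <- paste0(strrep("AT", 11), strrep("A", 8),
                    strrep("AT", 11))
  f <- foldRNA(at_rich)
  ev_au <- evaluateCandidate(at_rich, 1, 22, structure = f$structure,
                             mfe = f$mfe)
  if (ev_au$criteria[["hairpin"]]) expect_false(ev_au$criteria[["au"]])
  expect_false(ev_au$pass)
  # mature length out of range
  ev_len <- evaluateCandidate(pre, pl$hairpin$mature_start,
                              pl$hairpin$mature_start + 25)
  expect_false(ev_len$criteria[["mature_len"]])
})

test_that("tightening the MFEI threshold never accepts more candidates", {
  cfg <- simulationConfig(seed = 17,
                          library_sizes = c(fetal = 15000L, adult = 15000L))
  study <- simulateStudy(cfg)
  cl <- lapply(names(study$reads), function(lib)
    cleanReads(study$reads[[lib]], cfg@adapter3, cfg@adapter5,
               library = lib))
  tags <- mergeTagSets(cl[[1]]$tags, cl[[2]]$tags)
  idx <- buildGenomeIndex(study$genome)
  mk <- matchKnown(tags, study$mature_ref, study$hairpin_ref)
  accepted <- integer(0)
  for (thr in c(0.85, 1.2, 1.6, 2.2)) {
    p <- novelParams(); p$mfei_min <- thr
    nv <- discoverNovel(mk$leftover, idx, study$genome, p)
    accepted <- c(accepted, nrow(nv$novel))
  }
  expect_true(all(diff(accepted) <= 0))
})

test_that("tags with more than 10 genome hits are excluded", {
  set.seed(64)
  tag <- "TGAGGTAGTAGGTTGTATAGTT"
  spacer <- function() paste(sample(c("A", "C", "G", "T"), 60,
                                    replace = TRUE), collapse = "")
  g <- paste0(paste(replicate(11, paste0(spacer(), tag)), collapse = ""),
              spacer())
  genome <- Biostrings::DNAStringSet(c(chr1 = g))
  idx <- buildGenomeIndex(genome)
  ts <- TagSet(tag, matrix(50L, 1, 1, dimnames = list(NULL, "L")))
  nv <- discoverNovel(ts, idx, genome)
  expect_equal(nv$n_evaluated, 0L)   # removed before any evaluation
  expect_equal(nrow(nv$novel), 0L)
})

test_that("hairpins expressed in both libraries appear once in the overlap", {
  cfg <- simulationConfig(seed = 23,
                          library_sizes = c(fetal = 30000L, adult = 30000L))
  study <- simulateStudy(cfg)
  cl <- lapply(names(study$reads), function(lib)
    cleanReads(study$reads[[lib]], cfg@adapter3, cfg@adapter5,
               library = lib))
  tags <- mergeTagSets(cl[[1]]$tags, cl[[2]]$tags)
  idx <- buildGenomeIndex(study$genome)
  mk <- matchKnown(tags, study$mature_ref, study$hairpin_ref)
  mp <- mapTags(tags, idx)
  ann <- annotateTags(mp$hits, study$annotation, tags)
  ncRNA <- ann$assignment$tag_id[ann$assignment$category != "unknown"]
  keep <- setdiff(seq_len(length(tags)),
                  union(unique(mk$tag_assignment$tag_id), ncRNA))
  nv <- discoverNovel(tags[keep], idx, study$genome)
  both <- nv$novel$id[nv$novel$count_fetal > 0 & nv$novel$count_adult > 0]
  expect_setequal(nv$overlap, both)
  expect_equal(anyDuplicated(nv$overlap), 0L)
  # every accepted candidate re-passes the criteria audit
  for (i in seq_len(nrow(nv$novel))) {
    ev <- evaluateCandidate(nv$novel$precursor[i],
      regexpr(nv$novel$mature[i], nv$novel$precursor[i], fixed = TRUE),
      regexpr(nv$novel$mature[i], nv$novel$precursor[i], fixed = TRUE) +
        nchar(nv$novel$mature[i]) - 1)
    expect_true(ev$pass, info = nv$novel$id[i])
  }
})
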