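# Known-miRNA profiling: matching, arm usage, bias, edits, end variants,
# families, class totals.

# a tiny two-miRNA reference world used by several blocks
refWorld <- function() {
  m1 <- "TGAGGTAGTAGGTTGTATAGTT"                    # let-7-like
  m2 <- "TGGAATGTAAAGAAGTATGTAT"                    # miR-1-like
  loop <- strrep("CACA", 3)
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  list(mature = Biostrings::DNAStringSet(c(mirA = m1, mirB = m2)),
       hairpin = Biostrings::DNAStringSet(c(
         mirA = paste0(m1, loop, rc(m1)),
         mirB = paste0(m2, loop, rc(m2)))),
       m1 = m1, m2 = m2)
}

test_that("exact, variant and non-overlapping tags are partitioned", {
  rw <- refWorld()
  tags <- makeTagSet(c(rw$m1,                           # exact
                       substr(rw$m1, 1, 20),            # 3' trimmed variant
                       strrep("CACA", 3),               # loop only
                       "TTTTTTTTTTTTTTTTTTTTTT"),       # unrelated
                     c(10, 5, 2, 7), c(1, 0, 0, 3))
  mk <- matchKnown(tags, rw$mature, rw$hairpin)
  p <- mk$profiles
  expect_equal(p$exact_fetal[p$mirna_id == "mirA"], 10)
  expect_equal(p$total_fetal[p$mirna_id == "mirA"], 15)
  expect_equal(p$total_adult[p$mirna_id == "mirA"], 1)
  # loop-only and unrelated tags stay leftover
  expect_equal(length(mk$leftover), 2L)
  # partition: assigned + leftover = input
  expect_equal(nrow(mk$tag_assignment) + length(mk$leftover), length(tags))
})

test_that("planted matures are recovered with exact counts at zero noise", {
  cfg <- simulationConfig(seed = 55, isomir_rate = 0, edit_rate = 0,
                          error_rate = 0,
                          library_sizes = c(fetal = 10000L, adult = 10000L))
  study <- simulateStudy(cfg)
  cl <- lapply(names(study$reads), function(lib)
    cleanReads(study$reads[[lib]], cfg@adapter3, cfg@adapter5,
               library = lib))
  tags <- mergeTagSets(cl[[1]]$tags, cl[[2]]$tags)
  mk <- matchKnown(tags, study$mature_ref, study$hairpin_ref)
  tc <- study$truth_counts
  for (id in study$mirna$id[study$mirna$class == "known"]) {
    for (lib in c("fetal", "adult")) {
      want <- tc$mature_reads[tc$id == id & tc$library == lib]
      got <- mk$profiles[[paste0("exact_", lib)]][
        mk$profiles$mirna_id == id]
      if (want > 0) expect_equal(got, want, info = paste(id, lib))
    }
  }
})

test_that("arm usage flags near-equal miR/miR* pairs", {
  profiles <- data.frame(
    mirna_id = c("mir151", "mir151*", "mir455", "mir455*", "mirZ", "mirZ*"),
    arm_class = c("miR", "miR*", "miR", "miR*", "miR", "miR*"),
    precursor_id = c("p151", "p151", "p455", "p455", "pZ", "pZ"),
    mature = strrep("A", 22),
    total_fetal = c(447, 680, 186, 314, 1000, 0),
    stringsAsFactors = FALSE)
  au <- armUsage(profiles, library = "fetal")
  r151 <- au[au$precursor_id == "p151", ]
  expect_equal(r151$dominant_arm, "miR*")
  expect_true(r151$near_equal)
  r455 <- au[au$precursor_id == "p455", ]
  expect_equal(r455$dominant_arm, "miR*")
  rz <- au[au$precursor_id == "pZ", ]
  expect_equal(rz$dominant_arm, "miR")
  expect_false(rz$near_equal)
})

test_that("nucleotide bias rows are frequencies over observed bases", {
  profiles <- data.frame(
    mirna_id = c("a", "b"), arm_class = "miR", precursor_id = c("pa", "pb"),
    mature = c(strrep("A", 22), paste0("G", strrep("A", 21))),
    total_fetal = c(5, 5), stringsAsFactors = FALSE)
  nb <- nucleotideBias(profiles)
  expect_equal(unname(nb$matrix[1, "A"]), 0.5)
  expect_equal(unname(nb$matrix[1, "G"]), 0.5)
  expect_equal(unname(rowSums(nb$matrix)), rep(1, 22))
  one <- nucleotideBias(profiles[1, ])
  expect_equal(unname(one$matrix[1, "A"]), 1)
  expect_error(nucleotideBias(profiles[0, ]), "empty")
})

test_that("single-base edits and untemplated additions are told apart", {
  rw <- refWorld()
  edited <- rw$m1
  substr(edited, 5, 5) <- "C"                     # position-5 substitution
  added <- paste0(rw$m1, "A")                     # untemplated 3' A
  # the hairpin continues with the loop (C), so +A is untemplated
  lo <- makeTagSet(c(edited, added), c(4, 6), c(1, 0))
  de <- detectBaseEdits(lo, rw$mature, hairpin_ref = rw$hairpin)
  ed <- de$edits
  sub <- ed[ed$type == "substitution", ]
  expect_equal(sub$position, 5L)
  expect_equal(sub$mirna_id, "mirA")
  expect_true(sub$in_seed)
  expect_equal(sub$count_fetal, 4)
  add <- ed[ed$type == "addition3p", ]
  expect_equal(add$obs_base, "A")
  expect_equal(add$count_fetal, 6)
})

test_that("edits never fire on tags that known matching accepted", {
  rw <- refWorld()
  tags <- makeTagSet(c(rw$m1, rw$m2), c(3, 3), c(3, 3))
  mk <- matchKnown(tags, rw$mature, rw$hairpin)
  de <- detectBaseEdits(mk$leftover, rw$mature)
  expect_equal(nrow(de$edits), 0L)
})

test_that("a planted edit rate is recovered within binomial error", {
  cfg <- simulationConfig(seed = 77, isomir_rate = 0, error_rate = 0,
                          edit_rate = 0.05,
                          library_sizes = c(fetal = 20000L, adult = 20000L))
  study <- simulateStudy(cfg)
  cl <- lapply(names(study$reads), function(lib)
    cleanReads(study$reads[[lib]], cfg@adapter3, cfg@adapter5,
               library = lib))
  tags <- mergeTagSets(cl[[1]]$tags, cl[[2]]$tags)
  mk <- matchKnown(tags, study$mature_ref, study$hairpin_ref)
  de <- detectBaseEdits(mk$leftover, study$mature_ref,
                        hairpin_ref = study$hairpin_ref,
                        profiles = mk$profiles)
  # edited fraction of mature-matched + edited reads; star-arm reads reduce
  # the effective rate a little, so allow a generous band around 0.05
  expect_gt(de$edited_fraction, 0.02)
  expect_lt(de$edited_fraction, 0.09)
})

test_that("end-variant offsets are signed as extensions/trims", {
  rw <- refWorld()
  trimmed3 <- substr(rw$m1, 1, nchar(rw$m1) - 2)  # (0, -2)
  ext5 <- paste0("G", rw$m2)  # not templated upstream of m2? build tag from
  # the hairpin instead: 5' extension must be templated to stay in-hairpin
  hp2 <- as.character(rw$hairpin[["mirB"]])
  # mirB mature starts at position 1 of its hairpin, so use a 3' extension
  ext3 <- substr(hp2, 1, nchar(rw$m2) + 1)        # (0, +1), templated
  tags <- makeTagSet(c(rw$m1, trimmed3, ext3), c(5, 3, 2), c(0, 0, 0))
  mk <- matchKnown(tags, rw$mature, rw$hairpin)
  ev <- catalogEndVariants(mk, tags)
  v <- ev$variants
  tv <- v[v$tag == trimmed3, ]
  expect_equal(c(tv$offset5, tv$offset3), c(0, -2))
  xv <- v[v$tag == ext3, ]
  expect_equal(c(xv$offset5, xv$offset3), c(0, 1))
  expect_equal(ev$share3, 1)  # all variants here are 3'-end
})

test_that("3'-biased isomiRs are recovered as a dominant 3' share", {
  cfg <- simulationConfig(seed = 31, edit_rate = 0, error_rate = 0,
                          isomir_rate = 0.3,
                          library_sizes = c(fetal = 20000L, adult = 20000L))
  study <- simulateStudy(cfg)
  cl <- lapply(names(study$reads), function(lib)
    cleanReads(study$reads[[lib]], cfg@adapter3, cfg@adapter5,
               library = lib))
  tags <- mergeTagSets(cl[[1]]$tags, cl[[2]]$tags)
  mk <- matchKnown(tags, study$mature_ref, study$hairpin_ref)
  ev <- catalogEndVariants(mk, tags)
  expect_gt(ev$share3, 0.75)   # 90% of shifts are 3'-sided by design
})

test_that("family assignment reports ranges, singletons and unassigned", {
  profiles <- data.frame(
    mirna_id = c("bta-miR-2284a", "bta-miR-2284x", "bta-miR-1", "bta-miR-99"),
    arm_class = "miR", precursor_id = paste0("p", 1:4),
    mature = strrep("A", 22),
    total_fetal = c(1, 46548, 300, 12), stringsAsFactors = FALSE)
  fams <- data.frame(family = c("mir-2284", "mir-2284", "mir-1"),
                     id = c("bta-miR-2284a", "bta-miR-2284x", "bta-miR-1"),
                     stringsAsFactors = FALSE)
  out <- assignFamilies(profiles, fams)
  f2284 <- out$summary[out$summary$family == "mir-2284", ]
  expect_equal(c(f2284$min_reads, f2284$max_reads), c(1, 46548))
  f1 <- out$summary[out$summary$family == "mir-1", ]
  expect_equal(f1$min_reads, f1$max_reads)
  expect_equal(out$unassigned, "bta-miR-99")
  dup <- rbind(fams, data.frame(family = "other", id = "bta-miR-1"))
  expect_error(assignFamilies(profiles, dup), "two families")
})

test_that("family files round-trip through the stanza format", {
  fams <- data.frame(id = c("m1", "m2", "m3", "m4"),
                     family = c("famA", "famA", "famB", NA),
                     stringsAsFactors = FALSE)
  fp <- tempfile()
  writeFamilyFile(fams, fp)
  back <- readFamilyFile(fp)
  expect_setequal(back$id, c("m1", "m2", "m3"))
  expect_equal(back$family[back$id == "m3"], "famB")
})

test_that("arm-class totals sum to the library's category count", {
  # arm-class breakdowns of the two-library reference summary
  expect_equal(unname(mirnaClassTotals(c("miR" = 344, "miR*" = 21,
    "miR-5p" = 21, "miR-3p" = 21))[["total"]]), 407)
  expect_equal(unname(mirnaClassTotals(c("miR" = 243, "miR*" = 13,
    "miR-5p" = 16, "miR-3p" = 17))[["total"]]), 289)
  expect_error(mirnaClassTotals(c(foo = 1)), "unknown arm class")
})
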