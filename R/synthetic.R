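## Synthetic small-RNA study generator: a toy genome with planted miRNA
## hairpins, other RNA loci, two read libraries with adapter contamination
## and isomiR/edit structure, and qPCR Ct tables -- all with recorded ground
## truth so each pipeline stage is testable without downloads.

#' SimulationConfig: parameters of the synthetic small-RNA study
#'
#' Holds every knob of the generator. Defaults describe the study conditions
#' emulated throughout: two libraries (fetal-like and adult-like) of 2e5
#' reads each dominated by 21-23 nt inserts with a 22 nt mode, 30 planted
#' known miRNA hairpins (20 of them differentially expressed at 4-fold),
#' 10 planted novel hairpins, adapter contamination and sub-18-nt fragments
#' at rates mirroring a typical deep-sequencing filter ledger.
#'
#' @export
setClass("SimulationConfig", representation(
  seed = "integer", genome_length = "integer", gc_content = "numeric",
  n_known_mirna = "integer", n_novel_mirna = "integer",
  n_other_loci_per_class = "integer", library_sizes = "integer",
  length_mode = "integer", adapter3 = "character", adapter5 = "character",
  error_rate = "numeric", isomir_rate = "numeric", edit_rate = "numeric",
  polyA_rate = "numeric", short_rate = "numeric", a3null_rate = "numeric",
  insertnull_rate = "numeric", a5_rate = "numeric",
  mirna_read_share = "numeric", star_share = "numeric",
  planted_fold_changes = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  rates <- c(object@error_rate, object@isomir_rate, object@edit_rate,
             object@polyA_rate, object@short_rate, object@a3null_rate,
             object@insertnull_rate, object@a5_rate, object@star_share,
             object@mirna_read_share)
  if (any(rates < 0 | rates > 1)) msg <- c(msg, "rates must be in [0, 1]")
  if (any(object@library_sizes <= 0)) msg <- c(msg, "library sizes must be > 0")
  if (object@genome_length <= 0) msg <- c(msg, "genome length must be > 0")
  if (object@gc_content < 0 || object@gc_content > 1)
    msg <- c(msg, "gc_content must be in [0, 1]")
  ## rough span check: each planted locus needs < 400 bp on average
  n_loci <- object@n_known_mirna + object@n_novel_mirna +
    9L * object@n_other_loci_per_class
  if (object@genome_length < n_loci * 400L)
    msg <- c(msg, "genome too short for the requested planted loci")
  if (any(object@planted_fold_changes <= 0))
    msg <- c(msg, "planted fold changes must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @param genome_length Genome size in bases.
#' @param gc_content Genome GC fraction.
#' @param n_known_mirna,n_novel_mirna Number of planted known / novel hairpins.
#' @param n_other_loci_per_class Loci planted per non-miRNA class.
#' @param library_sizes Integer pair of total raw reads (fetal-like,
#'   adult-like library).
#' @param length_mode Modal mature/insert length, nt.
#' @param adapter3,adapter5 Adapter sequences ligated 3' / 5' of the insert.
#' @param error_rate Per-base sequencing substitution probability.
#' @param isomir_rate Fraction of miRNA reads carrying a 1-5 nt end shift.
#' @param edit_rate Fraction of miRNA reads carrying a single base edit or an
#'   untemplated 3' A/U addition.
#' @param polyA_rate,short_rate,a3null_rate,insertnull_rate,a5_rate Fractions
#'   of reads assigned to the corresponding filter-ledger categories.
#' @param mirna_read_share Fraction of clean reads drawn from miRNA loci,
#'   one value per library.
#' @param star_share Fraction of each hairpin's reads drawn from the star arm.
#' @param planted_fold_changes Named numeric vector of true fetal/adult
#'   expression ratios per planted miRNA id; empty means the default design
#'   (10 up at 4-fold, 10 down at 4-fold, built over the known miRNAs).
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(seed = 1L, genome_length = 50000L,
    gc_content = 0.42, n_known_mirna = 30L, n_novel_mirna = 10L,
    n_other_loci_per_class = 2L, library_sizes = c(fetal = 200000L,
    adult = 200000L), length_mode = 22L,
    adapter3 = "TCGTATGCCGTCTTCTGCTTG",
    adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
    error_rate = 0.001, isomir_rate = 0.15, edit_rate = 0.05,
    polyA_rate = 1e-05, short_rate = 0.024, a3null_rate = 7e-04,
    insertnull_rate = 3e-04, a5_rate = 0.0015,
    mirna_read_share = c(0.72, 0.72), star_share = 0.08,
    planted_fold_changes = numeric(0)) {
  if (is.null(names(library_sizes))) names(library_sizes) <- c("fetal", "adult")
  new("SimulationConfig", seed = as.integer(seed),
      genome_length = as.integer(genome_length), gc_content = gc_content,
      n_known_mirna = as.integer(n_known_mirna),
      n_novel_mirna = as.integer(n_novel_mirna),
      n_other_loci_per_class = as.integer(n_other_loci_per_class),
      library_sizes = stats::setNames(as.integer(library_sizes),
                                      names(library_sizes)),
      length_mode = as.integer(length_mode), adapter3 = toupper(adapter3),
      adapter5 = toupper(adapter5), error_rate = error_rate,
      isomir_rate = isomir_rate, edit_rate = edit_rate,
      polyA_rate = polyA_rate, short_rate = short_rate,
      a3null_rate = a3null_rate, insertnull_rate = insertnull_rate,
      a5_rate = a5_rate, mirna_read_share = mirna_read_share,
      star_share = star_share, planted_fold_changes = planted_fold_changes)
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@genome_length, "bp genome,",
      object@n_known_mirna, "known +", object@n_novel_mirna,
      "novel hairpins,", paste(object@library_sizes, collapse = "/"),
      "reads, seed", object@seed, "\n")
})

#' Generate a random genome
#'
#' @param config A [SimulationConfig-class] (length and GC are used). The
#'   caller is responsible for seeding the RNG; [simulateStudy()] seeds from
#'   `config@seed`.
#' @return A [Biostrings::DNAStringSet] with one chromosome `chr1`.
#' @export
generateGenome <- function(config) {
  if (config@genome_length <= 0) stop("non-positive genome length")
  DNAStringSet(c(chr1 = .randomSeq(config@genome_length, config@gc_content)))
}

## screen a candidate insert for simulation artefacts that would collide with
## the cleaning filters (adapter seed inside insert, 5' contaminant prefix,
## poly-A composition)
.insertClean <- function(seq, config) {
  seed3 <- substr(config@adapter3, 1, 8)
  tail5 <- substr(config@adapter5, nchar(config@adapter5) - 5,
                  nchar(config@adapter5))
  !grepl(seed3, seq, fixed = TRUE) && !startsWith(seq, tail5) &&
    mean(strsplit(seq, "")[[1]] == "A") < 0.8
}

## design one hairpin: mature + loop + star (or star + loop + mature for 3p
## arm), with the star a near-reverse-complement of the mature
.designHairpin <- function(mature, arm = c("5p", "3p"), loop_len = 12L,
                           star_mismatches = 0L) {
  arm <- match.arg(arm)
  L <- nchar(mature)
  if (L < 20 || L > 23) stop("mature length must be 20-23 nt")
  if (star_mismatches >= 6)
    stop("star with >= 6 mismatches cannot satisfy the hairpin criteria")
  star <- .revcomp(mature)
  if (star_mismatches > 0) {
    ## keep mismatches away from the helix ends so the stem stays anchored
    pos <- sample(4:(L - 3), star_mismatches)
    for (p in pos) star <- .mutateBase(star, p)
  }
  ## loop biased to A/C to avoid self-pairing competing with the stem
  loop <- paste(sample(c("A", "C"), loop_len, replace = TRUE,
                       prob = c(0.6, 0.4)), collapse = "")
  if (arm == "5p") {
    precursor <- paste0(mature, loop, star)
    mstart <- 1L
  } else {
    precursor <- paste0(star, loop, mature)
    mstart <- nchar(star) + loop_len + 1L
  }
  list(precursor = precursor, mature = mature, star = star, arm = arm,
       mature_start = mstart, mature_end = mstart + L - 1L,
       star_mismatches = star_mismatches)
}

#' Plant a miRNA hairpin into a genome
#'
#' Builds a precursor (mature arm + loop + near-reverse-complement star arm),
#' verifies by re-evaluation that the construct satisfies all novel-miRNA
#' screening criteria, and writes it into the genome at the given position
#' (overwriting the random sequence there, so genome length is unchanged).
#'
#' @param genome A DNAStringSet (single chromosome used).
#' @param mature Mature miRNA sequence, 20-23 nt.
#' @param at 1-based position where the precursor starts.
#' @param arm Which arm carries the mature sequence ("5p" or "3p").
#' @param loop_len Loop length in nt (>= 8).
#' @param star_mismatches Number of mismatches between the star and the
#'   mature's reverse complement (must be < 6).
#' @param max_tries Re-randomization attempts for the loop if the construct
#'   fails its own criteria audit.
#' @return List with the updated `genome`, the `locus` (start/end/strand),
#'   and the hairpin layout (precursor, mature/star sequences and spans).
#' @export
plantHairpin <- function(genome, mature, at, arm = "5p", loop_len = 12L,
                         star_mismatches = 0L, max_tries = 25L) {
  mature <- toupper(chartr("Uu", "Tt", mature))
  if (loop_len < 8) stop("loop must be at least 8 nt")
  for (try in seq_len(max_tries)) {
    hp <- .designHairpin(mature, arm, loop_len, star_mismatches)
    fold <- foldRNA(hp$precursor)
    ev <- evaluateCandidate(hp$precursor, hp$mature_start, hp$mature_end,
                            structure = fold$structure, mfe = fold$mfe,
                            mature_len_range = c(20L, 23L))
    if (ev$pass) {
      g <- as.character(genome[[1]])
      plen <- nchar(hp$precursor)
      if (at < 1 || at + plen - 1 > nchar(g)) stop("hairpin outside genome")
      substr(g, at, at + plen - 1) <- hp$precursor
      genome[[1]] <- DNAString(g)
      locus <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(at, at + plen - 1), strand = "+")
      return(list(genome = genome, locus = locus, hairpin = hp,
                  mature_start = at + hp$mature_start - 1L,
                  mature_end = at + hp$mature_end - 1L))
    }
  }
  stop("could not construct a criteria-compliant hairpin for this mature")
}

## class layout for non-miRNA loci: length and read share templates; shares
## are proportions of the non-miRNA clean reads, loosely following the
## category spread of a muscle small-RNA library
.OTHER_CLASSES <- data.frame(
  class = c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "srpRNA", "repeat",
            "exon", "intron"),
  len = c(120L, 75L, 100L, 85L, 100L, 150L, 200L, 220L, 300L),
  share = c(0.50, 0.065, 0.006, 0.005, 0.004, 0.008, 0.022, 0.020, 0.010),
  stringsAsFactors = FALSE)
.UNKNOWN_SHARE <- 0.30   # intergenic windows (annotated as unknown)
.NOMAP_SHARE <- 0.06     # random non-genomic tags

#' Simulate the full synthetic small-RNA study
#'
#' Generates the genome, plants known and novel miRNA hairpins and other
#' RNA-class loci, builds the miRBase-style references and family file, and
#' simulates both read libraries with full per-read provenance.
#'
#' @param config A [SimulationConfig-class].
#' @return A list (the "study") with elements `genome`, `annotation`
#'   (GRanges incl. known miRNA loci but not novel ones), `loci` (GRanges of
#'   everything planted, novel included), `mirna` (data.frame of planted
#'   hairpins: id, class known/novel, precursor, mature, star, arm, spans,
#'   fold change), `mature_ref`/`hairpin_ref` (DNAStringSet, known only),
#'   `families` (data.frame id, family), `reads` (list of DNAStringSet, one
#'   per library), `provenance` (data.frame per read), `truth_counts`
#'   (data.frame per miRNA per library: exact mature reads and all reads),
#'   and `config`.
#' @export
simulateStudy <- function(config = simulationConfig()) {
  set.seed(config@seed)
  genome <- generateGenome(config)

  n_known <- config@n_known_mirna
  n_novel <- config@n_novel_mirna
  n_mir <- n_known + n_novel

  ## --- design hairpins -------------------------------------------------
  mir <- vector("list", n_mir)
  for (i in seq_len(n_mir)) {
    known <- i <= n_known
    len <- if (known) sample(21:23, 1, prob = c(0.25, 0.6, 0.15))
           else sample(20:22, 1, prob = c(0.15, 0.25, 0.6))
    repeat {
      mature <- .randomSeq(len, gc = stats::runif(1, 0.40, 0.60))
      au <- auContent(mature)
      if (au >= 0.32 && au <= 0.68 && .insertClean(mature, config)) break
    }
    arm <- sample(c("5p", "3p"), 1)
    mm <- sample(0:3, 1)
    id <- if (known) sprintf("bta-miR-sim%d", i)
          else sprintf("novel%d", i - n_known)
    mir[[i]] <- list(id = id, known = known, mature = mature, arm = arm,
                     mm = mm, loop = sample(10:16, 1))
  }

  ## --- fold changes ----------------------------------------------------
  fc <- stats::setNames(rep(1, n_mir), vapply(mir, `[[`, "", "id"))
  if (length(config@planted_fold_changes)) {
    fc[names(config@planted_fold_changes)] <- config@planted_fold_changes
  } else if (n_known >= 20) {
    fc[seq_len(10)] <- 4
    fc[11:20] <- 0.25
  }

  ## --- plant loci ------------------------------------------------------
  classes <- .OTHER_CLASSES[rep(seq_len(nrow(.OTHER_CLASSES)),
                                each = config@n_other_loci_per_class), ]
  plant_len <- c(rep(80L, n_mir), classes$len)  # hairpins fit well within 80
  n_loci <- length(plant_len)
  gap <- floor((config@genome_length - sum(plant_len) - 200) / (n_loci + 1))
  starts <- integer(n_loci)
  pos <- 100L
  ord <- sample(n_loci)  # interleave classes along the genome
  for (k in seq_len(n_loci)) {
    idx <- ord[k]
    starts[idx] <- pos + sample.int(max(gap - 50L, 1L), 1)
    pos <- starts[idx] + plant_len[idx]
  }
  if (pos > config@genome_length) stop("genome too short for planted loci")

  mir_rows <- vector("list", n_mir)
  for (i in seq_len(n_mir)) {
    pl <- plantHairpin(genome, mir[[i]]$mature, at = starts[i],
                       arm = mir[[i]]$arm, loop_len = mir[[i]]$loop,
                       star_mismatches = mir[[i]]$mm)
    genome <- pl$genome
    hp <- pl$hairpin
    star_start <- if (hp$arm == "5p")
      starts[i] + nchar(hp$mature) + mir[[i]]$loop else starts[i]
    mir_rows[[i]] <- data.frame(
      id = mir[[i]]$id, class = ifelse(mir[[i]]$known, "known", "novel"),
      precursor = hp$precursor, mature = hp$mature, star = hp$star,
      arm = hp$arm, chrom = "chr1",
      pre_start = starts[i], pre_end = starts[i] + nchar(hp$precursor) - 1L,
      mature_start = pl$mature_start, mature_end = pl$mature_end,
      star_start = star_start, star_end = star_start + nchar(hp$star) - 1L,
      star_mismatches = hp$star_mismatches,
      fold_change = unname(fc[mir[[i]]$id]), stringsAsFactors = FALSE)
  }
  mirna <- do.call(rbind, mir_rows)

  other_start <- starts[(n_mir + 1):n_loci]
  other <- data.frame(class = classes$class, start = other_start,
                      end = other_start + classes$len - 1L,
                      share = classes$share / config@n_other_loci_per_class,
                      stringsAsFactors = FALSE)

  ## --- annotation (GFF-style; novel hairpins deliberately absent) ------
  ann <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(mirna$pre_start[mirna$class == "known"], other$start),
                     c(mirna$pre_end[mirna$class == "known"], other$end)),
    strand = "+",
    type = c(rep("miRNA", sum(mirna$class == "known")), other$class),
    ID = c(mirna$id[mirna$class == "known"],
           paste0(other$class, "_", seq_len(nrow(other)))))
  loci <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(mirna$pre_start, other$start),
                     c(mirna$pre_end, other$end)),
    strand = "+",
    type = c(ifelse(mirna$class == "known", "miRNA", "novel_miRNA"),
             other$class),
    ID = c(mirna$id, paste0(other$class, "_", seq_len(nrow(other)))))

  ## --- references & families ------------------------------------------
  kn <- mirna[mirna$class == "known", ]
  mature_ref <- DNAStringSet(stats::setNames(kn$mature, kn$id))
  ## star references for a third of the knowns (star counting is exercised
  ## both with and without an annotated star)
  star_idx <- seq(1, nrow(kn), by = 3)
  star_ref <- DNAStringSet(stats::setNames(kn$star[star_idx],
                                           paste0(kn$id[star_idx], "*")))
  mature_ref <- c(mature_ref, star_ref)
  hairpin_ref <- DNAStringSet(stats::setNames(kn$precursor,
                                              sub("miR", "mir", kn$id)))
  fam <- data.frame(id = kn$id, family = NA_character_,
                    stringsAsFactors = FALSE)
  nfam <- min(4L, nrow(kn) %/% 5L)
  if (nfam > 0) {
    sizes <- rep_len(c(4L, 3L, 2L, 2L), nfam)
    at <- 1L
    for (f in seq_len(nfam)) {
      fam$family[at:(at + sizes[f] - 1L)] <- sprintf("mir-simfam-%d", f)
      at <- at + sizes[f]
    }
  }

  ## --- reads ------------------------------------------------------------
  libs <- names(config@library_sizes)
  reads <- list(); prov <- list()
  weights <- .mirnaWeights(mirna, config)
  gseq <- as.character(genome[[1]])
  windows <- .readWindows(gseq, other, loci, config)
  for (L in seq_along(libs)) {
    sim <- .simulateLibraryReads(gseq, mirna, weights[[L]], windows, config,
                                 lib_index = L, lib = libs[L])
    reads[[libs[L]]] <- sim$reads
    prov[[libs[L]]] <- sim$provenance
  }
  provenance <- do.call(rbind, prov)

  truth_counts <- .truthCounts(provenance, mirna, libs)

  list(genome = genome, annotation = ann, loci = loci, mirna = mirna,
       mature_ref = mature_ref, hairpin_ref = hairpin_ref, families = fam,
       reads = reads, provenance = provenance, truth_counts = truth_counts,
       config = config)
}

## per-library sampling weights over mature and star arms; mirrored baseline
## abundances for the up-/down-regulated sets keep the total miRNA mass equal
## in the two libraries, so planted probability ratios equal the fold changes
.mirnaWeights <- function(mirna, config) {
  n <- nrow(mirna)
  base <- stats::rlnorm(n, meanlog = 0, sdlog = 1.2)
  up <- which(mirna$fold_change > 1)
  dn <- which(mirna$fold_change < 1)
  k <- min(length(up), length(dn))
  if (k > 0) base[dn[seq_len(k)]] <- base[up[seq_len(k)]]
  w1 <- base * sqrt(mirna$fold_change)
  w2 <- base / sqrt(mirna$fold_change)
  lapply(list(w1, w2), function(w) {
    m <- w / sum(w)
    list(mature = m * (1 - config@star_share), star = m * config@star_share)
  })
}

## fixed read-source windows for non-miRNA classes, intergenic "unknown"
## windows, and their per-class shares
.readWindows <- function(gseq, other, loci, config) {
  win <- list()
  for (r in seq_len(nrow(other))) {
    cls <- other$class[r]
    for (k in 1:3) {
      wlen <- sample(19:26, 1)
      ws <- other$start[r] + sample.int(other$end[r] - other$start[r] -
                                          wlen, 1)
      strand <- "+"
      ## exercise antisense categories on gene-model classes
      if (cls %in% c("exon", "intron") && k == 3) strand <- "-"
      seq <- substr(gseq, ws, ws + wlen - 1)
      if (strand == "-") seq <- .revcomp(seq)
      if (!.insertClean(seq, config)) next
      label <- if (cls %in% c("exon", "intron"))
        paste0(cls, ifelse(strand == "+", "_sense", "_antisense")) else cls
      win[[length(win) + 1]] <- data.frame(class = label, seq = seq,
                                           stringsAsFactors = FALSE)
    }
  }
  ## intergenic windows (unknown category)
  occ <- loci
  tries <- 0
  while (sum(vapply(win, function(w) w$class[1] == "unknown", TRUE)) < 12 &&
         tries < 400) {
    tries <- tries + 1
    wlen <- sample(19:25, 1)
    ws <- sample.int(nchar(gseq) - wlen, 1)
    cand <- GenomicRanges::GRanges("chr1", IRanges::IRanges(ws, ws + wlen - 1))
    if (length(GenomicRanges::findOverlaps(cand, occ)) > 0) next
    seq <- substr(gseq, ws, ws + wlen - 1)
    if (!.insertClean(seq, config)) next
    win[[length(win) + 1]] <- data.frame(class = "unknown", seq = seq,
                                         stringsAsFactors = FALSE)
  }
  do.call(rbind, win)
}

## read-share per non-miRNA class (normalized to 1 - mirna share at use time)
.classShares <- function(windows) {
  cls2share <- c(stats::setNames(.OTHER_CLASSES$share, .OTHER_CLASSES$class),
                 exon_sense = NA, intron_sense = NA)
  shares <- c(rRNA = 0.50, tRNA = 0.065, snRNA = 0.006, snoRNA = 0.005,
              scRNA = 0.004, srpRNA = 0.008, "repeat" = 0.022,
              exon_sense = 0.019, exon_antisense = 0.001,
              intron_sense = 0.008, intron_antisense = 0.002,
              unknown = .UNKNOWN_SHARE, nomap = .NOMAP_SHARE)
  present <- intersect(names(shares), c(unique(windows$class), "nomap"))
  shares[present] / sum(shares[present])
}

.randomInserts <- function(n, len_range, config) {
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    repeat {
      s <- .randomSeq(sample(len_range[1]:len_range[2], 1), 0.45)
      if (.insertClean(s, config)) return(s)
    }
  }, "")
}

.simulateLibraryReads <- function(gseq, mirna, weights, windows, config,
                                  lib_index, lib) {
  N <- config@library_sizes[[lib_index]]
  if (N <= 0) stop("library size must be > 0")
  a3 <- config@adapter3
  tail5 <- substr(config@adapter5, nchar(config@adapter5) - 5,
                  nchar(config@adapter5))

  ## top-level composition
  p_filters <- c(a3null = config@a3null_rate, insert_null = config@insertnull_rate,
                 a5 = config@a5_rate, short = config@short_rate,
                 polyA = config@polyA_rate)
  p_clean <- 1 - sum(p_filters)
  share_mir <- config@mirna_read_share[lib_index]
  cls <- .classShares(windows)
  probs <- c(p_filters,
             mirna = p_clean * share_mir,
             p_clean * (1 - share_mir) * cls)
  names(probs) <- c(names(p_filters), "mirna", names(cls))
  counts <- stats::setNames(as.vector(stats::rmultinom(1, N, probs)),
                            names(probs))

  inserts <- character(0); labels <- character(0)
  mirna_id <- character(0); flag_iso <- logical(0); flag_edit <- logical(0)

  add <- function(ins, lab, id = NA_character_, iso = FALSE, ed = FALSE) {
    k <- length(ins)
    if (k == 0) return(invisible())
    inserts <<- c(inserts, ins)
    labels <<- c(labels, rep_len(lab, k))
    mirna_id <<- c(mirna_id, rep_len(id, k))
    flag_iso <<- c(flag_iso, rep_len(iso, k))
    flag_edit <<- c(flag_edit, rep_len(ed, k))
  }

  ## --- filter-category reads ------------------------------------------
  a5ins <- .randomInserts(counts[["a5"]], c(18, 24), config)
  if (length(a5ins)) a5ins <- paste0(tail5, a5ins)
  add(a5ins, "adaptor5_contaminants")
  add(.randomInserts(counts[["short"]], c(5, 17), config), "small_than_18nt")
  add(vapply(seq_len(counts[["polyA"]]), function(i)
        strrep("A", sample(18:24, 1)), character(1)), "polyA")
  add(rep("", counts[["insert_null"]]), "insert_null")

  ## --- miRNA reads ------------------------------------------------------
  n_mir_reads <- counts[["mirna"]]
  arm_w <- c(weights$mature, weights$star)
  arm_is_star <- rep(c(FALSE, TRUE), each = nrow(mirna))
  pick <- sample.int(length(arm_w), n_mir_reads, replace = TRUE, prob = arm_w)
  mir_idx <- ((pick - 1) %% nrow(mirna)) + 1
  is_star <- arm_is_star[pick]
  iso <- stats::runif(n_mir_reads) < config@isomir_rate
  edit <- stats::runif(n_mir_reads) < config@edit_rate
  seqs <- ifelse(is_star, mirna$star[mir_idx], mirna$mature[mir_idx])
  ## isomiR end shifts, 3'-biased, templated on the precursor where extending
  if (any(iso)) {
    for (r in which(iso)) {
      i <- mir_idx[r]
      span <- if (is_star[r])
        c(mirna$star_start[i], mirna$star_end[i]) - mirna$pre_start[i] + 1
      else
        c(mirna$mature_start[i], mirna$mature_end[i]) - mirna$pre_start[i] + 1
      pre <- mirna$precursor[i]
      at3 <- stats::runif(1) < 0.9
      sh <- sample(1:5, 1, prob = c(0.45, 0.3, 0.15, 0.07, 0.03))
      if (stats::runif(1) < 0.5) sh <- -sh  # trim vs extend
      if (at3) span[2] <- span[2] + sh else span[1] <- span[1] - sh
      span[1] <- max(1, span[1]); span[2] <- min(nchar(pre), span[2])
      if (span[2] - span[1] + 1 >= 16) seqs[r] <- substr(pre, span[1], span[2])
    }
  }
  ## base edits / untemplated 3' additions
  if (any(edit)) {
    for (r in which(edit)) {
      s <- seqs[r]
      if (stats::runif(1) < 0.7) {
        seqs[r] <- .mutateBase(s, sample.int(nchar(s), 1))
      } else {
        i <- mir_idx[r]
        pre <- mirna$precursor[i]
        endpos <- if (is_star[r]) mirna$star_end[i] else mirna$mature_end[i]
        nxt <- substr(pre, endpos - mirna$pre_start[i] + 2,
                      endpos - mirna$pre_start[i] + 2)
        choicebase <- setdiff(c("A", "T"), nxt)
        if (length(choicebase))
          seqs[r] <- paste0(s, sample(choicebase, 1))
        else seqs[r] <- .mutateBase(s, sample.int(nchar(s), 1))
      }
    }
  }
  if (n_mir_reads > 0) {
    lab <- ifelse(is_star, "mirna_star", "mirna")
    add(seqs, "placeholder")
    ## overwrite the placeholder block with per-read labels/ids/flags
    n_all <- length(inserts)
    blk <- (n_all - n_mir_reads + 1):n_all
    labels[blk] <- lab
    mirna_id[blk] <- mirna$id[mir_idx]
    flag_iso[blk] <- iso
    flag_edit[blk] <- edit
  }

  ## --- other-class reads ------------------------------------------------
  for (cl in names(cls)) {
    nk <- counts[[cl]]
    if (nk == 0) next
    if (cl == "nomap") {
      add(.randomInserts(nk, c(20, 24), config), "nomap")
    } else {
      ws <- windows[windows$class == cl, , drop = FALSE]
      pickw <- sample.int(nrow(ws), nk, replace = TRUE)
      add(ws$seq[pickw], cl)
    }
  }
  ## a3null reads are full-length random sequences with no adapter seed
  seed3 <- substr(a3, 1, 8)
  a3null <- vapply(seq_len(counts[["a3null"]]), function(i) {
    repeat {
      s <- .randomSeq(49, 0.45)
      if (!grepl(seed3, s, fixed = TRUE)) return(s)
    }
  }, character(1))

  ## --- sequencing errors on clean-category inserts ---------------------
  if (config@error_rate > 0 && length(inserts)) {
    wd <- nchar(inserts)
    nm <- stats::rbinom(length(inserts), wd, config@error_rate)
    for (r in which(nm > 0 & wd > 0)) {
      for (k in seq_len(nm[r]))
        inserts[r] <- .mutateBase(inserts[r], sample.int(wd[r], 1))
    }
  }

  ## --- assemble raw reads ----------------------------------------------
  reads_with_adapter <- paste0(inserts, a3)
  all_reads <- c(reads_with_adapter, a3null)
  all_labels <- c(labels, rep("adaptor3_null", length(a3null)))
  all_ids <- c(mirna_id, rep(NA_character_, length(a3null)))
  all_iso <- c(flag_iso, rep(FALSE, length(a3null)))
  all_edit <- c(flag_edit, rep(FALSE, length(a3null)))
  all_inserts <- c(inserts, rep(NA_character_, length(a3null)))
  ord <- sample.int(length(all_reads))
  provenance <- data.frame(library = lib, label = all_labels[ord],
                           mirna_id = all_ids[ord], isomir = all_iso[ord],
                           edited = all_edit[ord], insert = all_inserts[ord],
                           stringsAsFactors = FALSE)
  rd <- DNAStringSet(all_reads[ord])
  names(rd) <- sprintf("%s_read%07d", lib, seq_along(rd))
  list(reads = rd, provenance = provenance)
}

.truthCounts <- function(provenance, mirna, libs) {
  rows <- list()
  for (lib in libs) {
    pv <- provenance[provenance$library == lib &
                       provenance$label %in% c("mirna", "mirna_star"), ]
    for (id in mirna$id) {
      sel <- pv$mirna_id == id
      mat <- sel & pv$label == "mirna"
      rows[[length(rows) + 1]] <- data.frame(
        id = id, library = lib,
        exact_mature = sum(mat & !pv$isomir & !pv$edited),
        mature_reads = sum(mat),
        star_reads = sum(sel & pv$label == "mirna_star"),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Simulate a stem-loop qPCR Ct table
#'
#' Ct values follow `intercept - log2(abundance) + noise`; the reference
#' gene has constant unit abundance across samples, so downstream 2^-ddCt
#' against it recovers the planted abundance ratios. Triplicate wells are
#' emitted per (sample, gene).
#'
#' @param abundance Numeric matrix of true relative abundances, targets x
#'   samples (dimnames required); all values must be > 0.
#' @param reference_gene Name of the reference gene row to add.
#' @param intercept Ct at unit abundance.
#' @param noise_sd Gaussian Ct noise (cycles); 0 gives exact triplicates.
#' @param replicates Wells per (sample, gene).
#' @return data.frame with columns sample, gene, replicate, Ct.
#' @export
simulateQpcr <- function(abundance, reference_gene = "RPS18",
                         intercept = 30, noise_sd = 0.2, replicates = 3L) {
  if (any(abundance <= 0)) stop("abundances must be > 0")
  if (is.null(dimnames(abundance))) stop("abundance needs dimnames")
  ab <- rbind(abundance,
              matrix(1, 1, ncol(abundance),
                     dimnames = list(reference_gene, colnames(abundance))))
  rows <- expand.grid(gene = rownames(ab), sample = colnames(ab),
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ct <- intercept - log2(ab[cbind(rows$gene, rows$sample)]) +
    stats::rnorm(nrow(rows), 0, noise_sd)
  data.frame(sample = rows$sample, gene = rows$gene,
             replicate = rows$replicate, Ct = ct, stringsAsFactors = FALSE)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: returns a random sequence with exactly the
#' same dinucleotide (and hence mononucleotide) composition as the input.
#' Used to build negative-control genomes for novel-miRNA discovery.
#'
#' @param sequence Character scalar.
#' @return Shuffled character scalar.
#' @export
dinucleotideShuffle <- function(sequence) {
  s <- strsplit(toupper(sequence), "")[[1]]
  n <- length(s)
  if (n < 3) return(sequence)
  first <- s[1]; last <- s[n]
  succ <- split(s[-1], s[-n])  # successor (edge) lists per base
  verts <- names(succ)
  nonterm <- setdiff(verts, last)
  ## reserve one random terminal out-edge per non-terminal vertex such that
  ## the reserved edges form a tree pointing at the terminal base
  repeat {
    lastEdge <- vapply(nonterm, function(v)
      succ[[v]][sample.int(length(succ[[v]]), 1)], "")
    ok <- TRUE
    for (v in nonterm) {
      cur <- v; steps <- 0L
      while (cur != last && steps <= length(verts)) {
        cur <- lastEdge[[cur]]; steps <- steps + 1L
      }
      if (cur != last) { ok <- FALSE; break }
    }
    if (ok) break
  }
  pools <- list()
  for (v in verts) {
    rest <- succ[[v]]
    if (v %in% nonterm) {
      rest <- rest[-match(lastEdge[[v]], rest)]
      pools[[v]] <- c(rest[sample.int(length(rest))], lastEdge[[v]])
    } else {
      pools[[v]] <- rest[sample.int(length(rest))]
    }
  }
  out <- character(n); out[1] <- first
  idx <- stats::setNames(rep(1L, length(verts)), verts)
  cur <- first
  for (i in 2:n) {
    nxt <- pools[[cur]][idx[[cur]]]
    idx[[cur]] <- idx[[cur]] + 1L
    out[i] <- nxt
    cur <- nxt
  }
  paste(out, collapse = "")
}
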