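## Novel miRNA discovery: flank extraction, folding, hairpin screening
## criteria, and genome-wide candidate discovery from unannotated tags.

#' Extract the genomic window around a tag hit
#'
#' Returns up to `flank` nt on each side of the hit plus the tag itself,
#' clipped at chromosome ends and strand-oriented (minus-strand windows are
#' reverse-complemented so the tag reads 5'->3' inside the window).
#'
#' @param hit A single-range GRanges (one hit from [mapTags()]).
#' @param genome DNAStringSet.
#' @param flank Flank size in nt (default 150).
#' @param flank5,flank3 Optional asymmetric flank sizes, given relative to
#'   the tag's 5'/3' ends (defaults: `flank` on both sides).
#' @return List with `sequence`, `tag_start`, `tag_end` (1-based within the
#'   window), and the genomic `window_start`/`window_end`.
#' @export
extractFlanks <- function(hit, genome, flank = 150L, flank5 = NULL,
                          flank3 = NULL) {
  if (is.null(flank5)) flank5 <- flank
  if (is.null(flank3)) flank3 <- flank
  chr <- as.character(GenomicRanges::seqnames(hit))[1]
  if (!chr %in% names(genome)) stop("hit outside genome bounds")
  glen <- Biostrings::width(genome)[match(chr, names(genome))]
  s <- GenomicRanges::start(hit)[1]; e <- GenomicRanges::end(hit)[1]
  if (s < 1 || e > glen) stop("hit outside genome bounds")
  minus <- as.character(GenomicRanges::strand(hit))[1] == "-"
  left <- if (minus) flank3 else flank5    # genomic left of the hit
  right <- if (minus) flank5 else flank3
  ws <- max(1L, s - left); we <- min(glen, e + right)
  seq <- as.character(Biostrings::subseq(genome[[chr]], ws, we))
  if (minus) {
    seq <- .revcomp(seq)
    tag_start <- we - e + 1L
  } else {
    tag_start <- s - ws + 1L
  }
  list(sequence = seq, tag_start = tag_start,
       tag_end = tag_start + (e - s), window_start = ws, window_end = we)
}

#' Default novel-miRNA screening parameters
#'
#' The hairpin criteria: the mature tag must sit wholly in one arm of a
#' single stem-loop with no loop overlap and no break (its paired partners
#' on one side, in order); mature:star hybridization free energy below
#' -20 kcal/mol; precursor MFEI above 0.85;
#' precursor AU content within 30-70%; fewer than `max_star_mismatch`
#' unpaired mature bases against the star region (bulges count per base);
#' mature length within `mature_len_range`. Tags with more than
#' `max_genome_hits` perfect genome hits are excluded before evaluation.
#'
#' @return Named list of parameters.
#' @export
novelParams <- function() {
  list(mfe_max = -20, mfei_min = 0.85, au_range = c(0.3, 0.7),
       max_star_mismatch = 6L, mature_len_range = c(20L, 22L),
       max_genome_hits = 10L, cluster_gap = 30L, flank = 150L,
       min_reads = 2L)
}

#' Evaluate a candidate hairpin against the screening criteria
#'
#' Folds the window (unless a structure is supplied), then checks, in order:
#' (a) the mature sits wholly within one arm of a hairpin — every paired
#' mature base pairs to the same side, partner positions run monotonically
#' (no break), the mature does not overlap the hairpin loop, and the
#' trimmed precursor is a single stem-loop (exactly one hairpin loop, no
#' multiloop branch); (e) the
#' number of unpaired mature bases (mismatches against the star region,
#' bulges counted per base) is below `max_star_mismatch`; (b) the
#' hybridization free energy of the mature:star duplex (stack terms of the
#' mature's helix plus interior/bulge penalties at its gaps, under the
#' folding energy model) is below `mfe_max`; the precursor is
#' then trimmed to the minimal stem-loop spanning mature and star before
#' computing (c) MFEI > `mfei_min` and (d) AU content
#' within `au_range`; (f) mature length within `mature_len_range`. Overall
#' pass requires (a)-(f); an observed star (criterion g) upgrades the
#' confidence class but is not required.
#'
#' @param window Window sequence containing the candidate.
#' @param tag_start,tag_end Mature candidate span within `window` (1-based).
#' @param structure,mfe Optional pre-computed fold of `window`.
#' @param star_observed Whether a star-arm tag was seen in the data.
#' @param params Screening parameters, see [novelParams()].
#' @param mature_len_range Override of the mature length bounds.
#' @return List: `pass`, per-criterion logical `criteria`, `confidence`
#'   ("high" with observed star, else "candidate"), `precursor` (trimmed
#'   sequence), `precursor_structure`, `mfe`, `amfe`, `mfei`, `au_content`,
#'   `star_mismatches`, `arm`, `star_start`/`star_end` (window coords), and
#'   `precursor_span`.
#' @export
evaluateCandidate <- function(window, tag_start, tag_end, structure = NULL,
                              mfe = NULL, star_observed = FALSE,
                              params = novelParams(),
                              mature_len_range = NULL) {
  if (is.null(mature_len_range)) mature_len_range <- params$mature_len_range
  if (is.null(structure)) {
    f <- foldRNA(window)
    structure <- f$structure; mfe <- f$mfe
  }
  if (nchar(structure) != nchar(window))
    stop("structure/sequence length mismatch")
  pt <- pairTable(structure)
  a <- tag_start; b <- tag_end
  mlen <- b - a + 1L

  crit <- c(hairpin = FALSE, mfe = FALSE, mfei = FALSE, au = FALSE,
            star_mismatch = FALSE, mature_len = FALSE)
  res <- list(pass = FALSE, criteria = crit, confidence = "rejected",
              precursor = NA_character_, precursor_structure = NA_character_,
              mfe = NA_real_, duplex_energy = NA_real_, amfe = NA_real_,
              mfei = NA_real_,
              au_content = NA_real_, star_mismatches = NA_integer_,
              arm = NA_character_, star_start = NA_integer_,
              star_end = NA_integer_, precursor_span = c(NA, NA))

  crit["mature_len"] <- mlen >= mature_len_range[1] &&
    mlen <= mature_len_range[2]

  partners <- pt[a:b]
  paired <- partners != 0
  ## (e) mismatches: unpaired mature positions (bulges count per base)
  mm <- sum(!paired)
  res$star_mismatches <- mm
  crit["star_mismatch"] <- mm < params$max_star_mismatch

  ## (a) one arm, no loop overlap, no break
  if (any(paired)) {
    pp <- partners[paired]
    on3 <- all(pp > b); on5 <- all(pp < a)
    monotone <- if (on3) all(diff(pp) < 0) else if (on5) all(diff(pp) < 0)
                else FALSE
    crit["hairpin"] <- (on3 || on5) && monotone
    if (crit["hairpin"]) {
      res$arm <- if (on3) "5p" else "3p"
      res$star_start <- min(pp); res$star_end <- max(pp)
      ## (b) hybridization energy of the mature:star duplex
      s <- strsplit(.baseCode(window), "")[[1]]
      em <- foldingParams()
      mpos <- (a:b)[paired]
      dup <- 0
      if (length(mpos) > 1) {
        for (t in seq_len(length(mpos) - 1)) {
          i1 <- mpos[t]; i2 <- mpos[t + 1]
          j1 <- pt[i1]; j2 <- pt[i2]
          if (i2 - i1 == 1 && abs(j1 - j2) == 1) {
            dup <- dup - (.pairStrength(s[i1], s[j1], em) +
                          .pairStrength(s[i2], s[j2], em)) / 2
          } else {
            dup <- dup + em[["interior0"]] +
              em[["interior1"]] * ((i2 - i1 - 1) + (abs(j1 - j2) - 1))
          }
        }
      }
      res$duplex_energy <- dup
      crit["mfe"] <- dup < params$mfe_max
      ## minimal stem-loop containing mature and star
      span <- c(min(a, res$star_start), max(b, res$star_end))
      keep <- pt
      inside <- seq(span[1], span[2])
      for (i in inside) {
        if (keep[i] != 0 && (keep[i] < span[1] || keep[i] > span[2])) {
          keep[keep[i]] <- 0L; keep[i] <- 0L
        }
      }
      sub_pt <- keep[inside] - span[1] + 1L
      sub_pt[sub_pt < 0] <- 0L
      ## an appropriate pre-miRNA hairpin is a single stem-loop: exactly one
      ## hairpin loop and no multiloop branching within the trimmed span
      nhair <- 0L; nmulti <- 0L
      for (i in which(sub_pt > seq_along(sub_pt))) {
        j <- sub_pt[i]; nch <- 0L; k <- i + 1L
        while (k < j) {
          if (sub_pt[k] > k && sub_pt[k] < j) { nch <- nch + 1L
            k <- sub_pt[k] + 1L } else k <- k + 1L
        }
        if (nch == 0L) nhair <- nhair + 1L
        if (nch >= 2L) nmulti <- nmulti + 1L
      }
      crit["hairpin"] <- nhair == 1L && nmulti == 0L
      pre <- substr(window, span[1], span[2])
      pre_mfe <- structureEnergy(pre, sub_pt)
      res$precursor <- pre
      res$precursor_structure <- paste(
        ifelse(sub_pt == 0, ".",
               ifelse(sub_pt > seq_along(sub_pt), "(", ")")), collapse = "")
      res$mfe <- pre_mfe
      res$precursor_span <- span
      mx <- tryCatch(computeMFEI(min(pre_mfe, 0), pre),
                     error = function(e) list(amfe = NA, mfei = NA))
      res$amfe <- mx$amfe; res$mfei <- mx$mfei
      res$au_content <- auContent(pre)
      crit["mfei"] <- !is.na(mx$mfei) && mx$mfei > params$mfei_min
      crit["au"] <- res$au_content >= params$au_range[1] &&
        res$au_content <= params$au_range[2]
    }
  }
  res$criteria <- crit
  res$pass <- all(crit)
  if (res$pass) res$confidence <- if (star_observed) "high" else "candidate"
  res
}

#' Shuffled-genome negative control for novel discovery
#'
#' Builds a dinucleotide-preserving shuffle of the genome, draws tag
#' sequences from random windows of the shuffled genome (so that tags map,
#' at a density matching a study's unannotated clusters), and runs
#' [discoverNovel()]. Any accepted candidate is a false positive of the
#' screening criteria, since the shuffle destroys all planted hairpins while
#' preserving composition.
#'
#' @param genome DNAStringSet (the study genome).
#' @param n_windows Number of source windows for control tags.
#' @param params Screening parameters.
#' @return The [discoverNovel()] result on the control.
#' @export
shuffledGenomeControl <- function(genome, n_windows = 25L,
                                  params = novelParams()) {
  g2 <- dinucleotideShuffle(as.character(genome[[1]]))
  genome2 <- DNAStringSet(stats::setNames(g2, names(genome)[1]))
  idx <- buildGenomeIndex(genome2)
  ws <- sample.int(nchar(g2) - 30L, n_windows)
  wl <- sample(20:22, n_windows, replace = TRUE)
  tags <- unique(substring(g2, ws, ws + wl - 1L))
  cnt <- matrix(sample(2:50, length(tags), replace = TRUE), ncol = 1,
                dimnames = list(NULL, "control"))
  discoverNovel(TagSet(tags, cnt), idx, genome2, params)
}

## merge tag hits into candidate clusters: intervals on the same strand
## overlapping or within `gap` nt are one cluster
.clusterHits <- function(hits, gap) {
  red <- GenomicRanges::reduce(hits, min.gapwidth = gap + 1L,
                               ignore.strand = FALSE, with.revmap = TRUE)
  red
}

#' Discover novel miRNA candidates from unannotated tags
#'
#' Implements the discovery screen: tags with more than
#' `params$max_genome_hits` perfect genome hits are removed; remaining hits
#' are clustered by genomic window (same strand, within
#' `params$cluster_gap` nt); each cluster's most abundant tag becomes the
#' mature candidate, its flanked window is folded and evaluated with
#' [evaluateCandidate()]; accepted candidates are reported with per-library
#' counts, per-library presence lists and their intersection. A candidate
#' whose star-arm sequence is also observed in the tag data is flagged
#' high-confidence.
#'
#' @param leftover A [TagSet-class] of tags already stripped of known
#'   miRNA/ncRNA matches.
#' @param index GenomeIndex from [buildGenomeIndex()].
#' @param genome DNAStringSet (the same genome).
#' @param params Screening parameters, see [novelParams()].
#' @return List with `novel` (data.frame, one row per accepted candidate:
#'   id, locus, mature, precursor, structure, mfe, amfe, mfei, au_content,
#'   confidence, per-library counts), `per_library` (list of id vectors),
#'   `overlap` (ids present in every library), and `n_evaluated`.
#' @export
discoverNovel <- function(leftover, index, genome, params = novelParams()) {
  counts <- tagCounts(leftover)
  libs <- colnames(counts)
  empty <- data.frame()
  if (length(leftover) == 0)
    return(list(novel = empty, per_library = stats::setNames(
      rep(list(character(0)), length(libs)), libs),
      overlap = character(0), n_evaluated = 0L))

  mp <- mapTags(leftover, index)
  hits <- mp$hits
  if (length(hits) == 0)
    return(list(novel = empty, per_library = stats::setNames(
      rep(list(character(0)), length(libs)), libs),
      overlap = character(0), n_evaluated = 0L))

  ## remove tags with too many genome hits
  nh <- table(hits$tag_id)
  multi <- as.integer(names(nh)[nh > params$max_genome_hits])
  hits <- hits[!hits$tag_id %in% multi]
  if (length(hits) == 0)
    return(list(novel = empty, per_library = stats::setNames(
      rep(list(character(0)), length(libs)), libs),
      overlap = character(0), n_evaluated = 0L))

  tag_reads <- rowSums(counts)
  clusters <- .clusterHits(hits, params$cluster_gap)
  seqs <- as.character(tagSequences(leftover))

  rows <- list(); n_eval <- 0L
  for (ci in seq_along(clusters)) {
    members <- clusters$revmap[[ci]]
    ctags <- hits$tag_id[members]
    cluster_reads <- sum(tag_reads[unique(ctags)])
    if (cluster_reads < params$min_reads) next
    ## most abundant tag is the mature candidate
    best_tag <- unique(ctags)[which.max(tag_reads[unique(ctags)])]
    bh <- hits[members][hits$tag_id[members] == best_tag][1]
    if (Biostrings::width(bh) < params$mature_len_range[1] ||
        Biostrings::width(bh) > params$mature_len_range[2]) next
    n_eval <- n_eval + 1L
    ## scan a ladder of windows around the tag: the full flanked window
    ## first, then smaller and one-sided windows, since a hairpin's star
    ## arm lies close on one side and distant flanks can bury the fold
    geometries <- list(c(params$flank, params$flank), c(80L, 80L),
                       c(50L, 50L), c(15L, 60L), c(60L, 15L),
                       c(15L, 45L), c(45L, 15L), c(100L, 20L),
                       c(20L, 100L))
    ev <- NULL; fl <- NULL
    for (gm in geometries) {
      fl_try <- extractFlanks(bh, genome, flank5 = gm[1], flank3 = gm[2])
      ev_try <- evaluateCandidate(fl_try$sequence, fl_try$tag_start,
                                  fl_try$tag_end, params = params)
      if (is.null(ev)) { ev <- ev_try; fl <- fl_try }
      if (ev_try$pass) { ev <- ev_try; fl <- fl_try; break }
    }
    if (!ev$pass) next
    ## star observed? look for a tag matching the star region (+- 2 nt)
    star_seq <- substr(fl$sequence, ev$star_start, ev$star_end)
    star_obs <- any(vapply(seqs[unique(ctags)], function(s)
      s != seqs[best_tag] &&
        (grepl(s, star_seq, fixed = TRUE) ||
         grepl(star_seq, s, fixed = TRUE)), TRUE))
    strand <- as.character(GenomicRanges::strand(bh))
    chrom <- as.character(GenomicRanges::seqnames(bh))
    lib_counts <- colSums(counts[unique(ctags), , drop = FALSE])
    ## genomic span of the trimmed precursor (window is strand-oriented)
    sp <- ev$precursor_span
    if (strand == "+") {
      pre_start <- fl$window_start + sp[1] - 1L
      pre_end <- fl$window_start + sp[2] - 1L
    } else {
      pre_start <- fl$window_end - sp[2] + 1L
      pre_end <- fl$window_end - sp[1] + 1L
    }
    row <- data.frame(
      chrom = chrom, strand = strand,
      pre_start = pre_start, pre_end = pre_end,
      start = GenomicRanges::start(bh), end = GenomicRanges::end(bh),
      mature = seqs[best_tag], precursor = ev$precursor,
      structure = ev$precursor_structure, mfe = ev$mfe,
      duplex_energy = ev$duplex_energy, amfe = ev$amfe,
      mfei = ev$mfei, au_content = ev$au_content,
      star_mismatches = ev$star_mismatches, arm = ev$arm,
      confidence = if (star_obs) "high" else "candidate",
      stringsAsFactors = FALSE)
    for (lib in libs) row[[paste0("count_", lib)]] <- lib_counts[[lib]]
    rows[[length(rows) + 1]] <- row
  }
  if (!length(rows))
    return(list(novel = empty, per_library = stats::setNames(
      rep(list(character(0)), length(libs)), libs),
      overlap = character(0), n_evaluated = n_eval))
  novel <- do.call(rbind, rows)
  ## one miRNA per genomic locus: candidates whose precursor spans overlap
  ## (either strand: a hairpin's reverse complement is the same hairpin)
  ## collapse to the most abundant; identical matures found at several
  ## loci also collapse to one miRNA
  tot <- rowSums(novel[, paste0("count_", libs), drop = FALSE])
  ord <- order(-tot)
  kept <- integer(0)
  for (i in ord) {
    gr_i <- GenomicRanges::GRanges(novel$chrom[i],
      IRanges::IRanges(novel$pre_start[i], novel$pre_end[i]))
    if (length(kept)) {
      gr_k <- GenomicRanges::GRanges(novel$chrom[kept],
        IRanges::IRanges(novel$pre_start[kept], novel$pre_end[kept]))
      if (length(GenomicRanges::findOverlaps(gr_i, gr_k)) > 0) next
    }
    kept <- c(kept, i)
  }
  novel <- novel[sort(kept), , drop = FALSE]
  novel <- novel[!duplicated(novel$mature), , drop = FALSE]
  novel$id <- sprintf("miRn%d", seq_len(nrow(novel)))
  per_library <- lapply(libs, function(lib)
    novel$id[novel[[paste0("count_", lib)]] > 0])
  names(per_library) <- libs
  overlap <- Reduce(intersect, per_library)
  list(novel = novel, per_library = per_library, overlap = overlap,
       n_evaluated = n_eval)
}
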