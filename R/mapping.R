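## Perfect-match mapping of tags to the genome and priority-based category
## annotation.

#' Build a genome index for exact tag matching
#'
#' The index answers exact full-length match queries on both strands. Tags
#' are matched with `Biostrings::matchPDict` grouped by tag width (the
#' grouping happens at query time; the object holds the sequences).
#'
#' @param genome A DNAStringSet or path to a genome FASTA.
#' @return An object of class `GenomeIndex`.
#' @export
buildGenomeIndex <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0)
    stop("empty genome")
  names(genome) <- sub("\\s.*$", "", names(genome))
  structure(list(genome = genome), class = "GenomeIndex")
}

#' @export
print.GenomeIndex <- function(x, ...) {
  cat("GenomeIndex:", length(x$genome), "sequence(s),",
      sum(Biostrings::width(x$genome)), "bp total\n")
  invisible(x)
}

#' Map tags to the genome (perfect matches only, both strands)
#'
#' Every reported hit satisfies: the genome substring (reverse-complemented
#' for minus-strand hits) equals the tag exactly. Hit lists are exhaustive.
#'
#' @param tags A [TagSet-class] or character vector of tag sequences.
#' @param index A GenomeIndex from [buildGenomeIndex()].
#' @return List with `hits` (a [GenomicRanges::GRanges] with metadata
#'   columns `tag_id` (index into the tag set) and `tag` (sequence)) and
#'   `unmatched` (integer indices of tags with no perfect hit).
#' @export
mapTags <- function(tags, index) {
  seqs <- if (is(tags, "TagSet")) as.character(tagSequences(tags)) else
    toupper(chartr("Uu", "Tt", tags))
  if (length(seqs) == 0)
    return(list(hits = GenomicRanges::GRanges(), unmatched = integer(0)))
  genome <- index$genome
  widths <- nchar(seqs)
  out <- vector("list", 0)
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    fwd <- DNAStringSet(seqs[idx])
    rev <- Biostrings::reverseComplement(fwd)
    pd_f <- Biostrings::PDict(fwd)
    pd_r <- Biostrings::PDict(rev)
    for (chr in names(genome)) {
      subject <- genome[[chr]]
      for (strand in c("+", "-")) {
        pd <- if (strand == "+") pd_f else pd_r
        m <- Biostrings::matchPDict(pd, subject)
        starts <- Biostrings::startIndex(m)
        nh <- lengths(starts)
        if (sum(nh) == 0) next
        tag_id <- rep(idx, nh)
        st <- unlist(starts[nh > 0], use.names = FALSE)
        out[[length(out) + 1]] <- data.frame(
          chrom = chr, start = st, end = st + w - 1L, strand = strand,
          tag_id = tag_id, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(list(hits = GenomicRanges::GRanges(),
                unmatched = seq_along(seqs)))
  df <- do.call(rbind, out)
  hits <- GenomicRanges::GRanges(df$chrom,
    IRanges::IRanges(df$start, df$end), strand = df$strand,
    tag_id = df$tag_id, tag = seqs[df$tag_id])
  hits <- GenomicRanges::sort(hits, ignore.strand = TRUE)
  list(hits = hits, unmatched = setdiff(seq_along(seqs),
                                        unique(df$tag_id)))
}

## map a raw class label + relative strand to the reporting category
.hitCategory <- function(type, same_strand) {
  ifelse(type == "exon", ifelse(same_strand, "exon_sense", "exon_antisense"),
  ifelse(type == "intron",
         ifelse(same_strand, "intron_sense", "intron_antisense"), type))
}

#' Annotate genome-matched tags into RNA categories
#'
#' Each genome-matched tag receives exactly one category using the fixed
#' priority miRNA > rRNA > tRNA > snRNA > snoRNA > scRNA > srpRNA > repeat >
#' exon_sense > exon_antisense > intron_sense > intron_antisense > unknown.
#' A hit is "in" a locus when it overlaps by at least `min_overlap` bp;
#' sense/antisense is decided by strand agreement between hit and gene. A
#' tag with hits in several categories gets the highest-priority one (read
#' counts are not split), keeping the category partition exact.
#'
#' @param hits GRanges of perfect hits from [mapTags()].
#' @param annotation GRanges with a `type` metadata column over the classes
#'   miRNA, rRNA, tRNA, snRNA, snoRNA, scRNA, srpRNA, repeat, exon, intron
#'   (or a path to a GFF3/BED file of such loci).
#' @param tags The [TagSet-class] the hits refer to.
#' @param min_overlap Minimum overlap in bp (default 1).
#' @return List with `assignment` (data.frame: tag_id, category) and
#'   `summary` (one [CategorySummary-class] per library).
#' @export
annotateTags <- function(hits, annotation, tags, min_overlap = 1L) {
  if (is.character(annotation)) annotation <- readAnnotation(annotation)
  known_classes <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                     "srpRNA", "repeat", "exon", "intron")
  bad <- setdiff(unique(annotation$type), known_classes)
  if (length(bad))
    stop("interval with unknown class label: ", paste(bad, collapse = ", "))

  tag_ids <- sort(unique(hits$tag_id))
  category <- rep("unknown", length(tag_ids))
  names(category) <- as.character(tag_ids)
  if (length(hits) && length(annotation)) {
    ov <- GenomicRanges::findOverlaps(hits, annotation,
                                      minoverlap = min_overlap,
                                      ignore.strand = TRUE)
    if (length(ov)) {
      h <- S4Vectors::queryHits(ov); a <- S4Vectors::subjectHits(ov)
      same <- as.character(GenomicRanges::strand(hits))[h] ==
        as.character(GenomicRanges::strand(annotation))[a]
      cat_hit <- .hitCategory(as.character(annotation$type)[a], same)
      prio <- match(cat_hit, .CATEGORY_PRIORITY)
      dfo <- data.frame(tag = hits$tag_id[h], prio = prio)
      best <- tapply(dfo$prio, dfo$tag, min)
      category[names(best)] <- .CATEGORY_PRIORITY[best]
    }
  }
  assignment <- data.frame(tag_id = tag_ids,
                           category = unname(category),
                           stringsAsFactors = FALSE)

  counts <- tagCounts(tags)
  summaries <- lapply(libraryNames(tags), function(lib) {
    w <- counts[, lib]
    present <- w[assignment$tag_id] > 0
    uq <- vapply(.CATEGORY_PRIORITY, function(cl)
      sum(assignment$category == cl & present), 0)
    rd <- vapply(.CATEGORY_PRIORITY, function(cl)
      sum(w[assignment$tag_id[assignment$category == cl]]), 0)
    CategorySummary(lib, uq, rd)
  })
  names(summaries) <- libraryNames(tags)
  list(assignment = assignment, summary = summaries)
}

#' Read a locus annotation from GFF3 or BED
#'
#' GFF3 `type` column (or the BED name field) carries the RNA class.
#' Coordinates are handled by rtracklayer, so BED's 0-based half-open
#' convention is converted at the boundary.
#'
#' @param path GFF3 (.gff/.gff3) or BED file.
#' @return GRanges with a `type` column.
#' @export
readAnnotation <- function(path) {
  gr <- rtracklayer::import(path)
  if (is.null(gr$type) && !is.null(gr$name)) gr$type <- gr$name
  gr
}

#' Write a locus annotation as GFF3
#' @param annotation GRanges with `type` (and optionally `ID`).
#' @param path Output path.
#' @export
writeAnnotation <- function(annotation, path) {
  if (is.null(annotation$source)) annotation$source <- "mirpipe"
  rtracklayer::export(annotation, path, format = "gff3")
}
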