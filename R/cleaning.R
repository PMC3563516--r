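## Read cleaning: adapter trimming, filter ledger, tag collapsing.

#' Clean raw small-RNA reads into unique tags
#'
#' Assigns every parseable read to exactly one ledger category, in this fixed
#' priority: no 3' adapter found, empty insert, 5'-adapter contamination,
#' shorter than `min_len`, poly-A, clean. The 3' adapter is located by exact
#' match of its first `seed_len` bases anywhere in the read; a read whose
#' trimmed insert begins with the last `contam_len` bases of the 5' adapter
#' is a 5' contaminant; an insert with at least `polyA_frac` A is poly-A.
#' Clean inserts are collapsed to unique tags with counts. All parseable
#' input reads count as high-quality (no quality model).
#'
#' @param reads A [Biostrings::DNAStringSet] of raw reads, or a path to a
#'   FASTQ file, or a character vector.
#' @param adapter3,adapter5 Adapter sequences (non-empty).
#' @param min_len Minimum insert length in nt (default 18).
#' @param library Library identifier for the ledger.
#' @param seed_len 3' adapter seed length used for matching.
#' @param contam_len Length of the 5'-adapter suffix tested at insert starts.
#' @param polyA_frac Minimum A fraction for the poly-A filter.
#' @return List with `tags` (a single-library [TagSet-class] of clean
#'   inserts) and `summary` (a [CleaningSummary-class]).
#' @export
cleanReads <- function(reads, adapter3, adapter5, min_len = 18L,
                       library = "library1", seed_len = 8L, contam_len = 6L,
                       polyA_frac = 0.8) {
  if (!nzchar(adapter3) || !nzchar(adapter5)) stop("adapters must be non-empty")
  if (is.character(reads) && length(reads) == 1 && file.exists(reads))
    reads <- Biostrings::readDNAStringSet(reads, format = "fastq")
  seqs <- toupper(chartr("Uu", "Tt", as.character(reads)))
  if (length(seqs) && any(grepl("[^ACGTN]", seqs)))
    stop("unparseable read record at line ",
         4L * (which(grepl("[^ACGTN]", seqs))[1] - 1L) + 2L)

  n <- length(seqs)
  seed3 <- substr(toupper(adapter3), 1, seed_len)
  tail5 <- substr(toupper(adapter5), nchar(adapter5) - contam_len + 1L,
                  nchar(adapter5))

  hit <- regexpr(seed3, seqs, fixed = TRUE)
  has_adapter <- hit > 0
  insert <- ifelse(has_adapter, substr(seqs, 1, hit - 1L), NA_character_)

  category <- character(n)
  category[!has_adapter] <- "adaptor3_null"
  open <- has_adapter
  sel <- open & !is.na(insert) & insert == ""
  category[sel] <- "insert_null"; open <- open & !sel
  sel <- open & startsWith(insert, tail5)
  category[sel] <- "adaptor5_contaminants"; open <- open & !sel
  sel <- open & nchar(insert) < min_len
  category[sel] <- "small_than_18nt"; open <- open & !sel
  nA <- nchar(insert) - nchar(gsub("A", "", insert, fixed = TRUE))
  sel <- open & (nA / pmax(nchar(insert), 1L) >= polyA_frac)
  sel[is.na(sel)] <- FALSE
  category[sel] <- "polyA"; open <- open & !sel
  category[open] <- "clean"

  summary <- CleaningSummary(
    library = library, total_read = n, high_quality = n,
    adaptor3_null = sum(category == "adaptor3_null"),
    insert_null = sum(category == "insert_null"),
    adaptor5_contaminants = sum(category == "adaptor5_contaminants"),
    small_than_18nt = sum(category == "small_than_18nt"),
    polyA = sum(category == "polyA"))

  cl <- .collapseTags(insert[category == "clean"])
  counts <- matrix(cl$count, ncol = 1, dimnames = list(NULL, library))
  tags <- TagSet(cl$sequence, counts)
  list(tags = tags, summary = summary, category = category)
}

#' Merge per-library TagSets into one multi-library TagSet
#'
#' @param ... Single- or multi-library [TagSet-class] objects.
#' @return A [TagSet-class] whose count matrix has one column per input
#'   library; tags absent from a library get count 0.
#' @export
mergeTagSets <- function(...) {
  sets <- list(...)
  allseq <- unique(unlist(lapply(sets, function(s)
    as.character(tagSequences(s)))))
  libs <- unlist(lapply(sets, libraryNames))
  if (anyDuplicated(libs)) stop("duplicate library names")
  counts <- matrix(0L, length(allseq), length(libs),
                   dimnames = list(NULL, libs))
  for (s in sets) {
    idx <- match(as.character(tagSequences(s)), allseq)
    counts[idx, libraryNames(s)] <- tagCounts(s)
  }
  TagSet(allseq, counts)
}

#' Length distribution of a tag set
#'
#' Read-count-weighted histogram of insert lengths, the standard
#' small-RNA-library length profile (typically peaking at 22 nt for
#' miRNA-rich libraries).
#'
#' @param tags A [TagSet-class].
#' @param library Optional library name; default sums over all libraries.
#' @return data.frame with columns `length`, `reads`, `fraction` covering
#'   the observed length range; fractions sum to 1.
#' @export
lengthDistribution <- function(tags, library = NULL) {
  if (length(tags) == 0) stop("empty tag set")
  counts <- tagCounts(tags)
  w <- if (is.null(library)) rowSums(counts) else counts[, library]
  len <- Biostrings::width(tagSequences(tags))
  bins <- seq(min(len), max(len))
  reads <- vapply(bins, function(b) sum(w[len == b]), 0)
  data.frame(length = bins, reads = reads, fraction = reads / sum(reads))
}

#' Read a pre-collapsed FASTA of tags
#'
#' Accepts the conventional `>id_xCOUNT` header form for collapsed reads.
#'
#' @param path FASTA file path.
#' @param library Library identifier.
#' @return A single-library [TagSet-class].
#' @export
readCollapsedFasta <- function(path, library = "library1") {
  x <- Biostrings::readDNAStringSet(path)
  cnt <- suppressWarnings(as.integer(sub(".*_x(\\d+)$", "\\1", names(x))))
  if (anyNA(cnt)) stop("headers must end in _xCOUNT")
  counts <- matrix(cnt, ncol = 1, dimnames = list(NULL, library))
  TagSet(as.character(x), counts)
}

#' Write a TagSet as a collapsed FASTA
#'
#' @param tags A [TagSet-class].
#' @param path Output path.
#' @param library Library whose counts go into the `_xCOUNT` suffix
#'   (default: sum over libraries).
#' @export
writeCollapsedFasta <- function(tags, path, library = NULL) {
  counts <- tagCounts(tags)
  w <- if (is.null(library)) rowSums(counts) else counts[, library]
  x <- tagSequences(tags)
  names(x) <- sprintf("tag%06d_x%d", seq_along(x), w)
  Biostrings::writeXStringSet(x, path)
}
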