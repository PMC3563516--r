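#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importFrom Biostrings DNAStringSet DNAString reverseComplement
#' @useDynLib mirpipe, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Fixed ledger category order, mirroring the standard cleaning summary layout.
.LEDGER_FIELDS <- c("total_read", "high_quality", "adaptor3_null", "insert_null",
                    "adaptor5_contaminants", "small_than_18nt", "polyA",
                    "clean_reads")
.LEDGER_FILTERS <- c("adaptor3_null", "insert_null", "adaptor5_contaminants",
                     "small_than_18nt", "polyA")

## Fixed annotation categories and their priority (highest first) used when a
## tag overlaps several locus classes.
.CATEGORY_PRIORITY <- c("miRNA", "rRNA", "tRNA", "snRNA", "snoRNA", "scRNA",
                        "srpRNA", "repeat", "exon_sense", "exon_antisense",
                        "intron_sense", "intron_antisense", "unknown")

#' TagSet: unique small-RNA tags with per-library read counts
#'
#' The pipeline's atomic data container: a set of unique trimmed insert
#' sequences (the "tags") together with a tag-by-library count matrix.
#' Sequences are stored as DNA (T rather than U); input U is normalized to T.
#'
#' @slot sequences A [Biostrings::DNAStringSet] of unique tag sequences.
#' @slot counts Integer matrix, one row per tag, one column per library.
#' @export
setClass("TagSet",
         representation(sequences = "DNAStringSet", counts = "matrix"))

setValidity("TagSet", function(object) {
  msg <- character()
  if (length(object@sequences) != nrow(object@counts))
    msg <- c(msg, "number of sequences and count rows differ")
  if (any(object@counts < 0)) msg <- c(msg, "negative counts")
  if (anyDuplicated(as.character(object@sequences)))
    msg <- c(msg, "duplicate tag sequences")
  if (length(object@sequences) && any(Biostrings::width(object@sequences) < 1))
    msg <- c(msg, "zero-length tag")
  if (is.null(colnames(object@counts)))
    msg <- c(msg, "count columns must be named by library")
  if (length(msg)) msg else TRUE
})

#' Construct a TagSet
#'
#' @param sequences Character vector or DNAStringSet of unique tag sequences
#'   (U is converted to T).
#' @param counts Matrix (tags x libraries) of read counts; a vector is taken
#'   as a single library. Column names are library identifiers.
#' @return A [TagSet-class] object.
#' @export
TagSet <- function(sequences, counts) {
  if (is.character(sequences))
    sequences <- DNAStringSet(chartr("Uu", "Tt", sequences))
  if (is.null(dim(counts)))
    counts <- matrix(counts, ncol = 1, dimnames = list(NULL, "library1"))
  storage.mode(counts) <- "integer"
  new("TagSet", sequences = sequences, counts = counts)
}

#' @describeIn TagSet Tag sequences as a DNAStringSet.
#' @param x,object A TagSet.
#' @export
tagSequences <- function(x) x@sequences

#' @describeIn TagSet Tag-by-library count matrix.
#' @export
tagCounts <- function(x) x@counts

#' @describeIn TagSet Library identifiers.
#' @export
libraryNames <- function(x) colnames(x@counts)

#' @describeIn TagSet Number of unique tags.
#' @export
setMethod("length", "TagSet", function(x) length(x@sequences))

#' @describeIn TagSet Subset tags by index or logical mask.
#' @param i Index vector.
#' @param j,drop,... Ignored.
#' @export
setMethod("[", "TagSet", function(x, i, j, ..., drop = FALSE) {
  new("TagSet", sequences = x@sequences[i],
      counts = x@counts[i, , drop = FALSE])
})

setMethod("show", "TagSet", function(object) {
  cat("TagSet with", length(object), "unique tags across",
      ncol(object@counts), "libraries (",
      paste(colnames(object@counts), collapse = ", "), ")\n")
  cat("  total reads per library:",
      paste(colSums(object@counts), collapse = ", "), "\n")
})

#' CleaningSummary: the read-cleaning filter ledger
#'
#' Bookkeeping for one library's raw-read cleaning, with the conservation
#' identity clean_reads = high_quality - sum(filter categories) enforced by
#' the validity method.
#'
#' @slot library Library identifier.
#' @slot counts Named numeric vector with elements total_read, high_quality,
#'   adaptor3_null, insert_null, adaptor5_contaminants, small_than_18nt,
#'   polyA, clean_reads.
#' @export
setClass("CleaningSummary",
         representation(library = "character", counts = "numeric"))

setValidity("CleaningSummary", function(object) {
  msg <- character()
  if (!identical(names(object@counts), .LEDGER_FIELDS))
    msg <- c(msg, "ledger fields missing or out of order")
  else {
    if (any(object@counts < 0)) msg <- c(msg, "negative ledger count")
    expect <- object@counts[["high_quality"]] -
      sum(object@counts[.LEDGER_FILTERS])
    if (object@counts[["clean_reads"]] != expect)
      msg <- c(msg, "ledger identity violated: clean_reads != high_quality - filters")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CleaningSummary
#'
#' `clean_reads` is always derived from the identity
#' high_quality - (adaptor3_null + insert_null + adaptor5_contaminants +
#' small_than_18nt + polyA), so the ledger cannot be constructed inconsistent.
#'
#' @param library Library identifier.
#' @param total_read,high_quality,adaptor3_null,insert_null,adaptor5_contaminants,small_than_18nt,polyA
#'   Read counts per ledger category.
#' @return A [CleaningSummary-class].
#' @export
CleaningSummary <- function(library, total_read, high_quality, adaptor3_null,
                            insert_null, adaptor5_contaminants,
                            small_than_18nt, polyA) {
  clean <- high_quality - (adaptor3_null + insert_null +
    adaptor5_contaminants + small_than_18nt + polyA)
  counts <- c(total_read = total_read, high_quality = high_quality,
              adaptor3_null = adaptor3_null, insert_null = insert_null,
              adaptor5_contaminants = adaptor5_contaminants,
              small_than_18nt = small_than_18nt, polyA = polyA,
              clean_reads = clean)
  new("CleaningSummary", library = library, counts = counts)
}

#' @describeIn CleaningSummary Clean-read count after all filters.
#' @param x,object A CleaningSummary.
#' @export
cleanReadCount <- function(x) unname(x@counts[["clean_reads"]])

#' @describeIn CleaningSummary Ledger counts as a named vector.
#' @export
ledgerCounts <- function(x) x@counts

#' @describeIn CleaningSummary Per-category percentages of high-quality reads,
#'   rounded to two decimals (total_read is reported as NA).
#' @export
ledgerPercentages <- function(x) {
  hq <- x@counts[["high_quality"]]
  p <- round(x@counts / hq * 100, 2)
  p[["total_read"]] <- NA_real_
  p
}

setMethod("show", "CleaningSummary", function(object) {
  cat("CleaningSummary for library", object@library, "\n")
  p <- ledgerPercentages(object)
  for (f in .LEDGER_FIELDS)
    cat(sprintf("  %-22s %12.0f %s\n", f, object@counts[[f]],
                ifelse(is.na(p[[f]]), "", sprintf("%6.2f%%", p[[f]]))))
})

#' CategorySummary: tag annotation by RNA category
#'
#' Unique-tag and read counts per annotation category for one library. The
#' validity method enforces the partition: category counts must be
#' non-negative and categories fixed to the standard layout.
#'
#' @slot library Library identifier.
#' @slot unique_counts Named numeric vector of unique-tag counts per category.
#' @slot read_counts Named numeric vector of read counts per category.
#' @export
setClass("CategorySummary",
         representation(library = "character", unique_counts = "numeric",
                        read_counts = "numeric"))

setValidity("CategorySummary", function(object) {
  msg <- character()
  if (!all(names(object@unique_counts) %in% .CATEGORY_PRIORITY) ||
      !identical(names(object@unique_counts), names(object@read_counts)))
    msg <- c(msg, "category names invalid or inconsistent")
  if (any(object@unique_counts < 0) || any(object@read_counts < 0))
    msg <- c(msg, "negative category count")
  if (length(msg)) msg else TRUE
})

#' Construct a CategorySummary
#'
#' @param library Library identifier.
#' @param unique_counts,read_counts Named numeric vectors (same names, drawn
#'   from the standard category set) of unique-tag and read counts.
#' @return A [CategorySummary-class].
#' @export
CategorySummary <- function(library, unique_counts, read_counts) {
  new("CategorySummary", library = library,
      unique_counts = unique_counts[names(unique_counts)],
      read_counts = read_counts[names(unique_counts)])
}

#' @describeIn CategorySummary Percentage of total reads (or unique tags)
#'   per category, rounded to two decimals.
#' @param x,object A CategorySummary.
#' @param what Either "reads" or "unique".
#' @export
categoryPercentages <- function(x, what = c("reads", "unique")) {
  what <- match.arg(what)
  v <- if (what == "reads") x@read_counts else x@unique_counts
  round(v / sum(v) * 100, 2)
}

#' @describeIn CategorySummary Total genome-matched reads and unique tags.
#' @export
categoryTotals <- function(x) {
  c(unique = sum(x@unique_counts), reads = sum(x@read_counts))
}

setMethod("show", "CategorySummary", function(object) {
  cat("CategorySummary for library", object@library, "\n")
  pu <- categoryPercentages(object, "unique")
  pr <- categoryPercentages(object, "reads")
  cat(sprintf("  %-18s %10s %8s %12s %8s\n", "category", "unique", "%",
              "reads", "%"))
  for (f in names(object@unique_counts))
    cat(sprintf("  %-18s %10.0f %7.2f%% %12.0f %7.2f%%\n", f,
                object@unique_counts[[f]], pu[[f]],
                object@read_counts[[f]], pr[[f]]))
})
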