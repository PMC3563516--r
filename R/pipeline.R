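## End-to-end orchestration: run every stage on a pair of libraries, write
## the standard result tables, and re-audit the cross-table identities.

#' Write a synthetic study to disk in standard formats
#'
#' Genome FASTA, loci GFF3 (class in the type column), mature/hairpin
#' reference FASTA, per-library FASTQ (constant high quality, Phred+33),
#' and a miFam-style family file.
#'
#' @param study Result of [simulateStudy()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(study$genome, file.path(dir, "genome.fa"))
  writeAnnotation(study$annotation, file.path(dir, "annotation.gff3"))
  Biostrings::writeXStringSet(study$mature_ref, file.path(dir, "mature.fa"))
  Biostrings::writeXStringSet(study$hairpin_ref, file.path(dir, "hairpin.fa"))
  writeFamilyFile(study$families, file.path(dir, "families.dat"))
  for (lib in names(study$reads)) {
    rd <- study$reads[[lib]]
    qual <- Biostrings::BStringSet(vapply(Biostrings::width(rd),
      function(w) strrep("I", w), ""))
    Biostrings::writeXStringSet(rd, file.path(dir, paste0(lib, ".fastq")),
                                format = "fastq", qualities = qual)
  }
  .writeTSV(study$mirna[, setdiff(names(study$mirna), "precursor")],
            file.path(dir, "ground_truth_mirna.tsv"))
  invisible(dir)
}

#' Run the full small-RNA analysis pipeline
#'
#' Cleans both libraries, maps and annotates tags, profiles known miRNAs
#' (arm usage, bias, edits, end variants, families), discovers novel
#' hairpin candidates, computes the differential expression table, and
#' (optionally) quantifies a qPCR Ct table. All standard result tables are
#' written to `outdir`.
#'
#' @param reads Named list (one element per library) of FASTQ paths,
#'   DNAStringSets or character vectors of raw reads; exactly two libraries.
#' @param genome DNAStringSet or FASTA path.
#' @param annotation GRanges (with `type`) or GFF3/BED path.
#' @param mature_ref,hairpin_ref DNAStringSets or FASTA paths of known
#'   miRNA references.
#' @param families data.frame or family-file path (optional).
#' @param adapter3,adapter5 Adapter sequences.
#' @param outdir Results directory.
#' @param alpha Significance level for the DE table.
#' @param params Novel-discovery parameters ([novelParams()]).
#' @param ct_table Optional Ct data.frame/TSV path for qPCR quantification.
#' @param reference_gene,calibrator_sample qPCR options.
#' @return Invisible list with every stage result (tags, summaries, known,
#'   novel, de, qpcr) plus `outdir`.
#' @export
runPipeline <- function(reads, genome, annotation, mature_ref, hairpin_ref,
                        families = NULL,
                        adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                        adapter5 = "GTTCAGAGTTCTACAGTCCGACGATC",
                        outdir = "mirpipe_results", alpha = 0.01,
                        params = novelParams(), ct_table = NULL,
                        reference_gene = "RPS18",
                        calibrator_sample = NULL) {
  if (length(reads) != 2 || is.null(names(reads)))
    stop("reads must be a named list of two libraries")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (is.character(annotation)) annotation <- readAnnotation(annotation)

  ## 1. cleaning
  cleaned <- lapply(names(reads), function(lib)
    cleanReads(reads[[lib]], adapter3, adapter5, library = lib))
  names(cleaned) <- names(reads)
  tags <- do.call(mergeTagSets, lapply(cleaned, `[[`, "tags"))
  summaries <- lapply(cleaned, `[[`, "summary")
  .writeTSV(.ledgerTable(summaries), file.path(outdir, "cleaning_summary.tsv"))
  .writeTSV(lengthDistribution(tags),
            file.path(outdir, "length_distribution.tsv"))

  ## 2. mapping + annotation
  index <- buildGenomeIndex(genome)
  mapped <- mapTags(tags, index)
  ann <- annotateTags(mapped$hits, annotation, tags)
  .writeTSV(.categoryTable(ann$summary),
            file.path(outdir, "category_summary.tsv"))
  .writeTSV(ann$assignment, file.path(outdir, "tag_categories.tsv"))

  ## 3. known miRNAs
  known <- matchKnown(tags, mature_ref, hairpin_ref)
  .writeTSV(known$profiles, file.path(outdir, "known_profiles.tsv"))
  arm <- tryCatch(armUsage(known$profiles), error = function(e) NULL)
  if (!is.null(arm)) .writeTSV(arm, file.path(outdir, "arm_usage.tsv"))
  bias <- nucleotideBias(known$profiles)
  .writeTSV(data.frame(position = seq_len(nrow(bias$matrix)), bias$matrix,
                       check.names = FALSE),
            file.path(outdir, "nucleotide_bias.tsv"))
  edits <- detectBaseEdits(known$leftover, mature_ref,
                           hairpin_ref = if (is.character(hairpin_ref))
                             Biostrings::readDNAStringSet(hairpin_ref)
                           else hairpin_ref,
                           profiles = known$profiles)
  .writeTSV(edits$edits, file.path(outdir, "base_edits.tsv"))
  ev <- catalogEndVariants(known, tags)
  if (nrow(ev$variants)) .writeTSV(ev$variants,
                                   file.path(outdir, "end_variants.tsv"))
  fams <- NULL
  if (!is.null(families)) {
    fams <- assignFamilies(known$profiles, families)
    .writeTSV(fams$summary, file.path(outdir, "family_summary.tsv"))
  }

  ## 4. novel discovery: drop tags annotated to known classes
  assigned_known <- unique(known$tag_assignment$tag_id)
  ncRNA <- ann$assignment$tag_id[!ann$assignment$category %in% "unknown"]
  keep <- setdiff(seq_len(length(tags)), union(assigned_known, ncRNA))
  novel <- discoverNovel(tags[keep], index, genome, params)
  if (nrow(novel$novel))
    .writeTSV(novel$novel, file.path(outdir, "novel_candidates.tsv"))

  ## 5. differential expression over known + novel miRNAs
  libs <- names(reads)
  totals <- vapply(summaries, cleanReadCount, 0)[libs]
  kc <- cbind(known$profiles[[paste0("total_", libs[1])]],
              known$profiles[[paste0("total_", libs[2])]])
  rownames(kc) <- known$profiles$mirna_id
  if (nrow(novel$novel)) {
    nc <- cbind(novel$novel[[paste0("count_", libs[1])]],
                novel$novel[[paste0("count_", libs[2])]])
    rownames(nc) <- novel$novel$id
    kc <- rbind(kc, nc)
  }
  de <- deTable(kc, totals, alpha = alpha)
  .writeTSV(de, file.path(outdir, "de_table.tsv"))
  desum <- attr(de, "summary")
  .writeTSV(data.frame(measure = names(desum), value = desum),
            file.path(outdir, "de_summary.tsv"))
  plotDE(de, file.path(outdir, "de_scatter.pdf"))

  ## 6. qPCR
  qpcr <- NULL
  if (!is.null(ct_table)) {
    if (is.null(calibrator_sample)) stop("calibrator_sample is required")
    qpcr <- deltaDeltaCt(ct_table, reference_gene, calibrator_sample)
    .writeTSV(qpcr, file.path(outdir, "qpcr_relative_expression.tsv"))
  }

  invisible(list(tags = tags, cleaning = summaries, mapping = mapped,
                 annotation = ann, known = known, edits = edits,
                 end_variants = ev, families = fams, novel = novel,
                 de = de, qpcr = qpcr, outdir = outdir))
}

.ledgerTable <- function(summaries) {
  df <- data.frame(type = .LEDGER_FIELDS)
  for (s in summaries) {
    p <- ledgerPercentages(s)
    df[[paste0(s@library, "_count")]] <- unname(s@counts)
    df[[paste0(s@library, "_pct")]] <- unname(p)
  }
  df
}

.categoryTable <- function(summaries) {
  df <- data.frame(category = .CATEGORY_PRIORITY)
  for (s in summaries) {
    df[[paste0(s@library, "_unique")]] <- unname(s@unique_counts)
    df[[paste0(s@library, "_unique_pct")]] <-
      unname(categoryPercentages(s, "unique"))
    df[[paste0(s@library, "_reads")]] <- unname(s@read_counts)
    df[[paste0(s@library, "_reads_pct")]] <-
      unname(categoryPercentages(s, "reads"))
  }
  df
}

#' Validate a results directory's conservation identities
#'
#' Re-checks, from the written tables alone: the cleaning ledger identity
#' (clean = high-quality minus filters, per library), the category
#' partition (per-category unique/read counts are internally consistent
#' with their percentages), and the DE summary totals (significant up/down
#' counts match the table).
#'
#' @param dir Results directory produced by [runPipeline()].
#' @return data.frame of checks: `check`, `pass`, `detail`. Failures are
#'   rows with `pass = FALSE`, not errors.
#' @export
validateOutputs <- function(dir) {
  checks <- list()
  addc <- function(check, pass, detail = "") {
    checks[[length(checks) + 1]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }
  led_path <- file.path(dir, "cleaning_summary.tsv")
  if (file.exists(led_path)) {
    led <- utils::read.delim(led_path)
    for (col in grep("_count$", names(led), value = TRUE)) {
      lib <- sub("_count$", "", col)
      v <- stats::setNames(led[[col]], led$type)
      ok <- v[["clean_reads"]] == v[["high_quality"]] -
        sum(v[.LEDGER_FILTERS])
      addc(paste0("cleaning_ledger_", lib), ok,
           paste("clean_reads =", v[["clean_reads"]]))
    }
  } else addc("cleaning_ledger", FALSE, "missing table")

  cat_path <- file.path(dir, "category_summary.tsv")
  if (file.exists(cat_path)) {
    cs <- utils::read.delim(cat_path, check.names = FALSE)
    for (col in grep("_reads$", names(cs), value = TRUE)) {
      lib <- sub("_reads$", "", col)
      pc <- cs[[paste0(lib, "_reads_pct")]]
      tot <- sum(cs[[col]])
      ok <- tot == 0 || all(abs(pc - round(cs[[col]] / tot * 100, 2)) < 0.011)
      addc(paste0("category_partition_", lib), ok,
           paste("total reads =", tot))
    }
  } else addc("category_partition", FALSE, "missing table")

  de_path <- file.path(dir, "de_table.tsv")
  ds_path <- file.path(dir, "de_summary.tsv")
  if (file.exists(de_path) && file.exists(ds_path)) {
    de <- utils::read.delim(de_path)
    ds <- utils::read.delim(ds_path)
    v <- stats::setNames(ds$value, ds$measure)
    ok <- v[["tested"]] == nrow(de) &&
      v[["up"]] == sum(de$significant & de$class == "up") &&
      v[["down"]] == sum(de$significant & de$class == "down")
    addc("de_totals", ok, paste("tested =", nrow(de)))
  } else addc("de_totals", FALSE, "missing table")

  do.call(rbind, checks)
}
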