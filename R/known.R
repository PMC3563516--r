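## Conserved miRNA identification against miRBase-style references, and the
## descriptive profiles built on top: arm usage, nucleotide bias, base
## edits, end variants and families.

.armClassFromId <- function(id) {
  ifelse(grepl("\\*$", id), "miR*",
  ifelse(grepl("-5p$", id), "miR-5p",
  ifelse(grepl("-3p$", id), "miR-3p", "miR")))
}

## locate each mature inside its hairpin; error if absent
.locateMature <- function(mature_ref, hairpin_ref) {
  mat <- as.character(mature_ref)
  hps <- as.character(hairpin_ref)
  res <- data.frame(mirna_id = names(mat), precursor_id = NA_character_,
                    start = NA_integer_, end = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(mat)) {
    hit <- regexpr(mat[i], hps, fixed = TRUE)
    j <- which(hit > 0)[1]
    if (is.na(j))
      stop("mature sequence absent from its declared hairpin: ",
           names(mat)[i])
    res$precursor_id[i] <- names(hps)[j]
    res$start[i] <- hit[j]
    res$end[i] <- hit[j] + nchar(mat[i]) - 1L
  }
  res
}

#' Match tags against known miRNA references
#'
#' A tag is assigned to a known miRNA iff it matches the mature sequence
#' exactly (exact-match count), or lies wholly within the miRNA's hairpin
#' and overlaps the mature site by at least `min_overlap` nt
#' (variant-inclusive count). Ties across references are broken toward the
#' exact match, then lexicographic miRNA id. Unassigned tags are returned
#' for base-edit detection and novel discovery.
#'
#' @param tags A [TagSet-class] of clean tags.
#' @param mature_ref DNAStringSet of mature miRNAs (miRBase-style names;
#'   `*`/-5p/-3p suffixes mark arms), or FASTA path.
#' @param hairpin_ref DNAStringSet of hairpins, or FASTA path.
#' @param min_overlap Minimum tag/mature-site overlap for variant counting
#'   (nt).
#' @return List with `profiles` (data.frame: mirna_id, arm_class,
#'   precursor_id, mature, per-library exact_<lib> and total_<lib> counts),
#'   `leftover` (a [TagSet-class] of unassigned tags), and `tag_assignment`
#'   (data.frame: tag_id, mirna_id, match type, hairpin offsets).
#' @export
matchKnown <- function(tags, mature_ref, hairpin_ref, min_overlap = 16L) {
  if (is.character(mature_ref))
    mature_ref <- Biostrings::readDNAStringSet(mature_ref)
  if (is.character(hairpin_ref))
    hairpin_ref <- Biostrings::readDNAStringSet(hairpin_ref)
  mature_ref <- DNAStringSet(chartr("Uu", "Tt", as.character(mature_ref)))
  hairpin_ref <- DNAStringSet(chartr("Uu", "Tt", as.character(hairpin_ref)))
  loc <- .locateMature(mature_ref, hairpin_ref)

  seqs <- as.character(tagSequences(tags))
  mat <- as.character(mature_ref)
  hps <- as.character(hairpin_ref)

  ## exact matches first
  exact_of <- match(seqs, mat)            # index into mature refs or NA
  assign_id <- names(mat)[exact_of]
  match_type <- ifelse(is.na(exact_of), NA_character_, "exact")
  off5 <- rep(NA_integer_, length(seqs)); off3 <- rep(NA_integer_, length(seqs))
  off5[!is.na(exact_of)] <- 0L; off3[!is.na(exact_of)] <- 0L

  ## variant-inclusive: tag within hairpin, overlapping the mature site
  todo <- which(is.na(assign_id))
  ord_ids <- order(names(mat))            # deterministic tie-break
  for (t in todo) {
    best <- NA_integer_
    for (m in ord_ids) {
      hp <- hps[[loc$precursor_id[m]]]
      p <- regexpr(seqs[t], hp, fixed = TRUE)
      if (p < 0) next
      tstart <- as.integer(p); tend <- tstart + nchar(seqs[t]) - 1L
      ov <- min(tend, loc$end[m]) - max(tstart, loc$start[m]) + 1L
      if (ov >= min_overlap) { best <- m; break }
    }
    if (!is.na(best)) {
      assign_id[t] <- names(mat)[best]
      match_type[t] <- "variant"
      hp <- hps[[loc$precursor_id[best]]]
      p <- as.integer(regexpr(seqs[t], hp, fixed = TRUE))
      ## positive offsets extend beyond the reference mature end
      off5[t] <- loc$start[best] - p
      off3[t] <- (p + nchar(seqs[t]) - 1L) - loc$end[best]
    }
  }

  counts <- tagCounts(tags)
  libs <- colnames(counts)
  profiles <- data.frame(mirna_id = names(mat),
                         arm_class = .armClassFromId(names(mat)),
                         precursor_id = loc$precursor_id,
                         mature = unname(mat), stringsAsFactors = FALSE)
  for (lib in libs) {
    ex <- vapply(names(mat), function(id)
      sum(counts[which(assign_id == id & match_type == "exact"), lib]), 0)
    tot <- vapply(names(mat), function(id)
      sum(counts[which(assign_id == id), lib]), 0)
    profiles[[paste0("exact_", lib)]] <- unname(ex)
    profiles[[paste0("total_", lib)]] <- unname(tot)
  }
  assigned <- !is.na(assign_id)
  tag_assignment <- data.frame(tag_id = which(assigned),
                               mirna_id = assign_id[assigned],
                               match = match_type[assigned],
                               offset5 = off5[assigned],
                               offset3 = off3[assigned],
                               stringsAsFactors = FALSE)
  list(profiles = profiles, leftover = tags[!assigned],
       tag_assignment = tag_assignment)
}

#' Arm usage: miR vs miR* read counts per precursor
#'
#' For each precursor with both arms profiled, reports the guide (miR) and
#' passenger (miR*) totals, the dominant arm, and a near-equal flag set when
#' the minority arm carries at least `near_equal_min` of the precursor's
#' reads (the miR-151/151*- or miR-455/455*-like situation where both arms
#' are retained; at the default 1/3, read pairs like 447/680 and 186/314
#' are flagged near-equal).
#'
#' @param profiles Profile data.frame from [matchKnown()] (or any data.frame
#'   with mirna_id, arm_class, precursor_id and total_<lib> columns).
#' @param library Library whose counts are used; default sums all.
#' @param near_equal_min Minority-arm fraction that flags near-equal usage.
#' @return data.frame: precursor_id, mir_reads, star_reads, dominant_arm,
#'   near_equal.
#' @export
armUsage <- function(profiles, library = NULL, near_equal_min = 1 / 3) {
  tot_cols <- grep("^total_", names(profiles), value = TRUE)
  if (!is.null(library)) tot_cols <- paste0("total_", library)
  reads <- rowSums(profiles[, tot_cols, drop = FALSE])
  is_star <- profiles$arm_class == "miR*"
  pre <- unique(profiles$precursor_id[is_star | profiles$arm_class != ""])
  rows <- lapply(unique(profiles$precursor_id), function(p) {
    sel <- profiles$precursor_id == p
    mir <- sum(reads[sel & !is_star]); star <- sum(reads[sel & is_star])
    if (mir + star == 0) return(NULL)
    data.frame(precursor_id = p, mir_reads = mir, star_reads = star,
               dominant_arm = ifelse(star > mir, "miR*", "miR"),
               near_equal = min(mir, star) / (mir + star) >= near_equal_min,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no precursor with observed arms")
  out
}

#' Per-position nucleotide bias of profiled miRNAs
#'
#' Frequencies of A/C/G/U at each position of the mature sequences, aligned
#' from the 5' end, weighted by read count (or per unique sequence).
#' Sequences shorter than a position do not contribute to it; each row is
#' renormalized over its observed bases.
#'
#' @param profiles Profile data.frame from [matchKnown()].
#' @param weight "reads" (read-weighted) or "unique" (one vote per miRNA).
#' @param library Library whose counts weight the rows; default sums all.
#' @return List with `matrix` (positions x A,C,G,U), `gc` and `au`
#'   per-position summaries.
#' @export
nucleotideBias <- function(profiles, weight = c("reads", "unique"),
                           library = NULL) {
  weight <- match.arg(weight)
  if (nrow(profiles) == 0) stop("empty profile set")
  tot_cols <- grep("^total_", names(profiles), value = TRUE)
  if (!is.null(library)) tot_cols <- paste0("total_", library)
  w <- if (weight == "reads")
    rowSums(profiles[, tot_cols, drop = FALSE]) else rep(1, nrow(profiles))
  keep <- w > 0
  seqs <- chartr("Tt", "Uu", profiles$mature[keep]); w <- w[keep]
  if (!length(seqs)) stop("no profiled miRNA has reads")
  L <- max(nchar(seqs))
  m <- matrix(0, L, 4, dimnames = list(seq_len(L), c("A", "C", "G", "U")))
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in seq_along(ch)) m[p, ch[p]] <- m[p, ch[p]] + w[i]
  }
  m <- m / rowSums(m)
  list(matrix = m, gc = m[, "G"] + m[, "C"], au = m[, "A"] + m[, "U"])
}

#' Detect single-base edits and untemplated 3' additions
#'
#' Compares each leftover tag (one that failed exact known matching) with
#' equal-length windows of the reference matures, anchored at the 5' end (a
#' suffix window is also tried when lengths differ): a Hamming distance of
#' exactly 1 yields an edit record with its position (1-based in the
#' mature), reference and observed base, and a seed-region flag (positions
#' 2-8). A tag equal to a mature plus 1-2 terminal A/U not templated in the
#' hairpin is recorded separately as a 3' addition. Ties across references
#' are broken by the higher-count reference, then lexicographic id.
#'
#' @param leftover A [TagSet-class] of unassigned tags.
#' @param mature_ref DNAStringSet (or FASTA path) of reference matures.
#' @param hairpin_ref Optional DNAStringSet of hairpins, used to decide
#'   whether a 3' extension is templated.
#' @param profiles Optional profile data.frame (for tie-break counts).
#' @param max_len_diff Maximum tag/mature length difference for the
#'   substitution search.
#' @return List with `edits` (data.frame: tag, mirna_id, type, position,
#'   ref_base, obs_base, in_seed, per-library counts) and `edited_fraction`
#'   (read-weighted: edited reads / (edited + profiled reads), when
#'   `profiles` is given, else NA).
#' @export
detectBaseEdits <- function(leftover, mature_ref, hairpin_ref = NULL,
                            profiles = NULL, max_len_diff = 2L) {
  if (is.character(mature_ref))
    mature_ref <- Biostrings::readDNAStringSet(mature_ref)
  mat <- chartr("Uu", "Tt", as.character(mature_ref))
  if (!is.null(hairpin_ref))
    hps <- chartr("Uu", "Tt", as.character(hairpin_ref))
  seqs <- as.character(tagSequences(leftover))
  counts <- tagCounts(leftover)
  libs <- colnames(counts)
  refw <- if (!is.null(profiles)) {
    tc <- grep("^total_", names(profiles), value = TRUE)
    stats::setNames(rowSums(profiles[, tc, drop = FALSE]),
                    profiles$mirna_id)[names(mat)]
  } else stats::setNames(rep(0, length(mat)), names(mat))
  ord <- order(-refw, names(mat))   # tie-break: high count, then id

  rows <- list()
  lens <- range(nchar(mat))
  for (t in seq_along(seqs)) {
    tag <- seqs[t]
    if (nchar(tag) < lens[1] - max_len_diff ||
        nchar(tag) > lens[2] + max(max_len_diff, 2L)) next
    hit <- NULL
    for (m in ord) {
      ref <- mat[[m]]
      dlen <- nchar(tag) - nchar(ref)
      ## untemplated 3' addition: tag = mature + 1-2 x A/U
      if (dlen >= 1 && dlen <= 2 &&
          substr(tag, 1, nchar(ref)) == ref) {
        extra <- substr(tag, nchar(ref) + 1, nchar(tag))
        if (grepl("^[AT]+$", extra)) {
          templated <- FALSE
          if (!is.null(hairpin_ref)) {
            for (h in hps) {
              p <- regexpr(ref, h, fixed = TRUE)
              if (p > 0 && substr(h, p + nchar(ref),
                                  p + nchar(tag) - 1) == extra)
                templated <- TRUE
            }
          }
          if (!templated) {
            hit <- data.frame(tag = tag, mirna_id = names(mat)[m],
                              type = "addition3p", position = NA_integer_,
                              ref_base = NA_character_, obs_base = extra,
                              in_seed = FALSE, stringsAsFactors = FALSE)
            break
          }
        }
      }
      if (abs(dlen) > max_len_diff) next
      L <- min(nchar(tag), nchar(ref))
      windows <- unique(list(c(1L, 1L),
                             c(max(nchar(tag) - L + 1L, 1L),
                               max(nchar(ref) - L + 1L, 1L))))
      for (wdw in windows) {
        a <- substr(tag, wdw[1], wdw[1] + L - 1L)
        b <- substr(ref, wdw[2], wdw[2] + L - 1L)
        d <- which(charToRaw(a) != charToRaw(b))
        if (length(d) == 1) {
          pos <- wdw[2] + d - 1L
          hit <- data.frame(tag = tag, mirna_id = names(mat)[m],
                            type = "substitution", position = pos,
                            ref_base = substr(b, d, d),
                            obs_base = substr(a, d, d),
                            in_seed = pos >= 2 && pos <= 8,
                            stringsAsFactors = FALSE)
          break
        }
      }
      if (!is.null(hit)) break
    }
    if (!is.null(hit)) {
      for (lib in libs) hit[[paste0("count_", lib)]] <- counts[t, lib]
      hit$a_to_g <- identical(hit$ref_base, "A") &&
        identical(hit$obs_base, "G")
      rows[[length(rows) + 1]] <- hit
    }
  }
  edits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(tag = character(0), mirna_id = character(0),
               type = character(0), position = integer(0),
               ref_base = character(0), obs_base = character(0),
               in_seed = logical(0), a_to_g = logical(0))
  frac <- NA_real_
  if (!is.null(profiles)) {
    tc <- grep("^total_", names(profiles), value = TRUE)
    matched <- sum(profiles[, tc])
    edited <- sum(edits[, grep("^count_", names(edits)), drop = FALSE])
    if (matched + edited > 0) frac <- edited / (matched + edited)
  }
  list(edits = edits, edited_fraction = frac)
}

#' Catalog 5'/3' end variants (isomiRs)
#'
#' Summarizes the signed end offsets of variant-matched tags against their
#' reference matures: positive offsets extend past the reference terminus,
#' negative offsets trim it. Variants are classed as 5'-only, 3'-only or
#' both, and the 3'-variant share of variant reads is reported (end
#' variation concentrates at the 3' end in animal miRNA data).
#'
#' @param known Result of [matchKnown()].
#' @param tags The [TagSet-class] passed to [matchKnown()].
#' @param max_offset Maximum |offset| in nt to keep (default 5).
#' @return List with `variants` (data.frame: tag, mirna_id, offset5,
#'   offset3, end_class, per-library counts), `per_mirna` summary, and
#'   `share3` (fraction of variant reads with 3'-end change).
#' @export
catalogEndVariants <- function(known, tags, max_offset = 5L) {
  ta <- known$tag_assignment
  va <- ta[ta$match == "variant" &
             abs(ta$offset5) <= max_offset &
             abs(ta$offset3) <= max_offset, , drop = FALSE]
  counts <- tagCounts(tags)
  libs <- colnames(counts)
  if (nrow(va) == 0) {
    return(list(variants = data.frame(), per_mirna = data.frame(),
                share3 = NA_real_))
  }
  variants <- data.frame(
    tag = as.character(tagSequences(tags))[va$tag_id],
    mirna_id = va$mirna_id, offset5 = va$offset5, offset3 = va$offset3,
    end_class = ifelse(va$offset5 != 0 & va$offset3 != 0, "both",
                ifelse(va$offset3 != 0, "3p_only", "5p_only")),
    stringsAsFactors = FALSE)
  for (lib in libs) variants[[paste0("count_", lib)]] <- counts[va$tag_id, lib]
  cc <- rowSums(variants[, paste0("count_", libs), drop = FALSE])
  per <- do.call(rbind, lapply(split(seq_len(nrow(variants)),
                                     variants$mirna_id), function(ii) {
    data.frame(mirna_id = variants$mirna_id[ii[1]],
               n_variants = length(ii),
               reads = sum(cc[ii]),
               n_5p_only = sum(variants$end_class[ii] == "5p_only"),
               n_3p_only = sum(variants$end_class[ii] == "3p_only"),
               n_both = sum(variants$end_class[ii] == "both"),
               stringsAsFactors = FALSE)
  }))
  with3 <- variants$end_class %in% c("3p_only", "both")
  share3 <- sum(cc[with3]) / sum(cc)
  list(variants = variants, per_mirna = per, share3 = share3)
}

#' Parse a miFam.dat-style family file
#'
#' Stanza format: `AC` accession, `ID` family name, one `MI` line per member
#' (accession, miRNA id), stanzas closed by `//`.
#'
#' @param path File path.
#' @return data.frame with columns `family`, `id`.
#' @export
readFamilyFile <- function(path) {
  lines <- readLines(path)
  fam <- NULL; rows <- list()
  for (ln in lines) {
    if (startsWith(ln, "ID")) fam <- trimws(sub("^ID\\s+", "", ln))
    else if (startsWith(ln, "MI")) {
      parts <- strsplit(trimws(sub("^MI\\s+", "", ln)), "\\s+")[[1]]
      rows[[length(rows) + 1]] <- data.frame(
        family = fam, id = parts[length(parts)], stringsAsFactors = FALSE)
    } else if (startsWith(ln, "//")) fam <- NULL
  }
  do.call(rbind, rows)
}

#' Write a miFam.dat-style family file
#' @param families data.frame with columns `id`, `family` (NA = unassigned).
#' @param path Output path.
#' @export
writeFamilyFile <- function(families, path) {
  fam <- families[!is.na(families$family), ]
  con <- file(path, "w"); on.exit(close(con))
  k <- 0
  for (f in unique(fam$family)) {
    k <- k + 1
    writeLines(sprintf("AC   MIPF%07d", k), con)
    writeLines(paste0("ID   ", f), con)
    for (id in fam$id[fam$family == f])
      writeLines(sprintf("MI   MI%07d  %s", k, id), con)
    writeLines("//", con)
  }
  invisible(path)
}

#' Assign profiled miRNAs to families
#'
#' @param profiles Profile data.frame from [matchKnown()].
#' @param families data.frame (`family`, `id`) from [readFamilyFile()], or a
#'   path to a family file. A miRNA listed in two families is an error.
#' @return List with `assignment` (profiles + family column; arm suffixes
#'   are stripped before lookup), `summary` (per family: members observed,
#'   min/max/total member reads), and `unassigned` (ids with no family).
#' @export
assignFamilies <- function(profiles, families) {
  if (is.character(families) && length(families) == 1)
    families <- readFamilyFile(families)
  if (anyDuplicated(families$id)) {
    dup <- unique(families$id[duplicated(families$id)])
    stop("miRNA in two families: ", paste(dup, collapse = ", "))
  }
  base_id <- sub("\\*$", "", profiles$mirna_id)
  fam <- families$family[match(base_id, families$id)]
  out <- profiles
  out$family <- fam
  tc <- grep("^total_", names(profiles), value = TRUE)
  reads <- rowSums(profiles[, tc, drop = FALSE])
  obs <- !is.na(fam) & reads > 0
  summ <- do.call(rbind, lapply(split(which(obs), fam[obs]), function(ii) {
    data.frame(family = fam[ii[1]], members = length(ii),
               min_reads = min(reads[ii]), max_reads = max(reads[ii]),
               total_reads = sum(reads[ii]), stringsAsFactors = FALSE)
  }))
  if (is.null(summ))
    summ <- data.frame(family = character(0), members = integer(0),
                       min_reads = numeric(0), max_reads = numeric(0),
                       total_reads = numeric(0))
  list(assignment = out, summary = summ,
       unassigned = unique(base_id[is.na(fam)]))
}

#' Count known-miRNA arm classes
#'
#' Tallies profiled miRNAs (those with at least one read) by arm class and
#' returns the class counts plus their sum — the library's number of
#' distinct miRNA categories.
#'
#' @param profiles Profile data.frame from [matchKnown()], or a named
#'   numeric vector of per-class counts (names from miR, miR*, miR-5p,
#'   miR-3p).
#' @param library Library to count; default: observed in any library.
#' @return Named vector of class counts with a `total` element.
#' @export
mirnaClassTotals <- function(profiles, library = NULL) {
  classes <- c("miR", "miR*", "miR-5p", "miR-3p")
  if (is.numeric(profiles)) {
    if (!all(names(profiles) %in% classes))
      stop("unknown arm class: ",
           paste(setdiff(names(profiles), classes), collapse = ", "))
    cnt <- stats::setNames(rep(0, length(classes)), classes)
    cnt[names(profiles)] <- profiles
  } else {
    tc <- grep("^total_", names(profiles), value = TRUE)
    if (!is.null(library)) tc <- paste0("total_", library)
    reads <- rowSums(profiles[, tc, drop = FALSE])
    cnt <- vapply(classes, function(cl)
      sum(profiles$arm_class == cl & reads > 0), 0)
  }
  c(cnt, total = sum(cnt))
}
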