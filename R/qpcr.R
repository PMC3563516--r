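## Stem-loop qPCR relative quantification by the 2^-ddCt method.

#' Read a Ct table
#'
#' Expects a TSV with columns sample, gene, replicate, Ct.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readCtTable <- function(path) {
  ct <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "gene", "replicate", "Ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "))
  ct
}

#' Relative expression by 2^-ddCt
#'
#' Per (sample, target): dCt = mean Ct(target) - mean Ct(reference);
#' ddCt = dCt(sample) - dCt(calibrator sample); N = 2^-ddCt. The calibrator
#' sample has N = 1 exactly. Replicates are aggregated by the arithmetic
#' mean; a replicate more than `outlier_cycles` from the within-triplicate
#' median is flagged. Ct values above `max_ct` (or missing) are treated as
#' not detected; a target is reported non-detected in a sample when fewer
#' than `min_replicates` wells remain.
#'
#' @param ct data.frame with sample, gene, replicate, Ct (or a TSV path).
#' @param reference_gene Endogenous control gene (must be measured in every
#'   sample).
#' @param calibrator_sample Sample against which ddCt is taken.
#' @param max_ct Detection cutoff in cycles (default 40).
#' @param outlier_cycles Replicate outlier flag threshold (default 0.5).
#' @param min_replicates Minimum usable wells per (sample, gene); fewer
#'   triggers a warning and a non-detected call.
#' @return data.frame: sample, target, mean_ct, sd_ct, n_replicates,
#'   outlier_flag, dct, ddct, relative_expression, detected.
#' @export
deltaDeltaCt <- function(ct, reference_gene, calibrator_sample,
                         max_ct = 40, outlier_cycles = 0.5,
                         min_replicates = 2L) {
  if (is.character(ct) && length(ct) == 1) ct <- readCtTable(ct)
  stopifnot(all(c("sample", "gene", "Ct") %in% names(ct)))
  if (!calibrator_sample %in% ct$sample) stop("calibrator sample not present")
  ct$usable <- !is.na(ct$Ct) & ct$Ct > 0 & ct$Ct <= max_ct

  agg <- do.call(rbind, lapply(split(ct, ct[c("gene", "sample")], drop = TRUE),
    function(g) {
      u <- g$Ct[g$usable]
      data.frame(sample = g$sample[1], gene = g$gene[1],
                 mean_ct = if (length(u)) mean(u) else NA_real_,
                 sd_ct = if (length(u) > 1) stats::sd(u) else NA_real_,
                 n_replicates = length(u),
                 outlier_flag = length(u) > 1 &&
                   any(abs(u - stats::median(u)) > outlier_cycles),
                 stringsAsFactors = FALSE)
    }))
  row.names(agg) <- NULL

  samples <- unique(ct$sample)
  ref <- agg[agg$gene == reference_gene, ]
  if (!all(samples %in% ref$sample[ref$n_replicates > 0]))
    stop("reference gene missing in sample(s): ",
         paste(setdiff(samples, ref$sample[ref$n_replicates > 0]),
               collapse = ", "))
  refct <- stats::setNames(ref$mean_ct, ref$sample)

  tg <- agg[agg$gene != reference_gene, ]
  low <- tg$n_replicates < min_replicates & tg$n_replicates > 0
  if (any(low))
    warning("fewer than ", min_replicates, " usable replicates for ",
            paste(unique(tg$gene[low]), collapse = ", "))
  tg$dct <- tg$mean_ct - refct[tg$sample]
  cal <- stats::setNames(tg$dct[tg$sample == calibrator_sample],
                         tg$gene[tg$sample == calibrator_sample])
  tg$ddct <- tg$dct - cal[tg$gene]
  tg$relative_expression <- 2^(-tg$ddct)
  tg$detected <- tg$n_replicates >= min_replicates & !is.na(tg$mean_ct)
  tg$relative_expression[!tg$detected] <- NA_real_
  names(tg)[names(tg) == "gene"] <- "target"
  tg[order(tg$target, tg$sample), ]
}
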