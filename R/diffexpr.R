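## Count-based differential expression between two libraries: normalized
## expression (transcripts per million), log2 fold change, and an exact
## conditional p-value on the pair of counts.

#' Normalized expression in transcripts per million
#'
#' NE = count / total x 1e6. For ratio computations, zero counts are
#' replaced by a pseudo-expression (default 0.01 TPM); the raw NE of 0 is
#' still reported.
#'
#' @param count Read count(s) (>= 0).
#' @param total Total clean reads in the library (> 0).
#' @param pseudo Pseudo-TPM substituted for zeros in `ratio_ne`.
#' @return List with `ne` (raw TPM) and `ratio_ne` (zeros replaced).
#' @export
normalizeExpression <- function(count, total, pseudo = 0.01) {
  if (any(total <= 0)) stop("total must be > 0")
  if (any(count < 0)) stop("counts must be >= 0")
  ne <- count / total * 1e6
  list(ne = ne, ratio_ne = ifelse(ne == 0, pseudo, ne))
}

#' Log2 fold change of normalized expression
#'
#' `log2(ne1 / ne2)`; antisymmetric under swapping the libraries.
#'
#' @param ne1,ne2 Ratio-safe normalized expressions (> 0).
#' @return log2 ratio.
#' @export
foldChange <- function(ne1, ne2) {
  stopifnot(all(ne1 > 0), all(ne2 > 0))
  log2(ne1 / ne2)
}

## log p(y | x) for the conditional count distribution
## p(y|x) = (N2/N1)^y * (x+y)! / (x! y! (1 + N2/N1)^(x+y+1))
.logPyx <- function(y, x, N1, N2) {
  r <- N2 / N1
  y * log(r) + lgamma(x + y + 1) - lgamma(x + 1) - lgamma(y + 1) -
    (x + y + 1) * log1p(r)
}

#' Exact conditional p-value for a pair of library counts
#'
#' For counts x (library 1) and y (library 2) with library depths N1, N2,
#' the conditional distribution of y given x is
#' p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y+1)),
#' the classic exact test for digital expression data from two libraries.
#' Tail sums are accumulated in log-gamma space (no factorial overflow):
#' the lower tail C = sum_(k <= y) p(k|x) directly; the upper tail
#' D = sum_(k >= y) p(k|x), whose infinite sum is closed by the
#' normalization identity, is summed upward from y until the geometric
#' decay of the terms makes the remainder negligible, which keeps tiny
#' tails free of the cancellation a 1 - C(y-1) evaluation would suffer.
#' The two-sided p-value is 2 min(C, D), capped at 1.
#'
#' @param x,y Non-negative integer counts.
#' @param N1,N2 Library totals (> 0).
#' @param two_sided If FALSE, returns min(C, D) uncapped.
#' @return List with `p` (two-sided), `lower` (C) and `upper` (D);
#'   vectorized over x/y.
#' @export
audicClaverieTest <- function(x, y, N1, N2, two_sided = TRUE) {
  if (any(x < 0) || any(y < 0) || any(x != floor(x)) || any(y != floor(y)))
    stop("counts must be non-negative integers")
  if (N1 <= 0 || N2 <= 0) stop("library totals must be > 0")
  n <- max(length(x), length(y))
  x <- rep_len(x, n); y <- rep_len(y, n)
  r <- N2 / N1
  C <- numeric(n); D <- numeric(n)
  for (i in seq_len(n)) {
    k <- 0:y[i]
    lp <- .logPyx(k, x[i], N1, N2)
    C[i] <- min(sum(exp(lp)), 1)
    ## upper tail: sum terms from y upward; beyond the mode the term ratio
    ## r (x + k + 1) / ((k + 1)(1 + r)) drops below 1 and decays to r/(1+r)
    lt <- lp[length(lp)]
    acc <- exp(lt)
    kk <- y[i]
    mode_k <- r * (x[i] + 1) / 1  # ratio < 1 once kk exceeds about this
    repeat {
      lt <- lt + log(r) + log(x[i] + kk + 1) - log(kk + 1) - log1p(r)
      term <- exp(lt)
      acc <- acc + term
      kk <- kk + 1
      if (kk > mode_k && (term < acc * 1e-17 || term < 1e-320)) break
      if (kk > y[i] + x[i] + 1e6) break
    }
    D[i] <- min(acc, 1)
  }
  p <- if (two_sided) pmin(2 * pmin(C, D), 1) else pmin(C, D)
  list(p = p, lower = C, upper = D)
}

#' Classify a fold change into expression classes
#'
#' Three-way classification by the NE ratio: "up" when ratio > 2, "down"
#' when ratio <= 1/2 (boundary included), otherwise "unchanged" — the
#' standard red/blue/green scatter-plot classes.
#'
#' @param ratio NE1/NE2 ratio(s) (> 0), or use `log2fc`.
#' @param log2fc Alternative input on the log2 scale.
#' @return Character vector in {"up", "unchanged", "down"}.
#' @export
classifyExpression <- function(ratio = NULL, log2fc = NULL) {
  if (is.null(ratio)) ratio <- 2^log2fc
  ifelse(ratio > 2, "up", ifelse(ratio <= 0.5, "down", "unchanged"))
}

#' Differential expression table for two libraries
#'
#' Builds one record per miRNA observed in either library: counts, NE
#' (TPM), log2 fold change (library 1 over library 2), the exact two-sided
#' conditional p-value, Benjamini-Hochberg adjusted p, expression class and
#' significance flag. Sorted by p-value.
#'
#' @param counts Matrix or data.frame of counts, rows named by miRNA id,
#'   exactly two columns (library 1, library 2).
#' @param totals Length-2 vector of total clean reads per library.
#' @param alpha Significance level applied to the adjusted p (default 0.01).
#' @param adjust Multiple-testing method for [stats::p.adjust] ("BH").
#' @param pseudo Pseudo-TPM for zero counts in ratios.
#' @return data.frame: mirna_id, x, y, ne1, ne2, log2fc, p, padj, class,
#'   significant; attribute `summary` holds the significant up/down counts.
#' @export
deTable <- function(counts, totals, alpha = 0.01, adjust = "BH",
                    pseudo = 0.01) {
  if (is.null(dim(counts)) || ncol(counts) != 2)
    stop("counts must have two columns (one per library)")
  if (length(totals) != 2 || any(totals <= 0)) stop("totals missing")
  counts <- as.matrix(counts)
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  x <- counts[, 1]; y <- counts[, 2]
  n1 <- normalizeExpression(x, totals[1], pseudo)
  n2 <- normalizeExpression(y, totals[2], pseudo)
  fc <- foldChange(n1$ratio_ne, n2$ratio_ne)
  ac <- audicClaverieTest(x, y, totals[1], totals[2])
  padj <- stats::p.adjust(ac$p, method = adjust)
  out <- data.frame(mirna_id = rownames(counts), x = x, y = y,
                    ne1 = n1$ne, ne2 = n2$ne, log2fc = fc, p = ac$p,
                    padj = padj,
                    class = classifyExpression(n1$ratio_ne / n2$ratio_ne),
                    significant = padj <= alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$p), ]
  attr(out, "summary") <- c(
    up = sum(out$significant & out$class == "up"),
    down = sum(out$significant & out$class == "down"),
    tested = nrow(out))
  out
}

#' Scatter plot of the two libraries' expression with DE classes
#'
#' Log-scale scatter of NE in the two libraries with the conventional
#' red (up), blue (unchanged), green (down) coloring.
#'
#' @param de A [deTable()] result.
#' @param path Optional file path (PDF) to write.
#' @export
plotDE <- function(de, path = NULL) {
  cols <- c(up = "red", unchanged = "blue", down = "green3")
  if (!is.null(path)) grDevices::pdf(path, width = 5, height = 5)
  eps <- 0.01
  graphics::plot(de$ne2 + eps, de$ne1 + eps, log = "xy", pch = 20,
                 col = cols[de$class],
                 xlab = "Expression level (library 2, TPM)",
                 ylab = "Expression level (library 1, TPM)")
  graphics::abline(0, 1, untf = TRUE, lty = 2, col = "grey40")
  if (!is.null(path)) grDevices::dev.off()
  invisible(de)
}
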