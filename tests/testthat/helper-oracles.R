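# Independent oracles used across the suite.

# Exhaustive minimum free energy: enumerate every pseudoknot-free pairing
# (min hairpin loop 3, legal pairs only) and score each with the package's
# structure evaluator. Independent of the DP in foldRNA().
enumMFE <- function(seq, params = foldingParams()) {
  n <- nchar(seq)
  s <- strsplit(chartr("Uu", "Tt", toupper(seq)), "")[[1]]
  strength <- function(a, b) {
    key <- paste0(sort(c(a, b)), collapse = "")
    switch(key, CG = 1, AT = 1, GT = 1, -1)
  }
  best <- 0
  rec <- function(pos, pt) {
    if (pos > n) {
      e <- tryCatch(structureEnergy(seq, pt, params), error = function(e) Inf)
      if (e < best) best <<- e
      return(invisible())
    }
    if (pt[pos] != 0) { rec(pos + 1, pt); return(invisible()) }
    rec(pos + 1, pt)
    for (j in seq_len(n)) {
      if (j > pos + 3 && pt[j] == 0 && strength(s[pos], s[j]) > 0) {
        inner <- (pos + 1):(j - 1)
        if (all(pt[inner] == 0 | (pt[inner] > pos & pt[inner] < j))) {
          pt2 <- pt; pt2[pos] <- j; pt2[j] <- pos
          rec(pos + 1, pt2)
        }
      }
    }
  }
  rec(1, integer(n))
  best
}

# Direct evaluation of the conditional count distribution
# p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1)), written with
# binomial coefficients and grouped powers so every factor stays finite:
# p = choose(x+y, y) (r/(1+r))^y / (1+r)^(x+1). Exact to double precision
# for x, y <= ~800 (no cancellation: all terms positive).
acOracleTerm <- function(y, x, N1, N2) {
  r <- N2 / N1
  choose(x + y, y) * (r / (1 + r))^y / (1 + r)^(x + 1)
}
acOracleLower <- function(y, x, N1, N2) sum(acOracleTerm(0:y, x, N1, N2))
acOracleUpper <- function(y, x, N1, N2) {
  K <- min(y + 2500, 1020 - x)  # keep choose() finite; tail beyond K is
  sum(acOracleTerm(y:K, x, N1, N2))  # below 1e-70 of the mode for r <= 2
}

# Naive O(n*m) exact matcher over both strands (mapping oracle)
naiveScan <- function(tag, genome_seq) {
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") tag else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(tag)))
    n <- nchar(genome_seq); w <- nchar(q)
    for (s in seq_len(n - w + 1)) {
      if (substr(genome_seq, s, s + w - 1) == q)
        hits[[length(hits) + 1]] <- data.frame(start = s, end = s + w - 1,
                                               strand = strand)
    }
  }
  if (length(hits)) do.call(rbind, hits) else
    data.frame(start = integer(0), end = integer(0), strand = character(0))
}

randomRNA <- function(n) paste(sample(c("A", "C", "G", "U"), n,
                                      replace = TRUE), collapse = "")

# small two-library TagSet from raw sequence/count vectors
makeTagSet <- function(seqs, c1, c2, libs = c("fetal", "adult")) {
  TagSet(seqs, matrix(c(c1, c2), ncol = 2,
                      dimnames = list(NULL, libs)))
}
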