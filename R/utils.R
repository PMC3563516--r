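## Small internal helpers shared across modules.

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(DNAStringSet(x)))
}

## random DNA of length n with a given GC fraction
.randomSeq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

.hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

## substitute one random base at position i (or random position)
.mutateBase <- function(seq, pos) {
  bases <- c("A", "C", "G", "T")
  old <- substr(seq, pos, pos)
  new <- sample(setdiff(bases, old), 1)
  substr(seq, pos, pos) <- new
  seq
}

.writeTSV <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## collapse a character vector of inserts to unique tags + counts
.collapseTags <- function(inserts) {
  tab <- table(inserts)
  list(sequence = names(tab), count = as.integer(tab))
}
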