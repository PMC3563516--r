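## RNA secondary structure: MFE folding under a simplified nearest-neighbour
## model, plus structure utilities used by the hairpin screening criteria.

#' Default folding energy model parameters
#'
#' The folding engine uses a simplified nearest-neighbour additive model:
#' stacked base pairs contribute -(s(outer) + s(inner))/2 kcal/mol where s()
#' is a per-pair-type strength (GC > AU > GU); hairpin loops cost
#' `hairpin0 + hairpin1 * loop_length`; interior loops and bulges cost
#' `interior0 + interior1 * loop_length`; closing a multiloop costs a flat
#' `multi0`. Unpaired external bases are free, so the minimum free energy is
#' always <= 0. The model is rank-oriented: it is designed to order hairpin
#' precursors against other RNAs the way full thermodynamic folders do, not
#' to reproduce wet-lab energies.
#'
#' @return Named numeric vector of model parameters (kcal/mol units).
#' @export
foldingParams <- function() {
  c(bpGC = 3.3, bpAU = 2.1, bpGU = 0.8,
    hairpin0 = 5.5, hairpin1 = 0.3,
    interior0 = 3.0, interior1 = 0.5,
    multi0 = 9.0)
}

#' Fold an RNA (or DNA-alphabet) sequence to its minimum free energy
#'
#' Computes the pseudoknot-free minimum-free-energy secondary structure by
#' dynamic programming under the model of [foldingParams()]. Allowed pairs
#' are AU, GC and GU (T is read as U); hairpin loops have at least 3
#' unpaired bases; interior/bulge loops are capped at 30 unpaired bases.
#'
#' @param sequence Character scalar over ACGU/ACGT.
#' @param params Energy model parameters, see [foldingParams()].
#' @return List with elements `structure` (dot-bracket string), `mfe`
#'   (kcal/mol, <= 0).
#' @examples
#' foldRNA("GGGGAAAACCCC")
#' @export
foldRNA <- function(sequence, params = foldingParams()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!grepl("^[ACGUTacgut]*$", sequence))
    stop("invalid alphabet: sequence must be over ACGU/ACGT")
  res <- .fold_mfe_cpp(sequence, unname(params))
  list(structure = res$structure, mfe = res$mfe)
}

#' Parse a dot-bracket string into a pair table
#'
#' @param structure Dot-bracket string.
#' @return Integer vector `pt` with `pt[i]` the partner of position i, or 0.
#' @export
pairTable <- function(structure) {
  ch <- strsplit(structure, "")[[1]]
  pt <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (!length(stack)) stop("unbalanced brackets in structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced brackets in structure")
  pt
}

.baseCode <- function(seq) {
  chartr("Uu", "Tt", toupper(seq))
}

.pairStrength <- function(a, b, params) {
  key <- paste0(sort(c(a, b)), collapse = "")
  switch(key, CG = params[["bpGC"]], AT = params[["bpAU"]],
         GT = params[["bpGU"]], -1)
}

#' Energy of a given secondary structure under the folding model
#'
#' Evaluates the additive energy of an explicit structure (pair table or
#' dot-bracket) on a sequence, applying exactly the same model as
#' [foldRNA()]: stack terms, hairpin and interior/bulge loop penalties, and
#' the multiloop constant. Used to score sub-structures (e.g. a trimmed
#' precursor) and as an independent check on the folding engine.
#'
#' @param sequence Character scalar.
#' @param structure Dot-bracket string, or an integer pair table.
#' @param params Energy model parameters.
#' @return Energy in kcal/mol.
#' @export
structureEnergy <- function(sequence, structure, params = foldingParams()) {
  s <- strsplit(.baseCode(sequence), "")[[1]]
  pt <- if (is.character(structure)) pairTable(structure) else structure
  if (length(pt) != length(s)) stop("structure/sequence length mismatch")
  pairs <- which(pt > seq_along(pt))  # i with partner j > i
  energy <- 0
  for (i in pairs) {
    j <- pt[i]
    if (.pairStrength(s[i], s[j], params) < 0)
      stop("illegal base pair ", s[i], "-", s[j], " at ", i, ",", j)
    ## direct children: top-level pairs strictly inside (i, j)
    children <- integer(0)
    k <- i + 1
    while (k < j) {
      if (pt[k] > k && pt[k] < j) { children <- c(children, k); k <- pt[k] + 1 }
      else if (pt[k] != 0 && (pt[k] <= i || pt[k] >= j))
        stop("crossing pairs (pseudoknot) in structure")
      else k <- k + 1
    }
    if (length(children) == 0) {
      L <- j - i - 1
      if (L < 3) stop("hairpin loop smaller than 3")
      energy <- energy + params[["hairpin0"]] + params[["hairpin1"]] * L
    } else if (length(children) == 1) {
      k <- children[1]; l <- pt[k]
      L <- (k - i - 1) + (j - l - 1)
      if (L == 0) {
        energy <- energy - (.pairStrength(s[i], s[j], params) +
                            .pairStrength(s[k], s[l], params)) / 2
      } else {
        energy <- energy + params[["interior0"]] + params[["interior1"]] * L
      }
    } else {
      energy <- energy + params[["multi0"]]
    }
  }
  energy
}

#' Adjusted MFE and minimal free energy index of a precursor
#'
#' AMFE is the MFE normalized to a 100-nt sequence, AMFE = (-MFE / length) x
#' 100. The minimal free energy index MFEI = AMFE / GC%, with GC content in
#' percent; values above ~0.85 are characteristic of miRNA precursors and
#' separate them from tRNA (~0.64), rRNA (~0.59) and mRNA (~0.65) folds.
#'
#' @param mfe Minimum free energy, kcal/mol (<= 0).
#' @param sequence Precursor sequence.
#' @return List with `amfe` (kcal/mol per 100 nt), `mfei` (dimensionless)
#'   and `gc_percent`.
#' @examples
#' computeMFEI(-40, strrep("ACGT", 25))  # AMFE 40, MFEI 0.8
#' @export
computeMFEI <- function(mfe, sequence) {
  stopifnot(mfe <= 0, nchar(sequence) > 0)
  s <- strsplit(.baseCode(sequence), "")[[1]]
  gc <- mean(s %in% c("G", "C")) * 100
  amfe <- (-mfe / length(s)) * 100
  if (gc == 0) stop("MFEI undefined for zero GC content")
  list(amfe = amfe, mfei = amfe / gc, gc_percent = gc)
}

#' AU content of a sequence
#' @param sequence Character scalar.
#' @return Fraction of A/U (A/T) bases in `[0, 1]`.
#' @export
auContent <- function(sequence) {
  s <- strsplit(.baseCode(sequence), "")[[1]]
  mean(s %in% c("A", "T"))
}
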