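---
title: "Small RNA-seq miRNA discovery and profiling with mirpipe: methods"
author: "mirpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirpipe methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model of the data

`mirpipe` re-implements, as a tested reusable pipeline, the classic
two-library small RNA-seq analysis used for miRNA surveys of animal
tissues (for example fetal versus adult skeletal muscle): raw reads are
cleaned into unique tags with a conservation-checked filter ledger, tags
are mapped perfectly to a genome and annotated into RNA categories,
conserved miRNAs are profiled against miRBase-style references, novel
miRNAs are discovered by hairpin folding with minimal-free-energy-index
screening, differential expression between the two libraries is assessed
with an exact conditional count test, and stem-loop qPCR is quantified by
2^-ddCt. The design has one pooled library per condition and no
biological replicates — the historical deep-sequencing survey design —
so no replicate-aware model (negative binomial and the like) is offered;
the count test conditions on the pair of library totals instead.

The central containers are S4 classes: `TagSet` (unique tag sequences as
a `DNAStringSet` plus a tag-by-library count matrix), `CleaningSummary`
(the filter ledger, whose validity method enforces
`clean = high_quality - sum(filters)` so an inconsistent ledger cannot be
constructed) and `CategorySummary` (per-category unique/read counts).
Genomic intervals are `GRanges`, references are `DNAStringSet`s, GFF3 and
FASTA/FASTQ go through `rtracklayer` and `Biostrings`.

# Read cleaning

Each parseable read is assigned to exactly one ledger category with fixed
priority: no 3' adapter, empty insert, 5'-adapter contamination, shorter
than 18 nt, poly-A, clean. Published pipelines name these categories but
not their matchers, so the matchers are explicit, deterministic choices
exposed as arguments: the 3' adapter is located by exact match of its
first 8 bases anywhere in the read; a 5' contaminant is an insert
beginning with the adapter's last 6 bases; poly-A means at least 80% A.
All parseable input reads count as "high quality": quality filtering
happens upstream on real data and no published rule exists to model, so
simulated reads carry constant high quality and the category is a
pass-through count. U and T are interchangeable on input; the internal
alphabet is DNA.

# Mapping and annotation

Mapping is perfect-match only, both strands, exhaustive
(`Biostrings::matchPDict` grouped by tag width); a naive sliding-window
scan serves as the test oracle on small genomes. Each genome-matched tag
receives one category by the fixed priority miRNA > rRNA > tRNA > snRNA >
snoRNA > scRNA > srpRNA > repeat > exon_sense > exon_antisense >
intron_sense > intron_antisense > unknown; one bp of overlap suffices,
and a multi-hit tag takes the highest-priority category among its hits so
the partition stays exact (read counts are never split). Tags with no
genome hit are reported separately from genome-matched "unknown" tags
rather than folded into one bucket. Coordinates are 1-based inclusive
internally; BED's 0-based half-open convention is converted at the I/O
boundary by `rtracklayer`.

# Known-miRNA profiling

A tag is a conserved miRNA iff it equals a reference mature exactly, or
lies wholly within the reference hairpin and overlaps the mature site by
at least 16 nt (the variant-inclusive count; published analyses pool 1–5
nt end homologs without stating a window, so the window is explicit and
configurable). End variants report signed 5'/3' offsets (positive =
extension); single-base edits are tags at Hamming distance exactly 1 from
an equal-length 5'-anchored window of a mature, with A-to-G transitions
and untemplated 3' A/U additions classed separately (an addition is
untemplated when the hairpin does not continue with those bases). Arm
usage flags a precursor "near-equal" when the minority arm carries at
least one third of its reads — chosen so that read pairs like 447/680 and
186/314, the canonical both-arms-retained examples, are flagged.
Nucleotide bias is the read-weighted base frequency per mature position,
renormalized per position over observed bases.

# Novel discovery

Unannotated genome-matched tags with at most 10 perfect genome hits are
clustered (same strand, within 30 nt); each cluster's most abundant tag
is the mature candidate; flanked windows around the tag are extracted,
folded, and the candidate screened. A ladder of window geometries is
scanned (the full 150/150 window first, then smaller and one-sided
windows down to 15/45): a pre-miRNA's star arm lies within a few dozen
nt on one side of the mature, and a single large window can bury the
hairpin when distant flanks pair more favourably — scanning windows is
what discovery tools in this family do. A candidate is accepted as soon
as one window passes every criterion. The criteria: the mature must lie wholly in one arm
of a single stem-loop (all paired mature bases pair to one side, partner
positions monotone — no break — and exactly one hairpin loop with no
multiloop branch inside the trimmed precursor); fewer than six unpaired
mature bases (a bulge counts one mismatch per base); mature:star duplex
hybridization energy below -20 kcal/mol; precursor MFEI above 0.85;
precursor AU content within 30–70%; mature length 20–22 nt (bound
configurable to 23). A candidate whose star-arm sequence is itself
observed in the tag data is upgraded to "high" confidence but the star is
not required. The precursor is trimmed to the minimal stem-loop spanning
mature and star before AMFE/MFEI are computed, because the 320-nt window
would otherwise bias MFEI downward. Accepted candidates are deduplicated
by overlapping genomic locus on either strand — the reverse complement of
a hairpin is the same hairpin, and minus-strand rediscovery would
otherwise double-count loci.

The single-stem-loop requirement deserves a note: without it, a random
tag that merely sits near a genuine hairpin can "borrow" that hairpin's
stem through the trimming step and pass the energy criteria. Requiring
exactly one hairpin loop and no branching inside the trimmed span
restores the intended meaning of "an appropriate hairpin".

## The folding engine

Folding is an in-package dynamic program (Rcpp) over a simplified
nearest-neighbour model: stacked pairs contribute
-(s(outer)+s(inner))/2 with strengths GC 3.3, AU 2.1, GU 0.8 kcal/mol;
hairpin loops cost 5.5 + 0.3/nt, interior/bulge loops 3.0 + 0.5/nt
(capped at 30 unpaired bases), multiloop closure a flat 9.0; hairpin
loops need 3 or more unpaired bases and pseudoknots are excluded. The
model is rank-oriented: loop penalties sit at realistic thermodynamic
magnitudes so that the conventional MFEI threshold of 0.85 — defined in
the literature under full thermodynamic folders — separates miRNA-like
hairpins from tRNA/rRNA/mRNA-like and random folds, while the absolute
energies are not wet-lab calibrated. Correctness of the DP itself is
pinned by an exhaustive-enumeration oracle: on random sequences up to 12
nt every pseudoknot-free structure is enumerated and scored by an
independent R evaluator of the same model, and the DP optimum must agree
exactly (200 sequences in the acceptance suite). An external
thermodynamic folder can be substituted behind `foldRNA()`'s contract.

# Differential expression

Normalized expression is transcripts per million clean reads,
NE = count/total x 1e6; zero counts take a pseudo-expression of 0.01 TPM
in ratios only (raw NE stays 0). Fold change is log2(NE1/NE2). The
p-value is the exact conditional test for a pair of counts from two
libraries of known depth: p(y|x) = (N2/N1)^y (x+y)! / (x! y!
(1+N2/N1)^(x+y+1)). Although the surrounding text of such pipelines
sometimes says x and y are normalized expressions, the factorial form
requires integers, so raw counts are used. Tails are accumulated in
log-gamma space; the upper tail is summed upward from y until geometric
decay makes the remainder negligible, which avoids the catastrophic
cancellation of evaluating 1 - C(y-1) when the tail is tiny. The
two-sided p is 2 min(C, D) capped at 1 (the combination rule is a package
choice; both tails are also reported), with Benjamini–Hochberg adjustment
across all tested miRNAs and a default alpha of 0.01. Classes follow the
conventional scatter coloring: ratio > 2 up, ratio <= 1/2 down, otherwise
unchanged.

# qPCR

2^-ddCt with triplicate wells aggregated by arithmetic mean; a replicate
more than 0.5 cycles from the triplicate median is flagged; Ct above 40
(or missing) is a non-detect, reported as non-detected rather than N = 0;
the calibrator sample is a required argument (never guessed) and has
N = 1 exactly. No amplification-efficiency correction is applied — the
pure 2^-ddCt form is the contract.

# The synthetic study

`simulateStudy()` generates the entire toy world with recorded ground
truth: a 50 kb random genome at GC 0.42, 30 known and 10 novel planted
hairpins (mature + A/C-biased loop of 10–16 nt + near-reverse-complement
star with 0–3 mismatches, re-audited against the discovery criteria at
construction), two loci per other RNA class, and two libraries of 2e5
reads. Inserts peak at 22 nt; filter-category rates mirror a typical
published ledger (for example 2.4% sub-18-nt, 0.15% 5'-contaminated);
15% of miRNA reads carry 1–5 nt end shifts (90% at the 3' end), 5% carry
a single base edit or an untemplated 3' A/U addition, sequencing error
is 0.001/base, and 8% of each hairpin's reads come from the star arm.
Twenty knowns are differentially expressed at 4-fold (ten up, ten down)
with mirrored baseline abundances and an equal miRNA read share (0.72)
in both libraries, so planted fold changes equal expected count ratios
exactly; an asymmetric share (as real fetal/adult libraries show) is
available through `mirna_read_share` but would shift all ratios by a
common factor. Problem sizes (2e5 reads, 50 kb genome) were chosen so a
desk-scale machine reproduces the full analysis in about a minute.

The generator does not model indels, quality decay, ligation bias or
biological replicates — so passing tests demonstrate correct bookkeeping,
screening and inference on an idealized library, not robustness to
instrument pathologies. The negative control for discovery is a
dinucleotide-preserving (Altschul–Erickson) shuffle of the genome with
tags drawn from its windows at the study's cluster density: the shuffle
destroys planted hairpins while preserving composition, so any accepted
candidate is a false positive of the criteria.

# Numerical and degenerate-input choices

Ties in known matching break toward the exact match, then lexicographic
id; edit-reference ties break toward the higher-count reference. Empty
inputs yield empty results (cleaning an empty file gives a ledger of
zeros; an empty tag set maps to an empty hit list); an empty genome, a
zero library total, a non-positive abundance, or a missing reference gene
are errors. The DP traceback prefers unpaired bases on exact energy
ties, so reported structures always score exactly their reported MFE.
All randomness flows from a single seed; a fixed seed reproduces the
study byte for byte.
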