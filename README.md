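# mirpipe

An end-to-end small RNA sequencing analysis pipeline for two-library
designs — the classic deep-sequencing survey layout with one pooled
library per condition (for example fetal versus adult skeletal muscle).
It is aimed at people who want the whole historical analysis chain as
tested, reusable R functions rather than a patchwork of one-off scripts:

* **Read cleaning** — adapter trimming and filtering with a
  conservation-checked ledger (`clean = high_quality − Σ filters` is an
  enforced class invariant), collapsing reads to unique tags with counts.
* **Mapping & annotation** — perfect-match genome mapping of tags on both
  strands, then one RNA category per tag (miRNA, rRNA, tRNA, sn/snoRNA,
  repeat, exon/intron sense/antisense, unknown) by a fixed priority.
* **Known-miRNA profiling** — exact and variant-inclusive matching
  against miRBase-style mature/hairpin references; arm (miR/miR*) usage,
  per-position nucleotide bias, single-base edits and untemplated 3′ A/U
  additions, 5′/3′ end variants (isomiRs), and family summaries.
* **Novel-miRNA discovery** — hairpin folding of 150-nt flanked windows
  with an in-package dynamic program and screening by the standard
  criteria: mature wholly in one arm of a single stem-loop with no loop
  overlap or break, mature:star hybridization energy < −20 kcal/mol,
  MFEI > 0.85, AU content 30–70%, fewer than six mature:star mismatches,
  mature length 20–22 nt.
* **Differential expression** — normalized expression (TPM),
  log2 fold change, and the exact conditional count test
  p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1)) with
  Benjamini–Hochberg adjustment and the conventional up/unchanged/down
  classes at ratio 2 and ½.
* **qPCR** — stem-loop RT-qPCR relative quantification by N = 2^−ΔΔCt
  against a reference gene and calibrator sample.
* **Synthetic data** — `simulateStudy()` builds a complete toy world
  (genome, planted known/novel hairpins, annotations, references, raw
  FASTQ, qPCR Ct tables) with per-read ground truth, so the entire
  pipeline is testable without any download.

## Worked example

```r
library(mirpipe)

cfg   <- simulationConfig(seed = 7,
                          library_sizes = c(fetal = 50000L, adult = 50000L))
study <- simulateStudy(cfg)
res   <- runPipeline(reads = study$reads, genome = study$genome,
                     annotation = study$annotation,
                     mature_ref = study$mature_ref,
                     hairpin_ref = study$hairpin_ref,
                     families = study$families,
                     adapter3 = cfg@adapter3, adapter5 = cfg@adapter5,
                     outdir = "results")

res$cleaning$fetal
#> CleaningSummary for library fetal
#>   total_read                    50000
#>   high_quality                  50000 100.00%
#>   adaptor3_null                    33   0.07%
#>   insert_null                      17   0.03%
#>   adaptor5_contaminants            77   0.15%
#>   small_than_18nt                1309   2.62%
#>   polyA                             1   0.00%
#>   clean_reads                   48563  97.13%
```

The ledger says 48,563 of 50,000 reads (97.13%) survive the five filters;
the class guarantees the categories sum exactly. The insert length
profile peaks at 22 nt (32,789 reads, 34%), the miRNA-typical mode. All
ten planted novel hairpins are recovered with their screening statistics:

```r
head(res$novel$novel[, c("id", "mature", "mfe", "duplex_energy",
                         "mfei", "confidence")], 3)
#>      id                 mature   mfe duplex_energy mfei confidence
#> 1 miRn1 TTCCAGCGCTGCTTTTACGAGT -37.3         -46.7 1.29       high
#> 2 miRn2  CTTGGCTTTCTTTGCTCTGTC -31.8         -40.3 1.51       high
#> 3 miRn3 AATCGGTTCAGACCCCTTTAGG -25.7         -36.0 0.95       high
```

`mfei` above 0.85 and duplex energies far below −20 kcal/mol mark genuine
hairpins; `"high"` confidence means the star arm was itself sequenced.
The DE table leads with the planted 4-fold miRNAs:

```r
head(res$de[, c("mirna_id", "x", "y", "log2fc", "padj", "class")], 3)
#>        mirna_id    x    y log2fc padj class
#> 1  bta-miR-sim1 4699 1204   1.97    0    up
#> 5  bta-miR-sim5 3412  846   2.01    0    up
#> 10 bta-miR-sim10 5173 1308   1.98    0    up
```

Counts of 4,699 versus 1,204 at equal depth are a 1.97 log2 ratio —
the planted 4-fold change (attenuated slightly by isomiR/edit reads) —
with a vanishing adjusted p-value from the exact conditional test.

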