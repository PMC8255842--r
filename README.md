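# mirpref

`mirpref` analyses how a microRNA selects its target genes and screens
miRNAs as prognostic biomarkers in a clinical cohort. It is aimed at
transcriptomics researchers who have (i) mimic-transfection RNA-seq
expression tables from two cell lines and a transcript FASTA/annotation,
and/or (ii) a cohort miRNA expression matrix with clinical follow-up, and
who want the standard canonical-seed-site readouts without depending on
web services.

## What it computes

**Seed-site scanning.** For a mature miRNA with sequence
*m₁m₂…mₙ* (5'→3'), the three canonical site types on the target strand
(5'→3') are

- **7mer-A1** = revcomp(*m₂…m₇*) + `A`
- **7mer-m8** = revcomp(*m₂…m₈*)
- **8mer** = revcomp(*m₂…m₈*) + `A`

where the terminal `A` is a literal target adenosine opposite miRNA
position 1. Every 8-nt window of a transcript is classified with
longest-match priority 8mer > 7mer-m8 > 7mer-A1, and each site is
localised to 5'UTR/CDS/3'UTR (windows straddling a boundary are labelled
`junction`).

**Differential expression intersection.** Per cell line,
log₂FC = log₂((mimic + ε)/(NC + ε)) on condition means; a gene is
*shared-down* when log₂FC ≤ −log₂(1.5) in every cell line (thresholds
configurable), and the most-downregulated table keeps genes with
log₂FC < −0.9 everywhere.

**Target preference.** Fraction of shared-down genes with ≥ 1 site,
binding-mode and binding-region distributions, Spearman correlation of
log₂FC versus site count, and hypergeometric over-representation of the
regulated set against user-supplied GMT gene sets with
Benjamini–Hochberg adjustment.

**Cohort screen.** Per miRNA: median-split log-rank test for overall
survival, Spearman correlation with ordinal T and pathological stage,
Mann–Whitney test for M0 vs M1, each reported as a signed association at
α = 0.05. A miRNA with survival "−", stage "+", M "+" significance is
*oncogenic-pattern*; the mirror image is *suppressor-pattern*; a miRNA
significant in all three endpoint groups with consistent signs is
*promising*.

**Synthetic data.** Every input can be generated with exhaustive ground
truth: transcriptomes with planted sites (backgrounds are scrubbed of
accidental matches), mimic/NC experiments under a stated knockdown model,
and cohorts with planted signed survival/stage/metastasis effects.

## Worked example

```r
library(mirpref)

mir <- mature_mirna("miR-194", "UGUAACAGCAACUCCAUGUGGA")
build_seed_patterns(mir)
#>    7mer-A1    7mer-m8       8mer
#>  "UGUUACA"  "CUGUUAC" "CUGUUACA"

tx <- transcript_model("CCND1-3utr", "CCND1", "GGGGTGTTACAGGGG", 0, 4)
find_seed_sites(mir, tx)
#>   transcript_id gene_id start length site_type region
#> 1    CCND1-3utr   CCND1     4      7   7mer-A1   3UTR
```

The 7mer-A1 pattern `UGUUACA` is `TGTTACA` in DNA spelling — the heptamer
found once in the CCND1 3'UTR — and the site starts at 0-based position 4
of the toy context (1-based 5 in written reports). Replacing the heptamer
with `AAAAACA` yields zero sites.

A fully synthetic end-to-end run:

```r
s <- run_pipeline("demo-out", seed = 1, n_genes = 120, quiet = TRUE)
s$shared_down                      # 69 genes knocked down in both lines
s$fraction_with_sites              # 1 (all shared-down genes carry sites)
round(unlist(s$mode_distribution), 3)
#> 7mer-A1 7mer-m8    8mer
#>   0.324   0.362   0.314
round(unlist(s$region_distribution), 3)
#>   CDS  3UTR
#> 0.105 0.895
s$cohort$promising
#> [1] "onco-1" "onco-2" "onco-3" "onco-4" "supp-2" "supp-3"
```

The mode distribution is near-uniform and ~90% of sites sit in the 3'UTR
because those are the generator's planting defaults; the cohort screen
recovers most of the eight planted prognostic miRNAs as promising. All
tables (`sites.tsv`, `fold_changes.tsv`, `associations.tsv`,
`biomarker_calls.tsv`, …) and a `summary.json` are written to the output
directory; reruns with the same seed are byte-identical.

A thin command-line wrapper is installed at
`inst/scripts/mirpref-pipeline.R` for shell use; see its header for
flags.

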