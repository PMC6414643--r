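# ampedit

Combinatorial A-to-I editing and splice-isoform quantification of the
serotonin receptor 2C (5-Ht2cr) pre-mRNA from amplicon deep sequencing.

## What it does, and for whom

The 5-Ht2cr pre-mRNA is processed in two coupled ways: alternative 5'
splicing either retains exon Vb (full-length receptor mRNA, 209 nt mapping
contig) or skips it (truncated variant, 114 nt), and ADAR enzymes edit up
to eleven adenosines (sites 1, 2, 3, A, B, E, C, D, F, G, H) inside a
30-nt window of exon Vb.  Since inosine reads as G, editing appears as
A→G substitutions in cDNA.  An RT-PCR amplicon spanning exons IV–VI covers
every site on every read, so each read reports one of 2^11 = 2048 joint
**editing patterns** ("ABD", "AECD", …, or "NoEdit") plus its splice
isoform.

`ampedit` is for transcriptomics researchers analysing such amplicon data
(e.g. comparing wild-type mice against Snord115-perturbed genotypes in
choroid plexus).  The pipeline:

1. assigns each read (SAM/BAM, or raw FASTQ via a built-in edit-distance
   classifier) to the full-length or truncated contig;
2. calls one editing pattern per read from the eleven site bases
   (`G` = edited, `A` = unedited; reads with indels, partial coverage, or
   non-A/G site bases are rejected and tallied);
3. builds libraries × patterns matrices normalized as
   `RPKM = reads / length × (1e9 / total mapped reads)` and filters on
   mean RPKM ≥ 10 in either genotype;
4. tests each pattern (and each site, by summing the patterns containing
   it) between genotypes with a two-sided Student's t-test, adjusts with
   the Benjamini–Hochberg step-up, and reports fold changes, isoform
   percentages and overall editing levels.

A generative simulator (`simulate_design()`, `snord115_profile_pair()`)
emulates the full 12-library two-genotype study design with per-read
ground truth, so every stage is testable with no external data.

## Worked example

Simulate the default design (6 + 6 libraries, 20,000 reads each, 0.5%
per-base error), quantify, and compare genotypes:

```r
library(ampedit)

cfg <- pipeline_config(seed = 1)
des <- sim_design(reads_per_library = 20000, seed = 1)
man <- run_simulate(cfg, des, "sim_out")
q   <- run_quantify(cfg, setNames(man$fastq, man$library_id),
                    man$genotype, "quant_out")
q$splice[, c("genotype", "avg_mapped_reads", "pct_full", "pct_truncated")]
#>   genotype avg_mapped_reads pct_full pct_truncated
#> 1     LoxP            20000     45.1          54.9
#> 2       WT            20000     45.3          54.7

fit <- run_differential(cfg, q$matrix, "diff_out")
fit
#> Differential editing analysis: WT vs LoxP
#>   overall editing level: WT 69.1%, LoxP 64.5% (diff 4.6)
#>   113 patterns tested, 10 with pBH < 0.05
#>   top patterns by |log fold change| (pBH < 0.05):
#>  pattern mean1 mean2 fold_change  p_value     p_bh  sig
#>      BCD  3828  1276       3.000 2.16e-04 0.003481  ***
#>     ABCD 19179  8293       2.312 1.24e-05 0.000280 ****
#>     AECD  5104  2352       2.169 7.23e-04 0.009079  ***
#>      ABD 43860 26834       1.634 2.90e-06 0.000107 ****
#>        E 18062 28190       0.641 4.79e-04 0.006761  ***
```

Reading the output: about 45% of reads carry the full-length isoform in
both genotypes (splicing is unaffected), while overall editing drops from
~69% to ~64% in the perturbed genotype, driven by decreases in
multi-site patterns such as BCD, ABCD, AECD and ABD — the behaviour the
built-in profile pair encodes.  `mean1`/`mean2` are group-mean RPKM
values (WT is the numerator genotype), `pBH` the FDR-adjusted p-value.
At this read depth the estimated fold changes still carry visible
sampling noise for rare patterns; the validation suite quantifies
recovery accuracy at higher depth.

`fit$patterns`, `fit$sites` and `fit$editing_level` hold the full tables;
`plot(fit)` draws a volcano-style overview.  All stages also write TSV
reports and a JSON provenance record to their output directories.

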