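---
title: "Quantifying combinatorial A-to-I editing of 5-Ht2cr pre-mRNA from amplicon deep sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying combinatorial A-to-I editing of 5-Ht2cr pre-mRNA from amplicon deep sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampedit)
```

## The measurement problem

The serotonin receptor 2C (5-Ht2cr) pre-mRNA is post-transcriptionally
processed in two coupled ways.  First, an alternative 5' splice donor either
retains exon Vb (the full-length, functional receptor mRNA) or skips it (a
truncated, non-functional variant).  Second, within a 30-nucleotide stretch
of exon Vb, ADAR enzymes deaminate adenosines to inosines at up to eleven
positions — the five classical sites A, B, E, C, D plus six flanking
positions labelled 1, 2, 3, F, G and H.  Because inosine is read as
guanosine by reverse transcription and sequencing, editing appears as A→G
substitutions in cDNA reads.

Deep sequencing of an RT-PCR amplicon spanning exons IV–VI observes every
site on every read, so the natural unit of analysis is not the per-site
editing rate but the *joint* editing pattern of a read: one of
2^11 = 2048 combinations, labelled by concatenating the edited site labels
in their genomic order ("ABD", "AECD", …) or "NoEdit".  This package
implements that analysis end to end: splice-isoform assignment, per-read
pattern calling, RPKM quantification, and genotype comparisons — together
with a generative simulator so every stage can be validated without any
external data.  The emulated study design compares wild-type mice against a
line that ectopically expresses the snoRNA Snord115 in choroid plexus,
with six biological replicate libraries per genotype.

## The reference model

The amplicon is modelled as two contigs: the full-length sequence (209 nt
by default) carrying the site map, and the truncated sequence (114 nt)
lacking the exon Vb block.  The default reference bundled with the package
is *synthetic*: the real murine sequence and exact site offsets are not
redistributed here, so `default_amplicon_reference()` builds a fixed
209/114-nt pair with eleven 'A' sites placed in a 30-nt window of the
exon Vb block, in the canonical order 1, 2, 3, A, B, E, C, D, F, G, H.
All coordinates are 0-based internally (SAM/BED interoperability) and
1-based only in reports.  Real coordinates can be supplied as a two-record
FASTA plus a site-map TSV via `read_reference()`; `validate_reference()`
checks every invariant (unique labels, monotone positions, ≤30-nt window,
'A' at every site, sites inside exon Vb).

The canonical site order is a design decision: it is inferred from the
pattern labels the analysis must reproduce ("123A", "AECD", "CDH"), which
place E between B and C and the digit sites before the letters.

## Pattern calling

Reads are assigned to a splice isoform either from SAM/BAM alignments
(`read_alignments()`; per-read CIGAR walk to reference-coordinate base
calls, mapping-quality filter, default `min_mapq = 30` — the conventional
high-confidence threshold, since the source analysis specifies only "high
mapping quality") or directly from FASTQ with the built-in classifier
(`classify_raw_reads()`): global edit distance against both contigs in
both orientations, smaller distance wins, ties are unassigned.  Because
the contigs differ by a 95-nt block, classification is robust far beyond
realistic error rates; length-matched reads take a fast mismatch-counting
path and anything else falls back to full dynamic programming.

`call_patterns()` converts the eleven site bases of a full-contig read
into a pattern: 'G' means edited, 'A' unedited.  Three rejection rules
keep the joint pattern trustworthy, and each rejection is tallied, never
silent:

* reads not covering all eleven sites (`partial_coverage`);
* reads with an indel inside the site window (`indel`) — a deletion makes
  site calls undefined;
* under the default `strict` policy, reads with any site base in
  {C, T, N} (`non_AG_base`), because a single miscalled site corrupts the
  whole pattern.  The `lenient` alternative treats such sites as unedited.
  How the original analysis handled non-A/G bases is not documented;
  both policies are implemented and reported.

Rejected reads still count as *mapped* for normalization purposes —
mapped-read totals are alignment-level quantities.

## Quantification and filtering

Counts are normalized exactly as
`RPKM = reads / sequence_length × (1e9 / total_mapped)`, with no
pseudocounts.  Two design decisions fix the terms: `sequence_length` is
the length of the mapping contig (209 nt for every editing pattern, not
the 30-nt window), and `total_mapped` is the library's mapped reads over
*both* splice contigs, since the study reports a single pooled
mapped-read figure per library.  Patterns are kept when their group-mean
RPKM is at least 10 in *either* genotype (inclusive ≥, groups combined
with OR).  Whether the original denominators excluded pattern-level
rejections is unstated; this implementation uses all mapped reads and
documents it.

## Differential statistics

Per pattern, a two-sided Student's equal-variance t-test compares the
per-library RPKM values between genotypes (`var_equal = FALSE` gives
Welch as an option); fold change is the group-1/group-2 mean ratio (NA on
a zero denominator, never infinity); Benjamini–Hochberg step-up
adjustment is applied jointly across all patterns surviving the filter.
Site-level results (`site_contribution()`) sum RPKM over all patterns
containing each site — sites co-occur, so site percentages may exceed
100% jointly — and receive their own BH family across the eleven sites.
Percentages use the edited-patterns denominator (excluding NoEdit) for
both the pattern-level and site-level tables; the source tables state
this explicitly only for the site-level one, so applying it to both is a
documented choice.  The overall editing level is the edited share of the
all-patterns (NoEdit included) group-mean RPKM.

Degenerate input — both groups constant — is resolved by convention:
p = 1 when the means agree, p = 0 with a warning when they differ (which
cannot happen with stochastic data).

## The simulator

`simulate_library()` draws each read independently: splice isoform ~
Bernoulli(`splice_full_fraction`); for full-length reads an editing
pattern from the profile's distribution, writing 'G' at edited sites; then
i.i.d. uniform per-base substitution errors.  Errors deliberately hit
editing sites too, producing false A↔G flips at rate `error_rate/3` per
site — the simulator's most important realism feature, because it lets the
tests quantify how sequencing noise contaminates rare patterns with reads
from abundant neighbours (e.g. CD→BCD needs a single false flip).  At
PGM-like error rates this cross-contamination biases rare-pattern fold
changes by tens of percent, which is why parameter-recovery validation
runs noise-free while the error model is validated separately.  There is
no indel or PCR-duplicate model: sites are substitution calls, and
indel-bearing reads would be discarded by the caller anyway.

`sim_design()` defaults encode the emulated study: 6 replicates × 2
genotypes, full-amplicon single-end reads, per-base error 0.005 (an
Ion-PGM-like substitution rate), per-library seeds derived from the master
seed by a fixed 31-bit hash so designs reproduce byte-identically.
`simulate_pattern_counts()` draws per-library pattern counts directly from
the same multinomial law — the exact marginal of the read generator at
`error_rate = 0` — for calibration experiments at realistic depth where
materializing millions of read strings adds nothing.

### The built-in genotype profile pair

`snord115_profile_pair()` is the package's reference truth for end-to-end
validation.  Its WT distribution is D-dominant (the single-D isoform is
~61% of edited transcripts), the overall editing levels are 69% (WT) and
64% (perturbed), splice full-length fractions 45.2%/45.3%, and the WT/LoxP
pattern-probability ratios equal the fold changes the pipeline is expected
to recover (BCD 4.9, AECD 2.8, ABCD 2.5, ABD 1.75, AC 1.6, among others).
One constraint deserves note: probabilities must sum to one in each
genotype, so the pair cannot simultaneously fix every pattern ratio, the
editing levels, *and* the implied site-level fold changes.  The profile
prioritizes exact pattern ratios and editing levels; as a consequence the
implied D-*site* fold change is ~1.07 rather than ~1.2.  Background
patterns (2D, DG, 1D, DH and a few non-D combinations) fill the remaining
mass with ratio 1.

## What the tests show — and what they cannot

The validation suite covers: exhaustive label round-trips over all 2048
patterns; lossless recovery (at `error_rate = 0` the pipeline reproduces
the truth histograms *exactly*); agreement between the pattern caller and
a naive enumerate-all-variants window scan, including injected C/T bases
and indels; BH against a hand-coded step-up; null calibration (both
genotypes from one profile, 500 replications at the emulated study's
depth of ~5.6 million reads/library: the raw p < 0.05 fraction sits in
the 99% binomial band around 5%); and effect recovery (6 + 6 libraries at
10^6 reads/library, noise-free, all five reference fold changes within
10% relative error with the correct sign).  The 10^6 depth is the
package's validation size: at 2×10^5 the rarest checked pattern (BCD,
probability 0.0018) yields only ~33 reads per perturbed library and the
10% band is not reliably powered.

The simulator emulates read sampling, splice choice, pattern choice and
uniform substitution noise.  It does *not* emulate PCR amplification
bias, duplicate reads, indel errors, position-dependent quality, or
correlated editing within biological replicates beyond the multinomial.
Passing tests therefore demonstrate the correctness of the *computation*
on data matching those assumptions, not robustness to every artefact of
real amplicon libraries.

## Numerical and reporting conventions

* Threshold comparisons are inclusive (≥); the RPKM filter defaults to 10.
* Percentages are reported at 1 decimal (fold changes at 1–2) while full
  precision is retained in machine-readable outputs.
* Classification ties go to `unassigned` rather than either contig.
* Significance stars follow the usual convention: * < 0.05, ** < 0.01,
  *** < 0.001, **** < 0.0001 on raw p-values.
* Every `run_*()` stage writes a provenance record (package version,
  full configuration, seeds, input checksums) sufficient to reproduce its
  outputs byte-identically.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(seed = 1)
des <- sim_design(reads_per_library = 20000, seed = 1)
man <- run_simulate(cfg, des, "sim_out")
q   <- run_quantify(cfg, setNames(man$fastq, man$library_id),
                    man$genotype, "quant_out")
fit <- run_differential(cfg, q$matrix, "diff_out")
fit$editing_level
head(fit$patterns[order(fit$patterns$p_bh), ])
```

At this scale (2.4 × 10^5 reads) the whole run takes well under a minute;
`scripts/acceptance.R` performs the same computation plus the calibration
and recovery experiments and writes the headline numbers as JSON.

## Known limitations

* The bundled reference is synthetic; real analyses must supply the true
  contigs and site coordinates.
* The statistical model is exactly the source analysis' one — t-tests on
  RPKM values.  No count-model alternatives (negative binomial,
  beta-binomial) are offered, deliberately.
* Editing calls require full-amplicon coverage of all eleven sites; data
  from fragmented libraries would be rejected wholesale rather than
  analysed site-by-site.
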