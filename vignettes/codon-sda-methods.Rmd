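---
title: "Scoring codon optimality as Supply-to-Demand Adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring codon optimality as Supply-to-Demand Adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonSDA)
```

## The problem

Synonymous codons are not interchangeable for the translation machinery:
each is decoded by a specific subset of tRNA isoacceptors, at rates shaped
by Watson–Crick versus wobble pairing and by how much of the cellular tRNA
pool competes for the same anticodons. Two cells with the same proteome
demand but different tRNA repertoires therefore translate the same
transcript with different efficiency. This package implements a complete,
testable chain from small RNA-seq alignments to a per-codon optimality
score — the Supply-to-Demand Adaptation weight (SDAw) — and the cohort
statistics used to compare it between conditions.

## Quantifying the supply: mature tRNA references and two-pass filtering

tRNA genes are short, heavily duplicated, intron-bearing, and post-
transcriptionally extended with a 3' CCA tail. Reads from mature tRNAs
therefore often cannot map to the genome at all (they span splice
junctions or run into the CCA), while reads from unprocessed pre-tRNAs and
from elsewhere in the genome can masquerade as tRNA signal. The reference
module handles this with two artifacts:

1. a **mature library**: each annotated gene is spliced, CCA-tailed, and
   100%-identical sequences are collapsed into clusters, because reads can
   never distinguish identical copies;
2. a **masked genome plus pre-tRNA contigs**: every gene span is replaced
   by N and each gene is re-added as a separate contig with genomic flanks
   (default 50 nt, configurable — annotation pipelines do not fix this
   width, and 50 nt comfortably exceeds small-RNA read lengths).

First-pass alignments against artifact 2 classify reads: hits on the
masked chromosomes are non-tRNA reads, hits overlapping a flank by even
one base are unprocessed pre-tRNA reads; both classes are excluded before
the second pass against the mature library. Reads absent from the first
pass are *kept* — inability to map to the genome is expected for genuine
mature-tRNA reads.

Quantification then applies an isodecoder-tolerant ambiguity rule: a read
whose best-tier hits (minimum mismatch count) all carry one anticodon is
counted for that isoacceptor even if it cannot be placed on a single gene;
a read whose best-tier hits span two anticodons is discarded. "Best tier"
is defined by the minimum edit distance among a read's reported hits: the
upstream aligner's multi-hit reporting is not standardized, and an
explicit tier rule makes the contract deterministic and testable. Reads
with mismatches are retained — tRNAs carry abundant modifications that
appear as misincorporations, and excluding such reads would bias against
heavily modified species.

Profiles are reported as reads per million over the *assigned* reads, so
every profile sums to 10^6 and is comparable across sequencing depths
regardless of how much non-tRNA material a library contains. Downstream
supply values use the square root of RPM, which tempers the dynamic range
of tRNA expression before it enters multiplicative scores; relative
anticodon abundance (RAA) additionally normalizes within each amino-acid
family so that family totals are 1.

## From supply and demand to SDAw

The tAI weight of a codon is the affinity-weighted sum of the abundances
of the anticodons that decode it. For each codon box the four anticodon
slots are the reverse complements of the four codons, and the pairing
affinities are `1 - s` with the non-optimized selective constraints
`s = (0, 0, 0, 0, 0.5, 0.5, 0.75, 0.5, 0.5)`: zero penalty for the four
Watson–Crick geometries, then U:G (0.5), C:I (0.5), A:I (0.75) and G:U
(0.5) wobble. Optimizing `s` against expression data would presuppose the
very codon-expression relationship being studied, so the fixed values are
used. The ninth entry describes prokaryotic lysidine decoding of AUA and
is carried in the configuration but not applied; ATG is the one special
case, decoded by the CAT anticodon alone (its U34 neighbour reads
isoleucine, not methionine). Anticodons whose cognate codon is a stop
(suppressors, selenocysteine) never enter the supply, and mitochondrial
or special-purpose tRNAs (SeC, Sup, Und) are quantified but excluded from
the cytosolic supply pool by default, since the wobble table encodes the
cytosolic decoding rules.

Raw weights are max-normalized (`w = W / max W`); codons left at zero
(no decoder expressed) take the geometric mean of the nonzero weights so
that geometric-mean gene scores stay defined. Gene scores are computed in
log space to avoid underflow on long genes:
`tAI = exp(mean(log w over codons))`. Stop codons are excluded from the
product and the length; for SDA scores methionine is excluded too, and
that exclusion also shortens the effective gene length — counting skipped
positions in the length would silently shrink every score toward 1.

The supply entering SDA is the *relative* weight
`Rw_c = w_c / max(family)`, and the demand is the expression-weighted
codon usage `CU_c = sum_j c_ij mRNA_j`, family-normalized to `D_c`.
Normalizing both sides within amino-acid families removes amino-acid
composition effects and isolates synonymous-codon optimality. Six-fold
amino acids (Leu, Ser, Arg) are single families: the normalization
quantifies over all synonymous codons of the amino acid. `SDAw = Rw / D`
is defined on the 60 codons excluding methionine and stops; codons whose
family demand is zero are flagged missing rather than infinite. Expression
enters on a linear scale (TPM-like); only the tRNA side is
square-root-transformed.

Two structural properties are enforced by tests: SDAw and RtAI are
invariant to global rescaling of either the tRNA pool or the expression
vector, and when supply is proportional to demand within every family all
SDAw — and hence all gene SDA scores — equal 1.

## Modification sites

Positions where reads systematically disagree with the mature reference
mark modified bases that interfere with reverse transcription. Calling is
restricted to uniquely mapped reads (single best-tier hit) so that
cross-mapping between near-identical genes cannot fabricate signal, and
uses a transparent threshold caller: a site is emitted when depth >= 20
and the non-reference fraction >= 0.1. The thresholds are package
defaults, exposed in the configuration; the discovery signal is the
misincorporation fraction itself, and a full genotyping model would add
nothing at tRNA-scale depths. Because tRNAs vary in D-loop and variable
region length, each cluster is globally aligned to a packaged 76-nt
consensus cloverleaf template and sites are reported in consensus
coordinates ("34" is the wobble base); alignments under 40% identity
return "unmapped", and insertions flanking the variable region are
labelled "V-region". Alignment tie-breaks follow the aligner's
deterministic leftmost convention.

One caveat the synthetic tests make visible: when a modification mimics
another isoacceptor's sequence at the modified position (e.g. A-to-G at
the wobble base), short modified reads can become ambiguous between the
two families and drop out of the unique-read pileup. The site is still
called, but its observed fraction underestimates the planted one; observed
misincorporation fractions are lower bounds.

## Cohort statistics

- **Differential**: per feature, `log2(median_B / median_A)` and an
  unpaired two-tailed Wilcoxon rank-sum test, BH-corrected within one
  comparison. Medians match how group-level abundances are summarized
  throughout; the log-fold-change is only reported when both medians are
  positive.
- **Methylation**: the beta value of a gene averages all positions from
  1.5 kb upstream of the strand-aware TSS to the gene end (array mode);
  dense bisulfite data is restricted to the gene body, since Pol-III
  promoter elements are intragenic. Isoacceptor values average member
  genes; coverage (fraction of genes with any data) is reported because
  sparse arrays cover tRNA genes poorly.
- **Copy number**: segmented values (log2(CN)-1 scale) are projected onto
  genes by overlap-weighted averaging; genes outside all segments are
  missing, never zero.
- **MLR**: per isoacceptor and condition,
  `abundance = b0 + bMe*Me + bCNA*CNA` by OLS on complete samples, with at
  least p + 2 = 4 observations and a full-rank design; coefficient
  t-statistic p-values are FDR-corrected jointly across the Me and CNA
  coefficients of all fitted models (the correction scope is recorded in
  the output metadata), and the sign balance of significant coefficients
  is tested with an exact two-sided binomial test against 0.5. Whether
  samples pool across groups within a condition is left to the caller,
  which passes an explicit sample table.
- **Survival**: patients are split into the bottom and top 40% of the
  SDAw distribution (middle excluded; boundary ties broken by stable
  input order), compared by Kaplan–Meier curves and a two-group log-rank
  test. When scanning codons, candidates are restricted to codons whose
  differential SDAw is significant in more than five conditions net of
  direction, and log-rank p-values are BH-corrected across codons.
  Survival times and censoring are taken from the input table as-is.

## What the synthetic data emulates — and what it does not

The generators produce every input the pipeline consumes with known
truth: template-derived tRNA genes (each anticodon family distinguished
by three stem substitutions, isodecoders by a variable-region
substitution, introns inserted after structural position 37, at least one
identical duplicate pair), multinomial reads with configurable length,
error rate and planted misincorporation sites, first-pass reads from
flanks and masked genome, and cohorts with declared regression
coefficients (`b0 = 2, bMe = -3, bCNA = 1.5`), SDAw shifts (2x on
declared codons, 50 samples per group) and survival hazard ratios
(default 3, exponential times, 20% censoring, 200 patients). All
randomness derives from a single integer seed; identical configurations
are byte-identical.

Passing tests on these fixtures demonstrates the correctness of the
contracts — filtering, ambiguity handling, weight algebra, statistical
procedures — not performance on real data: real tRNA families differ at
more positions and less uniformly than three stem substitutions, real
small-RNA libraries contain tRNA fragments and adapter artifacts the
generator does not model, sequencing errors are not uniform, and real
modification chemistry produces position- and context-dependent
misincorporation spectra. The emulated aligner reports hits at the
read's originating offset only, a simplification of full local alignment.

## Problem sizes and numerical choices

The test suite runs quantification recovery at 10^5 error-free reads
(rank correlation of recovered RPM against truth > 0.95), modification
recall on planted sites at 2x10^4 reads, the MLR census at the full
22 conditions x 64 isoacceptors = 1,408 models with 30 samples each,
confidence-interval coverage over 100 replicates at n = 100 and
sigma = 0.1, and log-rank null calibration over 200 replicates at hazard
ratio 1 (Kolmogorov–Smirnov uniformity at alpha = 0.01). Gene scores are
computed in log space; weight tables are exact to 10^-12 against
independent pairing-table oracles in the tests; Wilcoxon tests use the
exact distribution where possible and the mid-rank normal approximation
under ties.

## Known limitations

Isoacceptor-level quantification cannot resolve isodecoder-specific
regulation; discarded cross-anticodon reads bias abundances of closely
related isoacceptors slightly toward zero; SDAw treats supply as total
tRNA rather than the aminoacylated fraction, and demand as mRNA abundance
rather than ribosome occupancy — both are approximations inherited from
what is measurable at cohort scale. The MLR explains tRNA abundance with
two slowly varying genomic covariates and should be read as an
association screen, not a causal model.
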