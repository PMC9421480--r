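---
title: "linctk: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{linctk: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linctk)
```

This vignette explains what `linctk` computes, why its defaults are what
they are, what the synthetic fixtures do and do not emulate, and where
the design was genuinely open and a choice had to be made.

## Coordinates and strand

All coordinates inside the package are 0-based half-open, BED-style.
GTF/GFF (1-based inclusive) is converted at the I/O boundary and
converted back on export; the conversion is its own inverse and is
tested as such. Strand `"."` is permitted only where it is honest — a
mono-exonic model from an unstranded library — and every strand-aware
rule treats `"."` as compatible with either strand. The alternative
(dropping unstranded candidates) silently biases a catalog toward
well-covered loci, which is worse than the occasional ambiguous call.

There is no expression imputation anywhere: a gene absent from a matrix
is an error, not a zero, because "not quantified" and "not expressed"
lead to different downstream calls (a zero row is a legitimate
context-specific candidate; a missing row is a bookkeeping bug).

## The confidence cascade

The definitional filters run in a fixed order (length, intergenicity,
ORF, coding-potential veto) and record the *first* failure, so rejected
transcripts are attributable to one rule and category counts are
disjoint. The promotion cascade is likewise first-hit-wins:
long-read support, multi-exonic structure, then for mono-exonic
candidates synteny-backed conservation, length, expression support.
Fixing the order makes the per-rule counts a partition rather than an
overlapping Venn, and makes the output invariant to input order.

Two readings of "expressed in at least 10 experiments from different
bioprojects" are possible; `linctk` uses the stricter one — experiments
are counted at most once per bioproject, so ≥ 10 *distinct bioprojects*
must each contribute a supporting experiment. The looser reading (10
experiments, ≥ 2 projects) is obtainable by lowering
`hc_min_experiments`. Comparison strictness mirrors the wording each
threshold came with: `> 200 nt`, `> 500 nt`, `> 3 TPM`, `> 1 TPM`, and
`> 0.1 TPM` are strict; "at least"/"50% or more" thresholds (overlap
fractions, experiment counts, motif mismatch limits) are inclusive. A
transcript of exactly 500 nt is therefore LC, and an atlas maximum of
exactly 0.1 TPM is still context-specific.

Intergenicity is defined as zero exonic overlap with annotated genes on
either strand. A transcript nested in an intron is *not* intergenic
here: intronic lncRNAs are a separate class with different biogenesis,
and folding them in would blur the category the package is named for.

For the transposable-element rule two variants exist in the wild: "TE
covers ≥ 50% of the lincRNA" and "the lincRNA covers ≥ 50% of the TE".
The first is the default (`FRAC_OF_LINC`); the second is available as
`FRAC_OF_FEATURE`, which is also the mode used for conserved noncoding
sequences. Fractional modes merge overlapping features of a class
(union coverage) before computing the fraction, so two half-overlapping
TE fragments cannot double-count.

## Tissue specificity and expression annotation

`compute_tau()` averages replicates arithmetically on the TPM scale,
quantile-normalizes the genes × tissues matrix, and applies the
specificity index `sum(1 - x/max(x)) / (n - 1)`. Quantile
normalization is the classic rank-mean construction; ties within a
column receive the mean of the reference values over the tied ranks.
It is implemented directly (about fifteen lines) because the tie
behavior is part of the contract; `limma::normalizeQuantiles`, which
interpolates multi-way ties slightly differently, serves as an
independent cross-check on tie-free matrices in the test suite.

Genes expressed nowhere get `tau = NA` and are excluded from max-tissue
reports — 0/0 is not "uniform". The tissue of maximal expression is
taken on log2(TPM + 1); the argmax is invariant under any monotone
transform, which is the only property downstream code uses, so no
external variance-stabilizing model is needed. Exact ties are broken by
a configurable tissue order and flagged rather than silently resolved.

Differential-expression tables are consumed, not fitted. The default
response thresholds are |log2FC| ≥ 1 and adjusted P ≤ 0.05, both
inclusive; `strict = TRUE` switches both to strict, since the source
wording ("greater or less than 1 or −1", "0.05 or lower") is inclusive
for P but ambiguous for the fold change. Membership is monotone in both
thresholds, which the suite checks by property.

## Evolutionary annotation

The species tree is supplied by the user (newick); node indices are
computed from it rather than hard-coded, so the framework is not tied to
any particular set of genomes. The index of species *s* is the count of
internal nodes on the path from the query tip to `MRCA(query, s)`; the
conservation node of a lincRNA is the maximum index over species with a
hit. The test suite proves this equal to an exhaustive smallest-
containing-clade oracle over *all* presence/absence patterns on trees up
to 12 tips, including non-ladder topologies.

SBSD ("syntenic but sequence divergent") detection requires: a
qualifying block of at least 10 collinear ortholog anchors; the lincRNA
strictly between two consecutive anchors (a lincRNA overlapping an
anchor gene is excluded — counting the anchor itself as the transcribed
locus would make the call circular); a transcribed locus strictly
between the orthologous anchors; orientation relative to at least one
flanking anchor preserved; and *no* sequence homolog already at or
beyond that species' node, so sequence homologs and transcriptional
syntelogs stay disjoint categories. Both annotated lincRNAs and
assembled-but-unannotated transcripts count as "transcribed" on the
target side (configurable via `transcribed_biotypes`), since assembly
evidence is exactly what the call is about.

Reduced-stringency recovery takes the three 200-nt segments of an SBSD
lincRNA (5′, 3′, promoter) through a reciprocal-best-hit discipline on
pre-computed hit tables: best hit by bitscore, ties broken by e-value
then alignment length, exact residual ties meaning "no best hit"; the
forward hit must intersect the expected syntenic interval and the
reverse best hit must land back on the segment. When several segments
recover, the reported label prefers 5′ over 3′ over promoter (gene-body
homology is the stronger claim). Short lincRNAs use their full length
and are flagged truncated.

Family dynamics: ancestral copy number is the rounded mean of homolog
counts over ≥ 3 close relatives, times a whole-genome-duplication
factor (3 for a lineage-specific triplication). Rounding is
half-to-even by default — the choice is documented and configurable
(`"half_up"`) because nothing in the method fixes it; the class is
invariant under jointly scaling the query count and the expectation,
which the suite checks.

## Motif conservation on alignments

All three motif rules operate on the query's alignment columns.
"Alignable region" is read strictly: every query column of the motif
must carry a non-gap character in the homolog, with no credit for
terminal truncation. The sORF rule searches the homolog only within the
±3-AA projection window (a genome-wide search would make the call
depend on unrelated ORFs); peptide identity uses the query peptide
length as denominator and counts alignment gaps as mismatches, so a
truncated homolog peptide cannot pass by shrinking the comparison.
miRNA-site coverage is defined on the query's columns; homolog
insertions inside the site neither break coverage nor count as
mismatches by default (configurable in spirit via the spec object), as
an insertion does not change pairing at the covered positions.

## The synthetic-data generator

The generator is first-class, tested code. Its defaults are the study
conditions the validation suite runs at: fixtures of ~200 lincRNAs;
8-tissue atlases with 3 replicates; multiplicative lognormal replicate
noise (σ = 0.1 where noise is wanted, 0 for exact-recovery checks); a
30% context-specific fraction planted below the 0.1-TPM ceiling;
12-anchor synteny blocks with 20 planted SBSD loci and ≥ 50 decoys in
four classes (outside any block, in an 8-anchor block, orientation
flipped against both anchors, no transcribed target locus); a
ladder-shaped 8-tip default tree. Sequences come from a weak
second-order Markov chain with GC 34% for lincRNAs and 42% for mRNAs,
reflecting the GC deficit of lincRNAs relative to coding genes. Planted
ORFs always run ATG…stop on the sense strand, matching the scanner's
contract; background sequences are redrawn until they carry no
accidental ≥ 100-AA ORF.

Each output stream draws from its own RNG substream derived from the
master seed, so regenerating one fixture never perturbs another, and
identical configurations give byte-identical files (tested by checksum).

Two generator choices deserve a note. Peak tissues are assigned
round-robin rather than randomly, so a pure single-tissue population has
balanced per-column zero counts; under rank-mean quantile normalization
its zeros then map exactly to zero and planted tau is exactly 1 — with
random peaks the zero ranks collide with positive reference values and
the limit is only approached. Second, planted tau truth is computed
*analytically* from the planted means through an independent
re-implementation of the rank-mean map and the specificity index, not by
calling the package's own `quantile_normalize()`; zero-noise recovery is
therefore a genuine two-implementation agreement, not a tautology.

What the fixtures do **not** emulate: read-level errors, assembly
artifacts, splice-graph complexity beyond a few exons, alignment
uncertainty (homolog "alignments" are constructed by planting
substitutions and deletions, so the aligner itself is never exercised),
compositional biases beyond GC, or correlated noise across samples.
Passing the recovery suite therefore demonstrates that the *decision
rules* are implemented correctly and are mutually consistent — it does
not certify performance on real data, where the upstream tools that
produce the consumed tables (assemblers, aligners, DE models) dominate
error rates.

## Numerical choices and degenerate inputs

* Tie-breaks: max-tissue ties flagged and broken by configured order;
  RBH bitscore ties broken by e-value then length, residual ties → no
  best hit; quantile-normalization ties → mean of tied-rank references.
* Correlation: genes constant across samples yield no coefficient
  (`ABSENT`), which consumers render as 0 in consistency matrices;
  r = ±1 is clipped to ±(1 − 1e−6) before the Fisher transform, with a
  warning.
* ORF scanning: three sense-strand frames only; a codon containing `N`
  can be neither start nor stop; ORFs lacking an in-frame stop do not
  count; amino-acid length excludes the stop codon.
* Degenerate promoters at a chromosome edge are truncated at 0.
* Problem sizes in the validation suite (~200 lincRNAs, 8 tissues,
  5 synteny blocks, 8-tip trees) were chosen so every exhaustive oracle
  (all 2^k presence/absence patterns, base-by-base overlap counts) is
  feasible while remaining large enough that planted-truth agreement is
  meaningful.

## Known limitations

Coding potential is an input flag, not a model; ORF length is the only
intrinsic coding signal computed. The harmonization path assumes the
reference annotation's biotypes are trustworthy labels. SBSD detection
assumes anchor tables are collinear and non-overlapping as exported by
standard synteny pipelines; it does not re-verify collinearity.
Neighbor correlation uses log2(TPM+1) in place of a fitted
variance-stabilizing transform; for the MAD filter and Pearson step this
is a monotone, variance-compressing proxy, adequate for ranking but not
identical to a model-based transform on low counts.
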